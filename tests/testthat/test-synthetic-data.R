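test_that("study specs reject impossible designs", {
  expect_error(study_spec(n_tfs = 0), "positive")
  expect_error(study_spec(n_tfs = 20, n_genes = 10), "more regulators")
  expect_error(study_spec(tf_target_density = 1.2), "densities")
  expect_error(study_spec(n_imodulons = 25), "more iModulons")
  expect_error(plate_spec(n_control_wells = 1), "at least 2")
})

test_that("generated TRNs are deterministic, loop-free and structured", {
  spec <- study_spec(seed = 3L)
  trn1 <- simulate_trn(spec)
  trn2 <- simulate_trn(spec)
  expect_identical(trn1, trn2)
  expect_true(all(trn1$regulator != trn1$target))
  expect_false(anyDuplicated(trn1[c("regulator", "target")]) > 0)

  # hub out-degree at least 5x the median
  outdeg <- table(factor(trn1$regulator, levels = tf_names_for_test(20)))
  expect_gte(outdeg[["tf01"]], 5 * median(as.integer(outdeg)))

  # reserved sole-regulator genes really have a single regulator
  counts <- sole_regulator_counts(trn1)
  expect_gte(sum(counts), spec$n_sole_targets)
})

test_that("a dense two-TF spec yields the complete bipartite regulon", {
  spec <- study_spec(n_tfs = 2, n_genes = 3, tf_target_density = 1,
                     tf_tf_density = 0, hub_tfs = character(),
                     n_sole_targets = 0, n_imodulons = 1,
                     ko_specs = list(ko_spec("tf01")),
                     effect_probs = c(activation = 1, repression = 0,
                                      dual = 0))
  trn <- simulate_trn(spec)
  expect_equal(nrow(trn), 6)
  expect_true(all(trn$effect == "activation"))
  expect_true(all(table(trn$target) == 2))
})

test_that("expression decomposes exactly without noise and stores its noise draw", {
  spec <- small_spec(seed = 5L, noise_sd = 0)
  trn <- simulate_trn(spec)
  ex <- simulate_expression(spec, trn)
  expect_equal(ex$expression, ex$M %*% ex$A, tolerance = 1e-12)
  expect_lte(qr(ex$expression)$rank, spec$n_imodulons)

  # KO samples sit at the no-activity extreme of their iModulon's raw row
  for (ks in spec$ko_specs) {
    k <- ex$ground_truth$imodulon_of[[ks$regulator]]
    ko_ids <- ex$samples$sample_id[!is.na(ex$samples$ko) &
                                     ex$samples$ko == ks$regulator]
    if (ex$ground_truth$true_directions[[k]] == -1)
      expect_equal(unname(ex$A[k, ko_ids]),
                   rep(min(ex$A[k, ]), length(ko_ids)))
    else
      expect_equal(unname(ex$A[k, ko_ids]),
                   rep(max(ex$A[k, ]), length(ko_ids)))
  }
})

test_that("expression noise has the specified scale", {
  spec <- study_spec(n_tfs = 20, n_genes = 480, n_reference_samples = 280,
                     noise_sd = 0.25, seed = 11L)
  trn <- simulate_trn(spec)
  ex <- simulate_expression(spec, trn)
  resid <- ex$expression - ex$M %*% ex$A
  expect_equal(resid, ex$ground_truth$noise, tolerance = 1e-12)
  rms <- sqrt(sum(resid^2) / length(resid))
  expect_lt(abs(rms - spec$noise_sd) / spec$noise_sd, 0.10)
})

test_that("synthetic plates are deterministic with coherent ground truth", {
  ps <- plate_spec(n_wells = 30, n_control_wells = 6, n_timepoints = 96)
  p1 <- simulate_plate(ps, seed = 2L)
  p2 <- simulate_plate(ps, seed = 2L)
  expect_identical(p1, p2)
  expect_equal(dim(p1$signal), c(30, 96))

  null_plate <- simulate_plate(plate_spec(n_wells = 30, n_control_wells = 6,
                                          n_timepoints = 96, effect = 0),
                               seed = 3L)
  expect_false(any(attr(null_plate, "truth")$grown))

  clean <- simulate_plate(plate_spec(n_wells = 30, n_control_wells = 6,
                                     n_timepoints = 96, noise_sd = 0,
                                     well_sd = 0, growth_fraction = 0.7),
                          seed = 4L)
  truth <- attr(clean, "truth")
  grown_max <- apply(clean$signal[truth$grown, , drop = FALSE], 1, max)
  ctrl_max <- apply(clean$signal[clean$wells$is_control, , drop = FALSE],
                    1, max)
  expect_true(all(grown_max > max(ctrl_max)))
})

test_that("mutation tables plant convergence and keep frequencies in (0, 1]", {
  spec <- small_spec(seed = 6L)
  tab <- simulate_mutations(spec, simulate_trn(spec))
  expect_true(all(tab$frequency > 0 & tab$frequency <= 1))
  expect_true(all(tab$frequency[tab$sample_type == "isolate"] == 1))
  truth <- attr(tab, "truth")
  for (ko in names(truth)) for (g in truth[[ko]]) {
    lin <- unique(tab$lineage[tab$ko == ko & tab$gene == g])
    expect_gte(length(lin), 2)
  }

  # full-rate convergence reaches every lineage
  spec_all <- small_spec(seed = 7L, convergence_rate = 1,
                         ko_specs = list(ko_spec("tf04",
                                                 convergent_in_regulon = 1L)))
  tab_all <- simulate_mutations(spec_all, simulate_trn(spec_all))
  g <- attr(tab_all, "truth")[["tf04"]]
  expect_equal(length(unique(tab_all$lineage[tab_all$gene == g])), 6)

  # zero background and no planting gives an empty table
  spec0 <- small_spec(seed = 8L, mutations_per_isolate = 0,
                      population_extra_rate = 0,
                      ko_specs = list(ko_spec("tf02")))
  expect_equal(nrow(simulate_mutations(spec0, simulate_trn(spec0))), 0)
})

test_that("growth impacts respect their range and high-impact fraction", {
  spec <- small_spec(seed = 9L)
  trn <- simulate_trn(spec)
  imp <- simulate_growth_impacts(trn, spec)
  expect_true(all(imp$defect >= 0 & imp$defect <= 1))
  expect_identical(imp, simulate_growth_impacts(trn, spec))

  spec0 <- small_spec(seed = 9L, high_impact_fraction = 0)
  imp0 <- simulate_growth_impacts(trn, spec0)
  expect_lt(max(imp0$defect), 0.5)
})

test_that("growth rates encode recovery relative to wildtype", {
  spec <- small_spec(seed = 10L)
  rates <- simulate_growth_rates(spec)
  wt <- rates$growth_rate[rates$strain == "wildtype"]
  for (ks in spec$ko_specs) {
    ends <- rates$growth_rate[!is.na(rates$ko) & rates$ko == ks$regulator &
                                rates$stage == "endpoint"]
    expect_length(ends, spec$lineages)
    if (ks$recovered) expect_gte(mean(ends), 0.95 * wt)
    else expect_lt(mean(ends), 0.95 * wt)
  }
})
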