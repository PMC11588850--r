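#' Generate a synthetic transcriptional regulatory network
#'
#' Draws a regulon table (regulator, target, effect) emulating the
#' structure of curated TRN exports: a configurable TF-to-target and
#' TF-to-TF wiring density, designated hub regulators forced to an
#' out-degree at least five times the median, a reserved set of genes with
#' exactly one regulator, and no self-regulation records. Every regulator
#' is guaranteed at least two targets (curated regulators have annotated
#' binding sites by definition).
#'
#' @param spec A [study_spec()].
#' @return A data.frame with columns `regulator`, `target`, `effect`
#'   (`activation`, `repression` or `dual`), one row per regulatory
#'   interaction.
#' @export
simulate_trn <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  validate_study_spec(spec)
  tfs <- tf_names(spec$n_tfs)
  genes <- gene_names(spec$n_genes)
  with_seed(spec$seed, {
    sole <- if (spec$n_sole_targets > 0)
      sample(genes, spec$n_sole_targets) else character()
    open_genes <- setdiff(genes, sole)

    edge_r <- character(); edge_t <- character()
    # sole-regulator genes: exactly one regulator each
    if (length(sole)) {
      edge_r <- c(edge_r, sample(tfs, length(sole), replace = TRUE))
      edge_t <- c(edge_t, sole)
    }
    # TF -> gene edges
    if (length(open_genes)) {
      draw <- matrix(stats::runif(spec$n_tfs * length(open_genes)) <
                       spec$tf_target_density,
                     nrow = spec$n_tfs)
      idx <- which(draw, arr.ind = TRUE)
      edge_r <- c(edge_r, tfs[idx[, 1]])
      edge_t <- c(edge_t, open_genes[idx[, 2]])
    }
    # TF -> TF edges (ordered pairs, no self-loops)
    if (spec$n_tfs > 1) {
      draw <- matrix(stats::runif(spec$n_tfs^2) < spec$tf_tf_density,
                     nrow = spec$n_tfs)
      diag(draw) <- FALSE
      idx <- which(draw, arr.ind = TRUE)
      edge_r <- c(edge_r, tfs[idx[, 1]])
      edge_t <- c(edge_t, tfs[idx[, 2]])
    }

    # top up: every TF regulates >= 2 targets; hubs >= 5x median out-degree
    add_targets <- function(tf, n_needed, cur_targets) {
      pool <- setdiff(c(open_genes, setdiff(tfs, tf)), cur_targets)
      sample(pool, min(n_needed, length(pool)))
    }
    outdeg <- table(factor(edge_r, levels = tfs))
    for (tf in tfs[outdeg < 2]) {
      extra <- add_targets(tf, 2 - outdeg[[tf]], edge_t[edge_r == tf])
      edge_r <- c(edge_r, rep(tf, length(extra))); edge_t <- c(edge_t, extra)
    }
    outdeg <- table(factor(edge_r, levels = tfs))
    hub_goal <- 5L * max(1L, stats::median(as.integer(outdeg)))
    for (tf in intersect(spec$hub_tfs, tfs)) {
      if (outdeg[[tf]] < hub_goal) {
        extra <- add_targets(tf, hub_goal - outdeg[[tf]], edge_t[edge_r == tf])
        edge_r <- c(edge_r, rep(tf, length(extra))); edge_t <- c(edge_t, extra)
      }
    }

    keep <- !duplicated(paste(edge_r, edge_t)) & edge_r != edge_t
    edge_r <- edge_r[keep]; edge_t <- edge_t[keep]
    pr <- spec$effect_probs[c("activation", "repression", "dual")]
    eff <- sample(names(pr), length(edge_r), replace = TRUE, prob = pr)
    ord <- order(edge_r, edge_t)
    data.frame(regulator = edge_r[ord], target = edge_t[ord],
               effect = eff[ord], stringsAsFactors = FALSE)
  })
}

#' Generate expression data and its ICA decomposition with ground truth
#'
#' Builds a gene-weight matrix `M` whose non-zero weights for each
#' iModulon concentrate on one regulator's regulon (signed by the edge
#' effect), an activity matrix `A` over reference-compendium and study
#' samples, and the expression matrix `X = M A + E` with additive Gaussian
#' noise `E` of sd `spec$noise_sd`. Each iModulon's raw activity row
#' encodes the underlying (non-negative) regulatory activity with a
#' random, recorded direction: for direction -1 low raw values mean no
#' activity, for +1 high raw values do. Knockout samples carry exactly
#' zero activity of the KO'd regulator's iModulon, i.e. they sit at the
#' no-activity extreme of the row.
#'
#' @param spec A [study_spec()].
#' @param trn Regulon table from [simulate_trn()] under the same spec.
#' @return A list with elements `expression` (genes x samples matrix),
#'   `samples` (sample metadata), `M`, `A`, `annotations` (iModulon,
#'   linked regulator, annotated direction), and `ground_truth`
#'   (`true_directions`, `basal_truth`, `condition_activity`, `noise`,
#'   `imodulon_of`).
#' @export
simulate_expression <- function(spec, trn) {
  stopifnot(inherits(spec, "study_spec"), is.data.frame(trn))
  if (spec$n_imodulons > spec$n_tfs)
    stop("invalid study spec: more iModulons than regulators", call. = FALSE)
  tfs <- tf_names(spec$n_tfs)
  universe <- c(tfs, gene_names(spec$n_genes))
  kos <- vapply(spec$ko_specs, `[[`, character(1), "regulator")
  linked <- c(kos, setdiff(tfs, kos))[seq_len(spec$n_imodulons)]
  ims <- sprintf("iM%02d", seq_len(spec$n_imodulons))

  # sample layout: reference compendium, wildtype controls, per-KO
  # unevolved and evolved-endpoint duplicates
  ref_ids <- sprintf("ref%03d", seq_len(spec$n_reference_samples))
  samples <- data.frame(sample_id = ref_ids, strain = "reference",
                        ko = NA_character_, lineage = NA_character_,
                        stage = "reference", is_reference = TRUE,
                        is_wildtype = FALSE, stringsAsFactors = FALSE)
  add <- function(df, ids, strain, ko, lineage, stage, wt = FALSE) {
    rbind(df, data.frame(sample_id = ids, strain = strain, ko = ko,
                         lineage = lineage, stage = stage,
                         is_reference = FALSE, is_wildtype = wt,
                         stringsAsFactors = FALSE))
  }
  samples <- add(samples, c("wt_r1", "wt_r2"), "wildtype", NA_character_,
                 "A0", "unevolved", wt = TRUE)
  for (ko in kos) {
    samples <- add(samples, paste0(ko, "_A0_r", 1:2), paste0(ko, "_KO"),
                   ko, "A0", "unevolved")
    samples <- add(samples, paste0(ko, "_A1_end_r", 1:2), paste0(ko, "_KO"),
                   ko, "A1", "endpoint")
  }
  n_s <- nrow(samples)

  with_seed(spec$seed + 1L, {
    # gene weights: regulon members only, signed by effect
    M <- matrix(0, length(universe), spec$n_imodulons,
                dimnames = list(universe, ims))
    for (k in seq_len(spec$n_imodulons)) {
      sub <- trn[trn$regulator == linked[k], , drop = FALSE]
      sub <- sub[!duplicated(sub$target), , drop = FALSE]
      if (nrow(sub)) {
        w <- stats::runif(nrow(sub), 0.5, 1.5) *
          ifelse(sub$effect == "repression", -1, 1)
        M[sub$target, k] <- w
      }
    }

    # underlying non-negative activities
    b <- matrix(0, spec$n_imodulons, n_s, dimnames = list(ims, samples$sample_id))
    is_ref <- samples$is_reference
    b[, is_ref] <- stats::rexp(spec$n_imodulons * sum(is_ref),
                               rate = 1 / spec$activity_scale)
    mu <- stats::rexp(spec$n_imodulons, rate = 1 / spec$activity_scale)
    names(mu) <- ims
    for (i in seq_along(kos))
      mu[match(kos[i], linked)] <- spec$ko_specs[[i]]$effect_size
    n_study <- sum(!is_ref)
    b[, !is_ref] <- pmax(0, mu + matrix(stats::rnorm(spec$n_imodulons * n_study,
                                                     sd = 0.5),
                                        spec$n_imodulons))
    # KO samples: the KO'd regulator's iModulon is pinned at no activity
    for (ko in kos) {
      k <- match(ko, linked)
      b[k, !is.na(samples$ko) & samples$ko == ko] <- 0
    }

    directions <- sample(c(-1, 1), spec$n_imodulons, replace = TRUE)
    names(directions) <- ims
    base <- stats::rnorm(spec$n_imodulons, sd = 2)
    A <- base - directions * b          # -1: raw rises with activity
    dimnames(A) <- dimnames(b)

    E <- matrix(stats::rnorm(length(universe) * n_s, sd = spec$noise_sd),
                length(universe), n_s,
                dimnames = list(universe, samples$sample_id))
    X <- M %*% A + E

    list(expression = X, samples = samples, M = M, A = A,
         annotations = data.frame(imodulon = ims, regulator = linked,
                                  annotated_direction = directions,
                                  stringsAsFactors = FALSE),
         ground_truth = list(true_directions = directions, basal_truth = b,
                             condition_activity = mu, noise = E,
                             imodulon_of = stats::setNames(ims, linked)))
  })
}

#' Generate a kinetic phenotyping plate
#'
#' Growth wells follow a logistic opacity curve (random rate and midpoint)
#' on top of a flat baseline; non-growth and negative-control wells are
#' the baseline alone. Noise has two components: a per-well baseline
#' offset (`well_sd`) and per-read noise (`noise_sd`). The true
#' growth/no-growth status of every well is recorded in the `"truth"`
#' attribute.
#'
#' @param pspec A [plate_spec()].
#' @param seed Integer seed.
#' @return A `plate_kinetics` object: list with `wells` (well metadata),
#'   `signal` (wells x timepoints opacity matrix) and `timepoints`
#'   (hours), with the ground-truth call data.frame as attribute `truth`.
#' @export
simulate_plate <- function(pspec = plate_spec(), seed = 1L) {
  stopifnot(inherits(pspec, "plate_spec"))
  if (pspec$n_control_wells < 2)
    stop("invalid plate spec: need at least 2 negative-control wells",
         call. = FALSE)
  n <- pspec$n_wells
  n_ctrl <- pspec$n_control_wells
  tp <- seq(pspec$hours / pspec$n_timepoints, pspec$hours,
            length.out = pspec$n_timepoints)
  with_seed(seed, {
    is_ctrl <- c(rep(TRUE, n_ctrl), rep(FALSE, n - n_ctrl))
    category <- ifelse(is_ctrl, "control",
                       sample(c("C", "N", "S", "P"), n, replace = TRUE,
                              prob = c(0.30, 0.45, 0.10, 0.15)))
    wells <- data.frame(
      well = sprintf("W%03d", seq_len(n)),
      substrate = ifelse(is_ctrl, "negative_control",
                         sprintf("substrate_%03d", cumsum(!is_ctrl))),
      category = category, is_control = is_ctrl, stringsAsFactors = FALSE)
    grown <- !is_ctrl & stats::runif(n) < pspec$growth_fraction &
      pspec$effect > 0
    sig <- matrix(stats::rnorm(n * length(tp), sd = pspec$noise_sd),
                  n, length(tp)) +
      pspec$baseline + stats::rnorm(n, sd = pspec$well_sd)
    if (any(grown)) {
      rate <- stats::runif(n, 0.25, 0.5)
      mid <- stats::runif(n, 12, 28)
      for (i in which(grown))
        sig[i, ] <- sig[i, ] + pspec$effect / (1 + exp(-rate[i] * (tp - mid[i])))
    }
    rownames(sig) <- wells$well
    colnames(sig) <- formatC(tp, format = "g")
    out <- structure(list(wells = wells, signal = sig, timepoints = tp),
                     class = "plate_kinetics")
    attr(out, "truth") <- data.frame(well = wells$well, grown = grown,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' @export
print.plate_kinetics <- function(x, ...) {
  cat(sprintf("Plate kinetics: %d wells (%d negative controls), %d timepoints over %.3g h\n",
              nrow(x$wells), sum(x$wells$is_control), length(x$timepoints),
              max(x$timepoints)))
  invisible(x)
}

# resolve regulon-drawn convergent genes for each KO (seeded, so the
# standalone mutation generator and simulate_study agree)
resolve_convergent <- function(spec, trn) {
  with_seed(spec$seed + 6L, {
    lapply(spec$ko_specs, function(ks) {
      extra <- character()
      if (ks$convergent_in_regulon > 0) {
        targets <- sort(unique(trn$target[trn$regulator == ks$regulator]))
        targets <- setdiff(targets, ks$convergent_genes)
        if (length(targets) < ks$convergent_in_regulon)
          stop("regulator ", ks$regulator,
               " has too few targets for the requested convergent genes",
               call. = FALSE)
        extra <- sample(targets, ks$convergent_in_regulon)
      }
      sort(unique(c(ks$convergent_genes, extra)))
    })
  })
}

#' Generate per-strain mutation tables across evolution lineages
#'
#' For each KO, every lineage receives background mutations drawn without
#' replacement from a shared gene pool (a partition across lineages, so
#' background mutations never converge), while planted convergent genes
#' are mutated in at least two lineages. Each lineage yields a midpoint
#' isolate, an endpoint isolate (frequency 1) and an endpoint population
#' sample whose records are the endpoint isolate's mutations (frequency
#' drawn in (0.5, 1]) plus extra low-frequency subpopulation mutations.
#'
#' @param spec A [study_spec()] with non-empty `ko_specs`.
#' @param trn Regulon table from [simulate_trn()].
#' @return A data.frame with columns `strain`, `ko`, `lineage`, `stage`,
#'   `sample_type`, `gene`, `position`, `allele`, `frequency`; the planted
#'   convergent gene sets are attached as attribute `truth` (named list by
#'   KO regulator).
#' @export
simulate_mutations <- function(spec, trn) {
  stopifnot(inherits(spec, "study_spec"))
  if (!length(spec$ko_specs))
    stop("invalid study spec: ko_specs must be non-empty", call. = FALSE)
  kos <- vapply(spec$ko_specs, `[[`, character(1), "regulator")
  planted <- resolve_convergent(spec, trn)
  names(planted) <- kos
  universe <- c(tf_names(spec$n_tfs), gene_names(spec$n_genes))
  gene_pos <- stats::setNames(seq_along(universe) * 1500L, universe)
  bases <- c("A", "C", "G", "T")

  with_seed(spec$seed + 3L, {
    rows <- list()
    emit <- function(ko, lineage, stage, type, gene, freq) {
      if (!length(gene)) return()
      pos <- gene_pos[gene] + sample.int(1000L, length(gene), replace = TRUE)
      from <- sample(bases, length(gene), replace = TRUE)
      to <- vapply(from, function(x) sample(setdiff(bases, x), 1), "")
      rows[[length(rows) + 1L]] <<- data.frame(
        strain = paste(ko, lineage, sep = "_"), ko = ko, lineage = lineage,
        stage = stage, sample_type = type, gene = gene,
        position = unname(pos), allele = paste0(from, ">", to),
        frequency = freq, stringsAsFactors = FALSE)
    }
    for (i in seq_along(kos)) {
      ko <- kos[i]
      lin_ids <- paste0("A", seq_len(spec$lineages))
      pool <- sample(setdiff(universe, c(ko, unlist(planted))))
      take <- function(k) {
        k <- min(k, length(pool))
        if (k == 0L) return(character())
        out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
      }
      conv_lineages <- lapply(planted[[ko]], function(g) {
        k <- max(2L, stats::rbinom(1, spec$lineages, spec$convergence_rate))
        sample(lin_ids, min(k, spec$lineages))
      })
      for (lin in lin_ids) {
        half <- spec$mutations_per_isolate / 2
        core <- take(stats::rpois(1, half))
        mid_own <- take(stats::rpois(1, half))
        end_own <- take(stats::rpois(1, half))
        mid_genes <- c(core, mid_own)
        end_genes <- c(core, end_own)
        conv_here <- planted[[ko]][vapply(conv_lineages, function(l)
          lin %in% l, logical(1))]
        end_genes <- c(end_genes, conv_here)
        # per-sample records; isolates at frequency 1
        emit(ko, lin, "midpoint", "isolate", mid_genes, rep(1, length(mid_genes)))
        emit(ko, lin, "endpoint", "isolate", end_genes, rep(1, length(end_genes)))
        pop_extra <- take(stats::rpois(1, spec$population_extra_rate))
        emit(ko, lin, "endpoint", "population",
             c(end_genes, pop_extra),
             c(stats::runif(length(end_genes), 0.5, 1),
               stats::runif(length(pop_extra), 0.05, 0.5)))
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(strain = character(), ko = character(), lineage = character(),
                 stage = character(), sample_type = character(),
                 gene = character(), position = integer(),
                 allele = character(), frequency = numeric(),
                 stringsAsFactors = FALSE)
    # population records of a lineage must share keys with its endpoint
    # isolate for the same gene: reuse position/allele of the isolate record
    iso <- tab[tab$sample_type == "isolate" & tab$stage == "endpoint", ]
    key <- paste(tab$strain, tab$gene)
    iso_key <- paste(iso$strain, iso$gene)
    hit <- tab$sample_type == "population" & key %in% iso_key
    m <- match(key[hit], iso_key)
    tab$position[hit] <- iso$position[m]
    tab$allele[hit] <- iso$allele[m]
    rownames(tab) <- NULL
    attr(tab, "truth") <- planted
    tab
  })
}

#' Generate a gene growth-impact table
#'
#' Emulates a genome-wide deletion screen: each gene receives a relative
#' growth-rate defect in `[0, 1]` (0 = deletion has no effect, 1 = no
#' growth). A configurable fraction of genes is high-impact (defect above
#' 0.5).
#'
#' @param trn Regulon table; its gene universe is scored.
#' @param spec A [study_spec()].
#' @return A data.frame with columns `gene`, `defect`.
#' @export
simulate_growth_impacts <- function(trn, spec) {
  stopifnot(inherits(spec, "study_spec"))
  genes <- sort(unique(c(tf_names(spec$n_tfs), gene_names(spec$n_genes),
                         trn$regulator, trn$target)))
  with_seed(spec$seed + 4L, {
    defect <- 0.5 * stats::rbeta(length(genes), 1.5, 4)
    n_hi <- round(spec$high_impact_fraction * length(genes))
    if (n_hi > 0) {
      hi <- sample(seq_along(genes), n_hi)
      defect[hi] <- 0.5 + 0.5 * stats::rbeta(n_hi, 2, 2)
    }
    data.frame(gene = genes, defect = defect, stringsAsFactors = FALSE)
  })
}

#' Generate measured growth rates for wildtype and evolved strains
#'
#' Produces the growth-rate table the classification stage consumes:
#' the wildtype rate, each unevolved KO rate (reduced by the KO's initial
#' defect) and per-lineage endpoint rates. Recovering KOs end within a few
#' percent of the wildtype rate; non-recovering KOs stay well below 95%.
#'
#' @param spec A [study_spec()].
#' @param wildtype_rate Wildtype growth rate (per hour).
#' @return A data.frame with columns `strain`, `ko`, `lineage`, `stage`,
#'   `growth_rate`.
#' @export
simulate_growth_rates <- function(spec, wildtype_rate = 0.85) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(spec$seed + 5L, {
    rows <- list(data.frame(strain = "wildtype", ko = NA_character_,
                            lineage = NA_character_, stage = "unevolved",
                            growth_rate = wildtype_rate,
                            stringsAsFactors = FALSE))
    for (ks in spec$ko_specs) {
      ko <- ks$regulator
      rows[[length(rows) + 1L]] <- data.frame(
        strain = paste0(ko, "_A0"), ko = ko, lineage = "A0",
        stage = "unevolved",
        growth_rate = wildtype_rate * (1 - ks$initial_defect),
        stringsAsFactors = FALSE)
      lin <- paste0("A", seq_len(spec$lineages))
      mult <- if (ks$recovered) stats::runif(spec$lineages, 0.96, 1.02)
              else stats::runif(spec$lineages, 0.70, 0.88)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = paste(ko, lin, sep = "_"), ko = ko, lineage = lin,
        stage = "endpoint", growth_rate = wildtype_rate * mult,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a binary growth-call matrix with a dominant nitrogen factor
#'
#' Strains have a bimodal nitrogen-utilization ability (they either grow
#' on most nitrogen-limited substrates or on few of them), while calls on
#' the remaining conditions are near-constant with a small flip rate. The
#' condition-side generating factor (indicator of nitrogen conditions) is
#' returned for factor-recovery checks against PCA loadings.
#'
#' @param n_strains Number of strains (rows).
#' @param n_nitrogen Number of nitrogen-limited conditions.
#' @param n_other Number of other conditions.
#' @param ability Two-element vector of low/high nitrogen growth
#'   probabilities.
#' @param flip Flip probability for non-nitrogen calls.
#' @param seed Integer seed.
#' @return A list with `calls` (binary strains x conditions matrix),
#'   `conditions` (metadata with `category`), `factor` (generating
#'   condition-side factor) and `ability` (per-strain probability).
#' @export
simulate_call_matrix <- function(n_strains = 12, n_nitrogen = 45,
                                 n_other = 50, ability = c(0.1, 0.9),
                                 flip = 0.03, seed = 1L) {
  stopifnot(n_strains >= 3, n_nitrogen >= 1, n_other >= 1)
  with_seed(seed, {
    ab <- sample(ability, n_strains, replace = TRUE)
    if (length(unique(ab)) == 1L) ab[1] <- setdiff(ability, ab[1])[1]
    callsN <- matrix(stats::rbinom(n_strains * n_nitrogen, 1, rep(ab, n_nitrogen)),
                     n_strains, n_nitrogen)
    callsO <- matrix(stats::rbinom(n_strains * n_other, 1, 1 - flip),
                     n_strains, n_other)
    calls <- cbind(callsN, callsO)
    dimnames(calls) <- list(sprintf("strain%02d", seq_len(n_strains)),
                            c(sprintf("N_%03d", seq_len(n_nitrogen)),
                              sprintf("O_%03d", seq_len(n_other))))
    list(calls = calls,
         conditions = data.frame(condition = colnames(calls),
                                 category = rep(c("N", "C"),
                                                c(n_nitrogen, n_other)),
                                 stringsAsFactors = FALSE),
         factor = c(rep(1, n_nitrogen), rep(0, n_other)),
         ability = ab)
  })
}

#' Generate a complete synthetic knockout-evolution study
#'
#' Runs every generator under the spec's seed and assembles the inputs the
#' pipeline consumes together with the ground truth: true iModulon
#' directions, planted convergent genes, true growth calls per plate and
#' the true adaptation category of each KO (iv if growth does not recover;
#' i if the regulator is inactive on the condition; iii if a convergent
#' mutation was planted in its regulatory network; ii otherwise).
#'
#' @param spec A [study_spec()].
#' @param plates Logical; also simulate one phenotyping plate per strain
#'   (wildtype plus each KO).
#' @return An object of class `synthetic_study`.
#' @export
simulate_study <- function(spec = study_spec(), plates = TRUE) {
  stopifnot(inherits(spec, "study_spec"))
  trn <- simulate_trn(spec)
  expr <- simulate_expression(spec, trn)
  mutations <- simulate_mutations(spec, trn)
  impacts <- simulate_growth_impacts(trn, spec)
  rates <- simulate_growth_rates(spec)
  kos <- vapply(spec$ko_specs, `[[`, character(1), "regulator")
  planted <- attr(mutations, "truth")

  plate_list <- NULL
  plate_truth <- NULL
  if (plates) {
    strains <- c("wildtype", paste0(kos, "_evolved"))
    plate_list <- lapply(seq_along(strains), function(i)
      simulate_plate(spec$plate_spec, seed = spec$seed + 20L + i))
    names(plate_list) <- strains
    plate_truth <- lapply(plate_list, attr, "truth")
  }

  category <- vapply(spec$ko_specs, function(ks) {
    conv <- planted[[ks$regulator]]
    if (!ks$recovered) "iv"
    else if (ks$effect_size == 0) "i"
    else if (length(conv) > 0) "iii"
    else "ii"
  }, character(1))
  names(category) <- kos

  structure(list(
    spec = spec, trn = trn, expression = expr$expression,
    samples = expr$samples, M = expr$M, A = expr$A,
    annotations = expr$annotations, mutations = mutations,
    growth_impacts = impacts, growth_rates = rates, plates = plate_list,
    ground_truth = c(expr$ground_truth,
                     list(true_convergent_genes = planted,
                          true_category = category,
                          true_growth_calls = plate_truth))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic KO-ALE study\n")
  cat(sprintf("  %d regulatory interactions, %d genes x %d samples, %d iModulons\n",
              nrow(x$trn), nrow(x$expression), ncol(x$expression),
              ncol(x$M)))
  cat(sprintf("  KOs (true category): %s\n",
              paste(sprintf("%s (%s)", names(x$ground_truth$true_category),
                            x$ground_truth$true_category), collapse = ", ")))
  cat(sprintf("  %d mutation records, %d plates\n", nrow(x$mutations),
              length(x$plates)))
  invisible(x)
}
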