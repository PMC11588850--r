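#' Specify a synthetic knockout-evolution study
#'
#' A `study_spec` fixes every parameter of the synthetic-data generators:
#' the size and wiring density of the transcriptional regulatory network
#' (TRN), the reference expression compendium, the ICA decomposition, the
#' knockout (KO) strains with their archetypes, the phenotyping plate
#' layout and the mutation model. All generators derive their random
#' streams from the single `seed`, so a fixed spec reproduces every
#' artifact bit-for-bit and each artifact can be regenerated independently.
#'
#' The defaults describe a scaled-down regulator KO-ALE study: a TRN with
#' one hub regulator, a 100-sample reference compendium standing in for a
#' large expression database, four KO strains covering the four adaptation
#' archetypes (inactive regulator; active regulator recovering without
#' specific mutations; active regulator recovering through a convergent
#' regulon mutation; non-recovering hub), six independent evolution
#' lineages per KO, and 106-well kinetic plates (12 negative controls,
#' 94 tested wells).
#'
#' @param n_tfs Number of transcription factors (regulator genes).
#' @param n_genes Number of non-regulator target genes.
#' @param tf_target_density Probability that a given TF regulates a given
#'   target gene.
#' @param tf_tf_density Probability of a regulatory edge for each ordered
#'   TF pair.
#' @param hub_tfs Character vector of TF ids forced to high out-degree
#'   (at least five times the median).
#' @param n_sole_targets Number of target genes reserved to have exactly
#'   one regulator, exercising sole-regulator statistics.
#' @param n_reference_samples Number of reference-compendium samples.
#' @param n_imodulons Number of iModulons; must not exceed `n_tfs`.
#' @param noise_sd Standard deviation of the additive Gaussian expression
#'   noise, in log-expression units.
#' @param activity_scale Mean of the exponential distribution of reference
#'   iModulon activities (arbitrary activity units).
#' @param ko_specs List of [ko_spec()] entries, one per knockout strain.
#' @param plate_spec A [plate_spec()] describing the phenotyping plates.
#' @param lineages Independent evolution lineages per KO.
#' @param mutations_per_isolate Expected background mutations per endpoint
#'   isolate (Poisson mean).
#' @param population_extra_rate Expected extra low-frequency mutations in
#'   an endpoint population sample beyond its clonal isolate.
#' @param convergence_rate Probability that each lineage carries a planted
#'   convergent mutation (at least two lineages always do).
#' @param high_impact_fraction Fraction of genes whose deletion has a
#'   growth-rate defect above 0.5.
#' @param effect_probs Named probabilities for sampling edge effects
#'   (`activation`, `repression`, `dual`).
#' @param seed Integer seed; all generator streams derive from it.
#'
#' @return An object of class `study_spec` (a validated list).
#' @seealso [ko_spec()], [plate_spec()], [simulate_study()]
#' @export
study_spec <- function(n_tfs = 20,
                       n_genes = 180,
                       tf_target_density = 0.04,
                       tf_tf_density = 0.08,
                       hub_tfs = "tf01",
                       n_sole_targets = 10,
                       n_reference_samples = 100,
                       n_imodulons = 12,
                       noise_sd = 0.25,
                       activity_scale = 5,
                       ko_specs = default_ko_specs(),
                       plate_spec = trnadapt::plate_spec(),
                       lineages = 6,
                       mutations_per_isolate = 7.3,
                       population_extra_rate = 4.78,
                       convergence_rate = 0.8,
                       high_impact_fraction = 0.1,
                       effect_probs = c(activation = 0.55, repression = 0.4,
                                        dual = 0.05),
                       seed = 42L) {
  spec <- list(
    n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
    tf_target_density = tf_target_density, tf_tf_density = tf_tf_density,
    hub_tfs = as.character(hub_tfs), n_sole_targets = as.integer(n_sole_targets),
    n_reference_samples = as.integer(n_reference_samples),
    n_imodulons = as.integer(n_imodulons), noise_sd = noise_sd,
    activity_scale = activity_scale, ko_specs = ko_specs,
    plate_spec = plate_spec, lineages = as.integer(lineages),
    mutations_per_isolate = mutations_per_isolate,
    population_extra_rate = population_extra_rate,
    convergence_rate = convergence_rate,
    high_impact_fraction = high_impact_fraction,
    effect_probs = effect_probs,
    seed = as.integer(seed)
  )
  class(spec) <- "study_spec"
  validate_study_spec(spec)
  spec
}

#' Describe one knockout strain in a synthetic study
#'
#' @param regulator TF id (must exist in the generated TRN).
#' @param effect_size Wildtype-condition basal activity of the regulator's
#'   linked iModulon; 0 means the regulator is inactive on the growth
#'   condition (category-i archetype).
#' @param recovered Logical; whether the evolved lineages recover growth
#'   (at least 95% of the wildtype rate at endpoint).
#' @param convergent_genes Explicit gene ids planted as convergent
#'   mutations across lineages of this KO.
#' @param convergent_in_regulon Number of additional convergent genes to
#'   pick from the regulator's own regulon at generation time.
#' @param initial_defect Relative growth defect of the unevolved KO.
#'
#' @return An object of class `ko_spec`.
#' @export
ko_spec <- function(regulator, effect_size = 8, recovered = TRUE,
                    convergent_genes = character(),
                    convergent_in_regulon = 0L,
                    initial_defect = 0.4) {
  stopifnot(is.character(regulator), length(regulator) == 1L,
            length(effect_size) == 1L, effect_size >= 0,
            is.logical(recovered),
            initial_defect >= 0, initial_defect <= 1)
  structure(list(regulator = regulator, effect_size = effect_size,
                 recovered = isTRUE(recovered),
                 convergent_genes = as.character(convergent_genes),
                 convergent_in_regulon = as.integer(convergent_in_regulon),
                 initial_defect = initial_defect),
            class = "ko_spec")
}

#' The four knockout archetypes
#'
#' Default KO set covering the four adaptation categories: an inactive
#' regulator (i), an active regulator recovering without specific
#' mutations (ii), an active regulator recovering through a convergent
#' mutation inside its own regulon (iii), and a non-recovering hub (iv).
#'
#' @return A list of four [ko_spec()] objects.
#' @export
default_ko_specs <- function() {
  list(
    ko_spec("tf02", effect_size = 0, recovered = TRUE),
    ko_spec("tf03", effect_size = 8, recovered = TRUE),
    ko_spec("tf04", effect_size = 8, recovered = TRUE,
            convergent_in_regulon = 1L),
    ko_spec("tf01", effect_size = 8, recovered = FALSE)
  )
}

#' Describe a synthetic kinetic phenotyping plate
#'
#' Defaults model a 48-h OmniLog-style run read every 15 minutes:
#' 12 negative-control wells and 94 tested wells, a flat baseline of 30
#' opacity units with well-to-well baseline scatter (sd 2) and per-read
#' noise (sd 2), and a logistic respiration curve of amplitude `effect`
#' in growing wells.
#'
#' @param n_wells Total wells on the plate.
#' @param n_control_wells Negative-control wells; at least 2.
#' @param n_timepoints Number of opacity readings.
#' @param hours Total run length in hours.
#' @param effect Logistic amplitude of a growth well above baseline
#'   (opacity units); 0 gives a null plate.
#' @param noise_sd Per-timepoint read noise sd (opacity units).
#' @param well_sd Well-to-well baseline sd (opacity units).
#' @param baseline Mean baseline opacity.
#' @param growth_fraction Probability that a tested well truly grows.
#'
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(n_wells = 106, n_control_wells = 12,
                       n_timepoints = 192, hours = 48,
                       effect = 150, noise_sd = 2, well_sd = 2,
                       baseline = 30, growth_fraction = 0.5) {
  if (n_control_wells < 2)
    stop("invalid plate spec: need at least 2 negative-control wells",
         call. = FALSE)
  if (n_wells <= n_control_wells)
    stop("invalid plate spec: n_wells must exceed n_control_wells",
         call. = FALSE)
  if (n_timepoints < 2 || hours <= 0 || noise_sd < 0 || well_sd < 0 ||
      growth_fraction < 0 || growth_fraction > 1)
    stop("invalid plate spec", call. = FALSE)
  structure(list(n_wells = as.integer(n_wells),
                 n_control_wells = as.integer(n_control_wells),
                 n_timepoints = as.integer(n_timepoints), hours = hours,
                 effect = effect, noise_sd = noise_sd, well_sd = well_sd,
                 baseline = baseline, growth_fraction = growth_fraction),
            class = "plate_spec")
}

validate_study_spec <- function(spec) {
  with(spec, {
    if (n_tfs < 1L || n_genes < 1L || n_reference_samples < 1L ||
        n_imodulons < 1L || lineages < 1L)
      stop("invalid study spec: all counts must be positive", call. = FALSE)
    if (n_tfs > n_genes)
      stop("invalid study spec: more regulators than target genes",
           call. = FALSE)
    if (n_imodulons > n_tfs)
      stop("invalid study spec: more iModulons than regulators",
           call. = FALSE)
    for (d in c(tf_target_density, tf_tf_density))
      if (d < 0 || d > 1)
        stop("invalid study spec: densities must lie in [0, 1]",
             call. = FALSE)
    if (noise_sd < 0 || activity_scale <= 0)
      stop("invalid study spec: noise_sd must be >= 0 and activity_scale > 0",
           call. = FALSE)
    if (convergence_rate < 0 || convergence_rate > 1 ||
        high_impact_fraction < 0 || high_impact_fraction > 1)
      stop("invalid study spec: rates must lie in [0, 1]", call. = FALSE)
    if (n_sole_targets > n_genes)
      stop("invalid study spec: n_sole_targets exceeds n_genes",
           call. = FALSE)
    if (!all(c("activation", "repression", "dual") %in% names(effect_probs)) ||
        any(effect_probs < 0))
      stop("invalid study spec: effect_probs must name activation, repression, dual",
           call. = FALSE)
  })
  if (!all(vapply(spec$ko_specs, inherits, logical(1), "ko_spec")))
    stop("invalid study spec: ko_specs must be a list of ko_spec objects",
         call. = FALSE)
  tf_ids <- tf_names(spec$n_tfs)
  kos <- vapply(spec$ko_specs, `[[`, character(1), "regulator")
  if (anyDuplicated(kos))
    stop("invalid study spec: duplicate KO regulators", call. = FALSE)
  if (!all(kos %in% tf_ids))
    stop("invalid study spec: KO regulators must be TF ids (tf01, tf02, ...)",
         call. = FALSE)
  if (length(kos) > spec$n_imodulons)
    stop("invalid study spec: need one iModulon per KO regulator",
         call. = FALSE)
  invisible(spec)
}

tf_names <- function(n) sprintf("tf%02d", seq_len(n))
gene_names <- function(n) sprintf("g%03d", seq_len(n))

# Run code under a derived seed, restoring the caller's RNG state.
# Offsets stay tiny so derived seeds remain valid 32-bit integers.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' @export
print.study_spec <- function(x, ...) {
  cat("Synthetic KO-ALE study spec\n")
  cat(sprintf("  TRN: %d TFs, %d target genes (hub: %s)\n",
              x$n_tfs, x$n_genes, paste(x$hub_tfs, collapse = ", ")))
  cat(sprintf("  Expression: %d iModulons, %d reference samples, noise sd %.3g\n",
              x$n_imodulons, x$n_reference_samples, x$noise_sd))
  cat(sprintf("  KOs: %s\n",
              paste(vapply(x$ko_specs, `[[`, character(1), "regulator"),
                    collapse = ", ")))
  cat(sprintf("  Plate: %d wells (%d controls), %d timepoints\n",
              x$plate_spec$n_wells, x$plate_spec$n_control_wells,
              x$plate_spec$n_timepoints))
  cat(sprintf("  Seed: %d\n", x$seed))
  invisible(x)
}
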