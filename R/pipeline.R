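#' Configure a knockout-adaptation study run
#'
#' A study config either embeds a simulation spec (`simulation`) or names
#' input files for each stage. Thresholds default to the pipeline-wide
#' values: a 20% KO growth-defect cut for selection, plate alpha 0.05,
#' iModulon match correlation 0.6, minimum 2 lineages for convergence,
#' an activity threshold at 10% of the reference basal maximum, and a
#' recovery threshold at 95% of the wildtype growth rate.
#'
#' @param path YAML file to read, or `NULL` to build from arguments.
#' @param simulation A [study_spec()] (or a list of its arguments) for a
#'   simulation-backed run.
#' @param inputs Named list of file paths (`regulon`, `expression`, `m`,
#'   `a`, `annotations`, `samples`, `mutations`, `growth_impacts`,
#'   `growth_rates`, `plates` (vector)).
#' @param stages Stages to run, a subset of
#'   `c("network", "basal", "selection", "plates", "mutations", "classify")`.
#' @param thresholds Named list overriding `defect`, `alpha`, `match_r`,
#'   `min_lineages`, `activity_fraction`, `recovery`, `lfc`,
#'   `delta_activity`.
#' @param partners Named list: for each KO regulator, extra gene labels
#'   (e.g. post-transcriptional partners) counting as regulator-specific
#'   convergence targets.
#' @param seed Integer seed for any stage randomness.
#' @return An object of class `study_config`.
#' @export
study_config <- function(path = NULL, simulation = NULL, inputs = NULL,
                         stages = c("network", "basal", "selection",
                                    "plates", "mutations", "classify"),
                         thresholds = list(), partners = list(),
                         seed = 1L) {
  defaults <- list(defect = 0.20, alpha = 0.05, match_r = 0.6,
                   min_lineages = 2, activity_fraction = 0.10,
                   recovery = 0.95, lfc = 1, delta_activity = 5)
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    known <- c("simulation", "inputs", "stages", "thresholds", "partners",
               "seed")
    bad <- setdiff(names(raw), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
    simulation <- raw$simulation
    inputs <- raw$inputs
    if (!is.null(raw$stages)) stages <- raw$stages
    thresholds <- utils::modifyList(thresholds, as.list(raw$thresholds))
    partners <- if (is.null(raw$partners)) partners else raw$partners
    if (!is.null(raw$seed)) seed <- raw$seed
  }
  bad <- setdiff(names(thresholds), names(defaults))
  if (length(bad))
    stop("unknown threshold keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  th <- utils::modifyList(defaults, thresholds)
  for (nm in names(th))
    if (!is.numeric(th[[nm]]) || th[[nm]] < 0)
      stop("threshold '", nm, "' out of range", call. = FALSE)
  if (th$alpha > 1 || th$defect > 1 || th$match_r > 1 ||
      th$activity_fraction > 1)
    stop("fractional thresholds must lie in [0, 1]", call. = FALSE)
  if (!is.null(simulation) && !inherits(simulation, "study_spec"))
    simulation <- do.call(study_spec, simulation)
  stages <- match.arg(stages, c("network", "basal", "selection", "plates",
                                "mutations", "classify"),
                      several.ok = TRUE)
  structure(list(simulation = simulation, inputs = inputs, stages = stages,
                 thresholds = th, partners = partners,
                 seed = as.integer(seed)),
            class = "study_config")
}

load_study_inputs <- function(config) {
  if (!is.null(config$simulation))
    return(simulate_study(config$simulation,
                          plates = "plates" %in% config$stages))
  ins <- config$inputs
  need_input <- function(key, stage) {
    if (is.null(ins[[key]]))
      stop("stage '", stage, "' needs input '", key, "'", call. = FALSE)
    ins[[key]]
  }
  study <- list()
  if (any(c("network", "selection", "mutations", "classify", "basal") %in%
          config$stages))
    study$trn <- read_regulon(need_input("regulon", "network"))
  if (any(c("basal", "classify") %in% config$stages)) {
    dec <- read_decomposition(need_input("m", "basal"),
                              need_input("a", "basal"),
                              ins$annotations, need_input("samples", "basal"))
    study$M <- dec$M; study$A <- dec$A
    study$annotations <- dec$annotations
    study$samples <- dec$samples
  }
  if (!is.null(ins$expression))
    study$expression <- read_expression(ins$expression)
  if (any(c("mutations", "classify") %in% config$stages))
    study$mutations <- read_mutations(need_input("mutations", "mutations"))
  if ("selection" %in% config$stages)
    study$growth_impacts <- read_growth_impacts(
      need_input("growth_impacts", "selection"))
  if ("classify" %in% config$stages)
    study$growth_rates <- utils::read.csv(
      need_input("growth_rates", "classify"), stringsAsFactors = FALSE)
  if ("plates" %in% config$stages) {
    paths <- need_input("plates", "plates")
    study$plates <- lapply(paths, read_plate)
    names(study$plates) <- if (!is.null(names(paths))) names(paths)
      else tools::file_path_sans_ext(basename(unlist(paths)))
  }
  study
}

#' Run the knockout-adaptation study pipeline
#'
#' Executes the configured stages on simulated or file-backed inputs:
#' TF-graph network statistics, the basal iModulon transformation,
#' regulator selection scores, plate growth calls, convergent-mutation
#' detection, and the four-category classification of every KO. Results
#' are returned as a `study_report` (and written as CSVs plus a JSON
#' report when `out_dir` is given). Given a fixed config the report is
#' byte-identical across runs.
#'
#' @param config A [study_config()] (or a YAML path).
#' @param out_dir Optional output directory.
#' @return A `study_report` list with elements per stage plus
#'   `classification`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- study_config(path = config)
  stopifnot(inherits(config, "study_config"))
  th <- config$thresholds
  study <- load_study_inputs(config)
  report <- list(seed = config$seed, stages = config$stages,
                 thresholds = th)

  if ("network" %in% config$stages) {
    g <- build_tf_graph(study$trn)
    n <- igraph::vcount(g)
    stats_df <- data.frame(regulator = igraph::V(g)$name,
                           stringsAsFactors = FALSE)
    stats_df$betweenness <- if (n >= 3) unname(tf_betweenness(g)) else NA_real_
    sole <- sole_regulator_counts(study$trn)
    stats_df$sole_regulator_targets <-
      as.integer(sole[stats_df$regulator])
    stats_df$regulon_size <- vapply(stats_df$regulator, function(tf)
      regulon_size(study$trn, tf), integer(1))
    stats_df$subnetwork_skewness <- vapply(stats_df$regulator, function(tf) {
      if (regulon_size(study$trn, tf) < 3) return(NA_real_)
      suppressWarnings(regulon_subnetwork_skewness(study$trn, tf))
    }, numeric(1))
    report$network <- list(
      n_regulators = n,
      component_fraction = component_fraction(g),
      pair_connectivity = if (n >= 2) pair_connectivity(g) else NA_real_,
      per_regulator = stats_df)
  }

  kos <- if (!is.null(study$samples))
    sort(unique(stats::na.omit(study$samples$ko))) else character()

  basal <- NULL
  if (any(c("basal", "classify") %in% config$stages) && !is.null(study$A)) {
    ref_ids <- study$samples$sample_id[study$samples$is_reference]
    ann <- study$annotations
    directions <- stats::setNames(numeric(nrow(ann)), ann$imodulon)
    for (k in ann$imodulon) {
      reg <- ann$regulator[ann$imodulon == k]
      ko_ids <- study$samples$sample_id[!is.na(study$samples$ko) &
                                          study$samples$ko == reg &
                                          study$samples$stage == "unevolved"]
      annotated <- if ("annotated_direction" %in% names(ann))
        ann$annotated_direction[ann$imodulon == k] else NULL
      directions[k] <- assign_direction(study$A[k, ], ref_ids,
                                        ko_sample_ids = ko_ids,
                                        annotated_direction = annotated)
    }
    basal <- basal_transform(study$M, study$A, directions, ref_ids)
    ref_basal <- basal$A[, ref_ids, drop = FALSE]
    report$basal <- list(
      directions = as.list(directions),
      offsets = as.list(basal$offsets),
      reference_negative_fraction = as.list(rowMeans(ref_basal < 0)),
      reference_basal_max = as.list(apply(ref_basal, 1, max)))
  }

  if ("selection" %in% config$stages) {
    tfs <- sort(unique(study$trn$regulator))
    scores <- vapply(tfs, function(tf)
      tryCatch(as.numeric(impact_score(study$trn, study$growth_impacts, tf)),
               error = function(e) NA_real_), numeric(1))
    ok <- !is.na(scores)
    z <- rep(NA_real_, length(tfs))
    if (sum(ok) >= 3 && stats::sd(scores[ok]) > 0)
      z[ok] <- impact_zscores(scores[ok])
    report$selection <- data.frame(
      regulator = tfs,
      regulon_size = vapply(tfs, function(tf) regulon_size(study$trn, tf),
                            integer(1)),
      impact_score = unname(scores), impact_zscore = unname(z),
      stringsAsFactors = FALSE)
  }

  if ("plates" %in% config$stages && !is.null(study$plates)) {
    calls <- lapply(study$plates, growth_calls, alpha = th$alpha)
    report$plates <- list(calls = calls)
    mats <- lapply(calls, function(df) {
      tested <- df[!df$is_control, ]
      stats::setNames(tested$call, tested$substrate)
    })
    shared <- Reduce(intersect, lapply(mats, names))
    if (length(mats) >= 3 && length(shared) >= 2) {
      mat <- do.call(rbind, lapply(mats, `[`, shared))
      rownames(mat) <- names(mats)
      vr <- apply(mat, 2, stats::var)
      if (sum(vr > 0) >= 2) {
        pc <- suppressWarnings(pca_binary(mat))
        report$plates$pca_variance_fraction <- pc$variance_fraction
        report$plates$pca_scores <- pc$scores[, seq_len(min(2, ncol(pc$scores))),
                                              drop = FALSE]
      }
      cats <- study$plates[[1]]$wells
      cats <- stats::setNames(cats$category, cats$substrate)
      if ("wildtype" %in% names(mats)) {
        report$plates$vs_wildtype <- lapply(
          mats[setdiff(names(mats), "wildtype")], function(m)
            compare_calls(mats$wildtype, m, categories = cats))
      }
    }
  }

  if (any(c("mutations", "classify") %in% config$stages) &&
      !is.null(study$mutations)) {
    mut_kos <- sort(unique(study$mutations$ko))
    report$mutations <- list(
      convergent = lapply(stats::setNames(nm = mut_kos), function(ko)
        convergent_mutations(study$mutations, ko,
                             min_lineages = th$min_lineages)),
      summary = mutation_summary(study$mutations)["mean_per_isolate"])
  }

  if ("classify" %in% config$stages) {
    if (is.null(basal) || is.null(study$mutations) ||
        is.null(study$growth_rates))
      stop("stage 'classify' needs decomposition, mutation and growth-rate inputs",
           call. = FALSE)
    wt_rate <- study$growth_rates$growth_rate[
      study$growth_rates$strain == "wildtype"][1]
    wt_ids <- study$samples$sample_id[study$samples$is_wildtype]
    ann <- study$annotations
    rows <- lapply(kos, function(ko) {
      k <- ann$imodulon[ann$regulator == ko]
      if (!length(k))
        stop("stage 'classify': no iModulon annotated for regulator '",
             ko, "'", call. = FALSE)
      k <- k[1]
      basal_wt <- mean(basal$A[k, wt_ids])
      thr <- th$activity_fraction *
        max(basal$A[k, basal$reference_ids])
      regulon <- unique(study$trn$target[study$trn$regulator == ko])
      # regulators of iModulons whose member genes overlap the regulon
      overlapping <- unlist(lapply(ann$imodulon, function(kk) {
        mg <- suppressWarnings(member_genes(basal$M, kk))
        if (length(intersect(mg, regulon))) ann$regulator[ann$imodulon == kk]
        else character()
      }))
      specific_set <- unique(c(regulon, overlapping,
                               unlist(config$partners[[ko]])))
      conv <- convergent_mutations(study$mutations, ko,
                                   min_lineages = th$min_lineages,
                                   gene_set = specific_set)
      end_rates <- study$growth_rates$growth_rate[
        study$growth_rates$ko == ko &
          study$growth_rates$stage == "endpoint"]
      recovered <- mean(end_rates) >= th$recovery * wt_rate
      data.frame(ko = ko, imodulon = k, basal_wt_activity = basal_wt,
                 activity_threshold = thr,
                 regulator_specific_convergence = nrow(conv) > 0,
                 convergent_genes = paste(conv$gene, collapse = ";"),
                 growth_recovered = recovered,
                 category = classify_ko(basal_wt, thr, nrow(conv) > 0,
                                        recovered),
                 stringsAsFactors = FALSE)
    })
    report$classification <- do.call(rbind, rows)
  }

  class(report) <- "study_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$network))
    utils::write.csv(report$network$per_regulator,
                     file.path(out_dir, "network_statistics.csv"),
                     row.names = FALSE)
  if (!is.null(report$selection))
    utils::write.csv(report$selection,
                     file.path(out_dir, "selection_records.csv"),
                     row.names = FALSE)
  if (!is.null(report$classification))
    utils::write.csv(report$classification,
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
  if (!is.null(report$plates))
    for (nm in names(report$plates$calls))
      utils::write.csv(report$plates$calls[[nm]],
                       file.path(out_dir, paste0("calls_", nm, ".csv")),
                       row.names = FALSE)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("KO-adaptation study report\n")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$network))
    cat(sprintf("  network: %d regulators, component fraction %.3f, pair connectivity %.3f\n",
                x$network$n_regulators, x$network$component_fraction,
                x$network$pair_connectivity))
  if (!is.null(x$classification)) {
    cat("  classification:\n")
    for (i in seq_len(nrow(x$classification)))
      cat(sprintf("    %s: category %s (basal %.2f vs threshold %.2f; convergence %s; recovered %s)\n",
                  x$classification$ko[i], x$classification$category[i],
                  x$classification$basal_wt_activity[i],
                  x$classification$activity_threshold[i],
                  x$classification$regulator_specific_convergence[i],
                  x$classification$growth_recovered[i]))
  }
  invisible(x)
}
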