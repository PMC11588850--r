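#' Growth-impact score of a regulator
#'
#' The combined deletion growth-rate defect of all genes the regulator
#' represses minus the combined defect of all genes it activates: a large
#' positive score marks a TF holding back growth-important genes, a large
#' negative score one sustaining them. Dual-effect targets are excluded
#' (set `dual = "both"` to count them in both sums, which cancels).
#' Targets without an impact value are skipped; their count is attached
#' as attribute `n_missing`.
#'
#' @param regulon Regulon data.frame.
#' @param impacts Data.frame with columns `gene`, `defect` (relative
#'   growth-rate defect of the gene's deletion).
#' @param tf Regulator id; must have at least one scored target.
#' @param dual `"exclude"` (default) or `"both"`.
#' @return Numeric score with attribute `n_missing`.
#' @export
impact_score <- function(regulon, impacts, tf, dual = c("exclude", "both")) {
  dual <- match.arg(dual)
  sub <- unique(regulon[regulon$regulator == tf, c("target", "effect")])
  if (!nrow(sub)) stop("regulator '", tf, "' has no targets", call. = FALSE)
  w <- impacts$defect[match(sub$target, impacts$gene)]
  missing <- is.na(w)
  sub <- sub[!missing, , drop = FALSE]
  w <- w[!missing]
  rep_w <- sub$effect == "repression"
  act_w <- sub$effect == "activation"
  if (dual == "both") {
    rep_w <- rep_w | sub$effect == "dual"
    act_w <- act_w | sub$effect == "dual"
  }
  if (!any(rep_w | act_w))
    stop("regulator '", tf, "' has no scored targets", call. = FALSE)
  structure(sum(w[rep_w]) - sum(w[act_w]), n_missing = sum(missing))
}

#' Z-scores of regulator impact scores
#'
#' Standardizes the distribution of totaled impact scores across
#' regulators, using the n-1 standard deviation.
#'
#' @param scores Named numeric vector of at least 3 scores.
#' @return Named numeric vector of z-scores (mean 0, sd 1).
#' @export
impact_zscores <- function(scores) {
  if (length(scores) < 3)
    stop("need at least 3 regulator scores", call. = FALSE)
  s <- stats::sd(scores)
  if (s == 0) stop("impact scores have zero variance", call. = FALSE)
  (scores - mean(scores)) / s
}

#' Select knockout candidates by initial growth defect
#'
#' Keeps records whose measured KO growth defect meets the threshold
#' (default 20%), sorted by defect descending. Row order of the input is
#' irrelevant.
#'
#' @param records Data.frame with at least columns `regulator` and
#'   `ko_growth_defect` (fraction).
#' @param defect_threshold Minimum defect (default 0.20).
#' @return The selected rows, sorted by defect descending (ties broken by
#'   regulator id for determinism).
#' @export
select_candidates <- function(records, defect_threshold = 0.20) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  sel <- records[records$ko_growth_defect >= defect_threshold, , drop = FALSE]
  sel <- sel[order(-sel$ko_growth_defect, sel$regulator), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Classify a knockout strain into the four adaptation categories
#'
#' Category iv: growth did not recover. Category i: growth recovered and
#' the regulator was inactive on the growth condition (wildtype basal
#' activity of its iModulon below the activity threshold). Category iii:
#' growth recovered, the regulator was active, and a convergent mutation
#' hit its regulatory network. Category ii: growth recovered, the
#' regulator was active, and recovery used no regulator-specific
#' mutations.
#'
#' @param basal_wt_activity Wildtype basal activity of the KO'd
#'   regulator's iModulon on the growth condition.
#' @param activity_threshold Activity below which the regulator counts as
#'   inactive (the pipeline default is 10% of the iModulon's reference
#'   basal-activity maximum).
#' @param has_regulator_specific_convergence Logical; a convergent
#'   mutation in the regulator's regulon, in a regulator of an
#'   overlapping iModulon, or in a configured post-transcriptional
#'   partner.
#' @param growth_recovered Logical; evolved endpoint growth rate reached
#'   the recovery threshold relative to wildtype.
#' @return One of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @export
classify_ko <- function(basal_wt_activity, activity_threshold,
                        has_regulator_specific_convergence,
                        growth_recovered) {
  stopifnot(is.finite(basal_wt_activity), is.finite(activity_threshold),
            is.logical(has_regulator_specific_convergence),
            is.logical(growth_recovered))
  if (!growth_recovered) return("iv")
  if (basal_wt_activity < activity_threshold) return("i")
  if (has_regulator_specific_convergence) return("iii")
  "ii"
}

#' Read or write a growth-impact table
#'
#' CSV dialect `gene,defect`; `col_map` adapts files with other column
#' names or sign conventions (a rate-ratio column `r` converts to a
#' defect via `1 - r` with `transform = "one_minus"`).
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping file columns
#'   onto `gene` and `defect`.
#' @param transform `"none"` or `"one_minus"`.
#' @return A data.frame with columns `gene`, `defect`.
#' @export
read_growth_impacts <- function(path, col_map = NULL,
                                transform = c("none", "one_minus")) {
  transform <- match.arg(transform)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (nm in names(col_map))
      names(df)[names(df) == col_map[[nm]]] <- nm
  if (!all(c("gene", "defect") %in% names(df)))
    stop("growth-impact table needs columns gene, defect", call. = FALSE)
  if (transform == "one_minus") df$defect <- 1 - df$defect
  df[c("gene", "defect")]
}

#' @param impacts Growth-impact data.frame.
#' @rdname read_growth_impacts
#' @export
write_growth_impacts <- function(impacts, path) {
  utils::write.csv(impacts[c("gene", "defect")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
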