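#' Member genes of an iModulon
#'
#' Genes whose absolute gene weight in the `M` column exceeds the
#' threshold rule. The default rule is mean + 2 sd of the absolute
#' weights of that column, the usual heavy-tail cut for ICA components.
#'
#' @param M Genes x iModulons weight matrix with rownames.
#' @param imodulon Column name or index.
#' @param threshold Either a function of the absolute-weight vector
#'   returning a cutoff, or a numeric cutoff.
#' @return Character vector of member gene ids (empty, with a warning,
#'   for an all-zero column).
#' @export
member_genes <- function(M, imodulon,
                         threshold = function(w) mean(w) + 2 * stats::sd(w)) {
  w <- abs(M[, imodulon])
  if (all(w == 0)) {
    warning("iModulon ", imodulon, " has an all-zero weight column")
    return(character())
  }
  cut <- if (is.function(threshold)) threshold(w) else threshold
  rownames(M)[w > cut]
}

#' Variance of a gene set explained by one iModulon
#'
#' R-squared of the rank-one reconstruction `M[, k] A[k, ]` restricted to
#' the gene set, with every gene row centered across samples before both
#' the residual and the total sum of squares:
#' `R2 = 1 - ||Xc - Rc||_F^2 / ||Xc||_F^2`. Values can be negative when
#' the component fits worse than the per-gene mean.
#'
#' @param X Genes x samples expression matrix.
#' @param M,A Decomposition matrices.
#' @param imodulon iModulon name or index.
#' @param gene_set Non-empty subset of `rownames(X)`.
#' @return R-squared (<= 1).
#' @export
explained_variance <- function(X, M, A, imodulon, gene_set) {
  if (!length(gene_set)) stop("gene_set is empty", call. = FALSE)
  if (!all(gene_set %in% rownames(X)))
    stop("gene_set contains genes absent from the expression matrix",
         call. = FALSE)
  Xg <- X[gene_set, , drop = FALSE]
  R <- M[gene_set, imodulon, drop = FALSE] %*% A[imodulon, , drop = FALSE]
  Xc <- Xg - rowMeans(Xg)
  Rc <- R - rowMeans(R)
  tot <- sum(Xc^2)
  if (tot == 0) stop("gene set has zero variance", call. = FALSE)
  1 - sum((Xc - Rc)^2) / tot
}

#' Assign an iModulon's activity direction
#'
#' The direction fixes which end of a raw activity row means "no
#' regulatory activity". When knockout samples of the linked regulator
#' are available they anchor the no-activity end empirically: if the mean
#' KO raw activity exceeds the median reference raw activity the
#' no-activity end is the high end (direction +1), otherwise the low end
#' (direction -1). Exact ties resolve to -1 with a warning. Without KO
#' samples the annotated direction (from the regulator's known function)
#' is required and returned as-is.
#'
#' @param a_row Raw activity values, named by sample id.
#' @param reference_ids Non-empty reference sample ids.
#' @param ko_sample_ids Sample ids of knockouts of the linked regulator.
#' @param annotated_direction Fallback direction, +1 or -1.
#' @return +1 or -1.
#' @export
assign_direction <- function(a_row, reference_ids, ko_sample_ids = NULL,
                             annotated_direction = NULL) {
  if (!length(reference_ids))
    stop("reference_ids must be non-empty", call. = FALSE)
  if (length(ko_sample_ids)) {
    ko_mean <- mean(a_row[ko_sample_ids])
    ref_med <- stats::median(a_row[reference_ids])
    if (ko_mean == ref_med) {
      warning("KO activity exactly at the reference median; direction set to -1")
      return(-1)
    }
    return(if (ko_mean > ref_med) +1 else -1)
  }
  if (is.null(annotated_direction))
    stop("need KO samples or an annotated direction", call. = FALSE)
  if (!annotated_direction %in% c(-1, 1))
    stop("annotated_direction must be +1 or -1", call. = FALSE)
  annotated_direction
}

#' Basal activity transformation
#'
#' Rescales every raw activity row so that larger values mean more
#' regulatory activity and the no-activity level sits at approximately
#' zero. For a direction -1 iModulon the 5th quantile of the raw activity
#' over the reference samples is subtracted. For a direction +1 iModulon
#' the 95th quantile is used and the row is then sign-flipped
#' (`A' = q95 - A`), with the matching `M` column negated to keep the
#' reconstruction `M A` sign-consistent. Quantiles use linear
#' interpolation between order statistics; using outlier-robust quantiles
#' rather than the row extremes keeps single outliers from shifting the
#' baseline. By construction at most 5% of reference samples (plus one
#' order statistic) fall below zero.
#'
#' @param M,A Decomposition matrices (`A` rows named by iModulon, columns
#'   by sample).
#' @param directions Named vector of +1/-1 covering every iModulon.
#' @param reference_ids Reference sample ids over which quantile offsets
#'   are computed (a warning is given below 20 samples, where the
#'   quantiles are unstable).
#' @return An object of class `basal_activity`: list with the transformed
#'   `A`, the direction-corrected `M`, `directions`, `offsets` and
#'   `reference_ids`.
#' @seealso [basal_invert()] for the exact inverse.
#' @export
basal_transform <- function(M, A, directions, reference_ids) {
  ims <- rownames(A)
  if (is.null(ims)) stop("A must have iModulon rownames", call. = FALSE)
  if (!all(ims %in% names(directions)))
    stop("directions must cover every iModulon", call. = FALSE)
  if (!length(reference_ids) || !all(reference_ids %in% colnames(A)))
    stop("reference_ids must be non-empty columns of A", call. = FALSE)
  if (length(reference_ids) < 20)
    warning("fewer than 20 reference samples; quantile offsets are unstable")
  dirs <- directions[ims]
  offsets <- stats::setNames(numeric(length(ims)), ims)
  A2 <- A
  M2 <- M
  for (k in ims) {
    ref <- A[k, reference_ids]
    if (dirs[[k]] == -1) {
      offsets[[k]] <- stats::quantile(ref, 0.05, names = FALSE, type = 7)
      A2[k, ] <- A[k, ] - offsets[[k]]
    } else {
      offsets[[k]] <- stats::quantile(ref, 0.95, names = FALSE, type = 7)
      A2[k, ] <- offsets[[k]] - A[k, ]
      M2[, k] <- -M[, k]
    }
  }
  structure(list(A = A2, M = M2, directions = dirs, offsets = offsets,
                 reference_ids = reference_ids),
            class = "basal_activity")
}

#' Invert a basal activity transformation
#'
#' Reconstructs the raw decomposition exactly from the stored directions
#' and offsets.
#'
#' @param basal A `basal_activity` object.
#' @return List with the original `M` and `A`.
#' @export
basal_invert <- function(basal) {
  stopifnot(inherits(basal, "basal_activity"))
  A <- basal$A
  M <- basal$M
  for (k in rownames(A)) {
    if (basal$directions[[k]] == -1) {
      A[k, ] <- A[k, ] + basal$offsets[[k]]
    } else {
      A[k, ] <- basal$offsets[[k]] - A[k, ]
      M[, k] <- -M[, k]
    }
  }
  list(M = M, A = A)
}

#' @export
print.basal_activity <- function(x, ...) {
  neg <- rowMeans(x$A[, x$reference_ids, drop = FALSE] < 0)
  cat(sprintf("Basal activity: %d iModulons x %d samples (%d reference)\n",
              nrow(x$A), ncol(x$A), length(x$reference_ids)))
  cat(sprintf("  directions: %d negative, %d positive (flipped)\n",
              sum(x$directions == -1), sum(x$directions == 1)))
  cat(sprintf("  reference samples below zero: max %.1f%% per iModulon\n",
              100 * max(neg)))
  invisible(x)
}

#' Match iModulons between two decompositions
#'
#' Computes pairwise Pearson correlations of gene-weight columns over the
#' shared gene universe and greedily pairs components by descending
#' absolute correlation (one-to-one). Pairs at or above `r_threshold` in
#' absolute value count as matched; sign flips between runs are thereby
#' ignored.
#'
#' @param M1,M2 Gene-weight matrices with gene rownames.
#' @param r_threshold Minimum absolute correlation for a match
#'   (default 0.6).
#' @return A data.frame with columns `k1`, `k2`, `r`, `matched`, one row
#'   per greedy pair, with the matched fraction (matched pairs over the
#'   smaller component count) as attribute `matched_fraction`.
#' @export
match_imodulons <- function(M1, M2, r_threshold = 0.6) {
  shared <- intersect(rownames(M1), rownames(M2))
  if (length(shared) < 10)
    stop("fewer than 10 shared genes between decompositions", call. = FALSE)
  r <- stats::cor(M1[shared, , drop = FALSE], M2[shared, , drop = FALSE])
  r[is.na(r)] <- 0
  k1 <- colnames(M1); k2 <- colnames(M2)
  ord <- order(-abs(r))
  used1 <- logical(length(k1)); used2 <- logical(length(k2))
  rows <- list()
  for (idx in ord) {
    i <- (idx - 1) %% length(k1) + 1
    j <- (idx - 1) %/% length(k1) + 1
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      k1 = k1[i], k2 = k2[j], r = r[i, j],
      matched = abs(r[i, j]) >= r_threshold, stringsAsFactors = FALSE)
    if (all(used1) || all(used2)) break
  }
  out <- do.call(rbind, rows)
  attr(out, "matched_fraction") <- sum(out$matched) / min(length(k1), length(k2))
  out
}

#' Differential iModulon activity between two sample groups
#'
#' A simple, fully documented two-group procedure: the absolute mean
#' basal-activity difference per iModulon, a two-sided label-permutation
#' p-value, and Benjamini-Hochberg adjustment across iModulons. An
#' iModulon is flagged only when both the effect size exceeds
#' `delta_threshold` (basal-activity units) and the adjusted p-value is
#' below `fdr`.
#'
#' @param basal A `basal_activity` object.
#' @param group1,group2 Disjoint, non-empty sample id vectors.
#' @param delta_threshold Minimum absolute activity difference (default 5).
#' @param n_permutations Label permutations (default 10000).
#' @param fdr BH-adjusted significance level (default 0.05).
#' @param seed Optional seed for the permutation stream.
#' @return A data.frame with columns `imodulon`, `delta`, `p`, `q`,
#'   `flagged`.
#' @export
differential_activity <- function(basal, group1, group2, delta_threshold = 5,
                                  n_permutations = 10000, fdr = 0.05,
                                  seed = NULL) {
  stopifnot(inherits(basal, "basal_activity"))
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(intersect(group1, group2)))
    stop("groups overlap", call. = FALSE)
  A <- basal$A[, c(group1, group2), drop = FALSE]
  n1 <- length(group1)
  obs <- abs(rowMeans(A[, seq_len(n1), drop = FALSE]) -
               rowMeans(A[, -seq_len(n1), drop = FALSE]))
  perm_stat <- function() {
    idx <- sample(ncol(A))
    abs(rowMeans(A[, idx[seq_len(n1)], drop = FALSE]) -
          rowMeans(A[, idx[-seq_len(n1)], drop = FALSE]))
  }
  run <- function() {
    exceed <- rep(0L, nrow(A))
    for (b in seq_len(n_permutations))
      exceed <- exceed + (perm_stat() >= obs)
    (exceed + 1) / (n_permutations + 1)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  q <- stats::p.adjust(p, "BH")
  data.frame(imodulon = rownames(A), delta = unname(obs), p = unname(p),
             q = unname(q),
             flagged = unname(obs > delta_threshold & q < fdr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differentially expressed operons between two conditions
#'
#' Summarizes gene-level log2 fold changes (mean condition difference of
#' log-scale expression) at the operon level: the operon fold change is
#' the mean of its member genes' fold changes, and significance comes
#' from a two-sample t-test on per-replicate operon means (the mean
#' expression of member genes within each replicate), BH-adjusted across
#' operons. An operon is differentially expressed when
#' `|log2FC| > lfc_threshold` and `q < fdr`.
#'
#' @param X Genes x samples log-scale expression matrix.
#' @param operon_map Data.frame with columns `gene`, `operon`; each gene
#'   may belong to at most one operon. Operons without measured genes are
#'   skipped with a warning.
#' @param cond_a,cond_b Sample id vectors (at least 2 replicates each).
#' @param lfc_threshold Minimum absolute operon log2 fold change
#'   (default 1).
#' @param fdr BH-adjusted significance level (default 0.05).
#' @return A data.frame with columns `operon`, `n_genes`, `log2fc`, `t`,
#'   `p`, `q`, `de`.
#' @export
diff_expressed_operons <- function(X, operon_map, cond_a, cond_b,
                                   lfc_threshold = 1, fdr = 0.05) {
  if (length(cond_a) < 2 || length(cond_b) < 2)
    stop("need at least 2 replicates per condition", call. = FALSE)
  if (anyDuplicated(operon_map$gene))
    stop("operon_map assigns some gene to more than one operon", call. = FALSE)
  operons <- unique(operon_map$operon)
  rows <- list()
  for (op in operons) {
    genes <- intersect(operon_map$gene[operon_map$operon == op], rownames(X))
    if (!length(genes)) {
      warning("operon ", op, " has no measured genes; skipped")
      next
    }
    lfc_genes <- rowMeans(X[genes, cond_a, drop = FALSE]) -
      rowMeans(X[genes, cond_b, drop = FALSE])
    rep_a <- colMeans(X[genes, cond_a, drop = FALSE])
    rep_b <- colMeans(X[genes, cond_b, drop = FALSE])
    tt <- tryCatch(stats::t.test(rep_a, rep_b, var.equal = TRUE),
                   error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      operon = op, n_genes = length(genes), log2fc = mean(lfc_genes),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) 1 else tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$de <- abs(out$log2fc) > lfc_threshold & out$q < fdr
  rownames(out) <- NULL
  out
}
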