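# cache of Savitzky-Golay smoother matrices keyed by (length, window, degree)
.sg_cache <- new.env(parent = emptyenv())

sg_smoother <- function(len, window, degree) {
  key <- paste(len, window, degree)
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  F <- signal::sgolay(p = degree, n = window)
  k <- (window - 1L) %/% 2L
  S <- matrix(0, len, len)
  for (i in seq_len(k)) S[i, seq_len(window)] <- F[i, ]
  centre <- F[k + 1L, ]
  for (i in (k + 1L):(len - k)) S[i, (i - k):(i + k)] <- centre
  for (i in seq_len(k))
    S[len - k + i, (len - window + 1L):len] <- F[k + 1L + i, ]
  .sg_cache[[key]] <- S
  S
}

check_sg_args <- function(len, window, degree) {
  if (window %% 2 == 0) {
    message("Savitzky-Golay window length ", window,
            " is even; rounding up to ", window + 1)
    window <- window + 1L
  }
  if (degree >= window)
    stop("polynomial degree must be below the window length", call. = FALSE)
  if (len <= window)
    stop("trace (length ", len, ") must be longer than the smoothing window (",
         window, ")", call. = FALSE)
  window
}

#' Savitzky-Golay smoothing of a kinetic trace
#'
#' Least-squares local polynomial smoothing with the classical
#' Savitzky-Golay filter. Even window lengths are rounded up to the next
#' odd integer with a notice (the published window of 50 becomes 51).
#' Boundary points are smoothed by fitting the polynomial over the
#' truncated one-sided window at each end, so a polynomial of the fit
#' degree is reproduced exactly everywhere.
#'
#' @param trace Numeric vector, longer than the window.
#' @param window Window length (default 51).
#' @param degree Polynomial degree (default 3), below the window length.
#' @return The smoothed trace.
#' @export
smooth_signal <- function(trace, window = 51, degree = 3) {
  window <- check_sg_args(length(trace), window, degree)
  drop(sg_smoother(length(trace), window, degree) %*% trace)
}

#' Smooth every well of a plate at once
#'
#' Applies [smooth_signal()] to each row of a wells x timepoints matrix
#' through a single precomputed smoother-matrix product.
#'
#' @param signal Wells x timepoints matrix.
#' @inheritParams smooth_signal
#' @return Matrix of the same shape.
#' @export
smooth_plate <- function(signal, window = 51, degree = 3) {
  window <- check_sg_args(ncol(signal), window, degree)
  out <- signal %*% t(sg_smoother(ncol(signal), window, degree))
  dimnames(out) <- dimnames(signal)
  out
}

#' Maximum signal of a smoothed trace
#'
#' @param trace Numeric (smoothed) trace.
#' @return Its maximum.
#' @export
max_signal <- function(trace) max(trace)

#' Binary growth calls for a kinetic phenotyping plate
#'
#' Every well's opacity trace is Savitzky-Golay smoothed and its maximum
#' recorded. The negative-control wells form the control group, providing
#' the mean and (n-1) standard deviation of the no-growth maximum signal.
#' Each tested well gets a one-sided standardized statistic
#' `z = (s - mu) / sigma`, an upper-tail p-value, Bonferroni correction
#' over the tested wells of the plate, and a growth call when the
#' adjusted p-value is below `alpha`.
#'
#' With `reference = "t"` (default) the p-value uses the exact null of
#' the standardized statistic under Gaussian maxima with estimated
#' control parameters, `z / sqrt(1 + 1/n) ~ t(n - 1)`, which preserves
#' the Bonferroni family-wise guarantee at realistic control counts.
#' `reference = "normal"` uses the standard-normal upper tail (the plain
#' z-test), which is anti-conservative when the controls are few; see the
#' methods vignette for the design analysis.
#'
#' @param plate A `plate_kinetics` object (see [simulate_plate()] /
#'   [read_plate()]).
#' @param alpha Familywise significance level (default 0.05).
#' @param window,degree Savitzky-Golay parameters.
#' @param reference `"t"` or `"normal"`.
#' @return A data.frame with one row per well: `well`, `substrate`,
#'   `category`, `is_control`, `max_signal`, `z`, `p`, `p_adj`, `call`
#'   (`NA` statistics for control wells).
#' @export
growth_calls <- function(plate, alpha = 0.05, window = 51, degree = 3,
                         reference = c("t", "normal")) {
  reference <- match.arg(reference)
  stopifnot(inherits(plate, "plate_kinetics"))
  smoothed <- smooth_plate(plate$signal, window, degree)
  mx <- apply(smoothed, 1, max)
  ctrl <- plate$wells$is_control
  n_ctrl <- sum(ctrl)
  if (n_ctrl < 2)
    stop("need at least 2 negative-control wells", call. = FALSE)
  mu <- mean(mx[ctrl])
  sigma <- stats::sd(mx[ctrl])
  if (sigma == 0)
    stop("negative-control maxima have zero variance; cannot calibrate",
         call. = FALSE)
  n_tested <- sum(!ctrl)
  z <- (mx - mu) / sigma
  p <- if (reference == "t")
    stats::pt(z / sqrt(1 + 1 / n_ctrl), df = n_ctrl - 1, lower.tail = FALSE)
  else stats::pnorm(z, lower.tail = FALSE)
  p_adj <- pmin(1, p * n_tested)
  out <- data.frame(plate$wells,
                    max_signal = unname(mx), z = unname(z),
                    p = unname(p), p_adj = unname(p_adj),
                    call = as.integer(p_adj < alpha),
                    stringsAsFactors = FALSE)
  out[ctrl, c("z", "p", "p_adj")] <- NA_real_
  out$call[ctrl] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Compare growth calls between two strains
#'
#' Lists conditions gained (0 to 1) and lost (1 to 0) going from strain a
#' to strain b, and the per-category loss percentage
#' `100 |lost in category| / |grown by a in category|`.
#'
#' @param calls_a,calls_b Named binary vectors (1 = growth) over
#'   conditions; only shared conditions are compared.
#' @param categories Optional named character vector assigning each
#'   condition to a nutrient category.
#' @return A list with `gained`, `lost` (condition names) and
#'   `loss_percent` (named by category; `NA` where strain a grew on
#'   nothing in the category).
#' @export
compare_calls <- function(calls_a, calls_b, categories = NULL) {
  shared <- intersect(names(calls_a), names(calls_b))
  if (!length(shared)) stop("no shared conditions", call. = FALSE)
  a <- calls_a[shared]
  b <- calls_b[shared]
  gained <- shared[a == 0 & b == 1]
  lost <- shared[a == 1 & b == 0]
  loss_percent <- NULL
  if (!is.null(categories)) {
    cats <- sort(unique(categories[shared]))
    loss_percent <- vapply(cats, function(cc) {
      in_cat <- shared[categories[shared] == cc]
      denom <- sum(a[in_cat] == 1)
      if (denom == 0) return(NA_real_)
      100 * sum(in_cat %in% lost) / denom
    }, numeric(1))
  }
  list(gained = gained, lost = lost, loss_percent = loss_percent)
}

#' PCA of a binary growth-call matrix
#'
#' Principal component analysis of strains x conditions binary calls via
#' singular value decomposition of the column-centered (per condition),
#' unscaled matrix. Conditions without variance are dropped with a
#' warning.
#'
#' @param calls Binary strains x conditions matrix (at least 3 strains).
#' @return A list with `scores` (strains x PCs), `loadings`
#'   (conditions x PCs), and `variance_fraction` (descending, summing
#'   to 1).
#' @export
pca_binary <- function(calls) {
  if (nrow(calls) < 3) stop("need at least 3 strains", call. = FALSE)
  v <- apply(calls, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance conditions dropped")
    calls <- calls[, v > 0, drop = FALSE]
  }
  if (ncol(calls) < 2)
    stop("need at least 2 conditions with variance", call. = FALSE)
  pc <- stats::prcomp(calls, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf)
}

#' Read and write plate kinetics CSV files
#'
#' Dialect: one row per well with leading columns
#' `well,substrate,category,is_control` followed by one column per
#' timepoint whose header is the time in hours.
#'
#' @param path File path.
#' @return `read_plate()`: a `plate_kinetics` object.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("well", "substrate", "category", "is_control")
  if (!all(meta_cols %in% names(df)))
    stop("plate CSV needs columns ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  tp_cols <- setdiff(names(df), meta_cols)
  tp <- as.numeric(tp_cols)
  if (anyNA(tp) || is.unsorted(tp, strictly = TRUE))
    stop("timepoint columns must be strictly increasing hours", call. = FALSE)
  sig <- as.matrix(df[tp_cols])
  rownames(sig) <- df$well
  wells <- df[meta_cols]
  wells$is_control <- as.logical(wells$is_control)
  structure(list(wells = wells, signal = sig, timepoints = tp),
            class = "plate_kinetics")
}

#' @param plate A `plate_kinetics` object.
#' @rdname read_plate
#' @export
write_plate <- function(plate, path) {
  df <- cbind(plate$wells,
              as.data.frame(plate$signal, check.names = FALSE))
  colnames(df)[-(1:4)] <- formatC(plate$timepoints, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
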