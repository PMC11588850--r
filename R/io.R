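#' Read and write expression matrices
#'
#' TSV with gene ids in the first column (`gene`) and one column per
#' sample; values are log-scale expression.
#'
#' @param path File path.
#' @return `read_expression()`: genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("expression matrix must be finite numeric", call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("gene and sample ids must be unique", call. = FALSE)
  m
}

#' @param X Genes x samples matrix.
#' @rdname read_expression
#' @export
write_expression <- function(X, path) {
  df <- data.frame(gene = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write ICA decompositions
#'
#' `M` (genes x iModulons) and `A` (iModulons x samples) are CSV files
#' with id header row and first column; annotations are a CSV with
#' columns `imodulon`, `regulator` and optionally `annotated_direction`;
#' sample metadata a CSV with at least `sample_id`, `is_reference`.
#'
#' @param m_path,a_path,annotation_path,samples_path File paths
#'   (annotations and samples optional for reading).
#' @return `read_decomposition()`: list with `M`, `A`, `annotations`,
#'   `samples` (the latter two `NULL` when not given).
#' @export
read_decomposition <- function(m_path, a_path, annotation_path = NULL,
                               samples_path = NULL) {
  read_mat <- function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    m
  }
  M <- read_mat(m_path)
  A <- read_mat(a_path)
  if (ncol(M) != nrow(A) || !all(colnames(M) == rownames(A)))
    stop("M columns and A rows must carry the same iModulon ids",
         call. = FALSE)
  ann <- if (!is.null(annotation_path))
    utils::read.csv(annotation_path, stringsAsFactors = FALSE) else NULL
  smp <- if (!is.null(samples_path)) {
    s <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
    s$is_reference <- as.logical(s$is_reference)
    if ("is_wildtype" %in% names(s)) s$is_wildtype <- as.logical(s$is_wildtype)
    s
  } else NULL
  list(M = M, A = A, annotations = ann, samples = smp)
}

#' @param M,A Decomposition matrices.
#' @param annotations,samples Optional annotation / sample metadata
#'   data.frames.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @rdname read_decomposition
#' @export
write_decomposition <- function(M, A, annotations = NULL, samples = NULL,
                                dir, prefix = "ica") {
  write_mat <- function(m, p, id) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- id
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  }
  write_mat(M, file.path(dir, paste0(prefix, "_M.csv")), "gene")
  write_mat(A, file.path(dir, paste0(prefix, "_A.csv")), "imodulon")
  if (!is.null(annotations))
    utils::write.csv(annotations, file.path(dir, paste0(prefix, "_annotations.csv")),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(samples))
    utils::write.csv(samples, file.path(dir, paste0(prefix, "_samples.csv")),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write every artifact of a synthetic study to a directory
#'
#' Emits the regulon TSV, expression TSV, decomposition CSVs, plate CSVs,
#' mutation TSV, growth-impact and growth-rate CSVs, and a ground-truth
#' JSON.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_regulon(study$trn, file.path(dir, "regulon.tsv"))
  write_expression(study$expression, file.path(dir, "expression.tsv"))
  write_decomposition(study$M, study$A, study$annotations, study$samples, dir)
  write_mutations(study$mutations, file.path(dir, "mutations.tsv"))
  write_growth_impacts(study$growth_impacts, file.path(dir, "growth_impacts.csv"))
  utils::write.csv(study$growth_rates, file.path(dir, "growth_rates.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(study$plates))
    write_plate(study$plates[[nm]], file.path(dir, paste0("plate_", nm, ".csv")))
  gt <- study$ground_truth
  gt$noise <- NULL           # large matrix; regenerate from the spec instead
  gt$basal_truth <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
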