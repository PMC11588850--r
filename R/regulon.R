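#' Read and write regulon tables
#'
#' The regulon TSV dialect has a header line `regulator<TAB>target<TAB>effect`
#' with effects coded `+` (activation), `-` (repression) or `+-` (dual),
#' loosely mirroring curated TRN network exports. `col_map` renames
#' arbitrary columns onto this dialect so real exports can be read
#' directly.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping the file's
#'   column names onto `regulator`, `target`, `effect`, e.g.
#'   `c(regulator = "TF_name", target = "gene", effect = "sign")`.
#' @return `read_regulon()`: a data.frame with columns `regulator`,
#'   `target`, `effect` in `{activation, repression, dual}`.
#' @export
read_regulon <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("column '", col_map[[nm]], "' not found in ", path, call. = FALSE)
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  need <- c("regulator", "target", "effect")
  if (!all(need %in% names(df)))
    stop("regulon table needs columns regulator, target, effect", call. = FALSE)
  code <- c("+" = "activation", "-" = "repression", "+-" = "dual",
            activation = "activation", repression = "repression",
            dual = "dual")
  if (!all(df$effect %in% names(code)))
    stop("unknown effect codes: ",
         paste(unique(df$effect[!df$effect %in% names(code)]), collapse = ", "),
         call. = FALSE)
  df$effect <- unname(code[df$effect])
  df[need]
}

#' @param regulon A regulon data.frame (`regulator`, `target`, `effect`).
#' @rdname read_regulon
#' @export
write_regulon <- function(regulon, path) {
  code <- c(activation = "+", repression = "-", dual = "+-")
  out <- data.frame(regulator = regulon$regulator, target = regulon$target,
                    effect = unname(code[regulon$effect]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of distinct targets of a regulator
#'
#' @param regulon Regulon data.frame.
#' @param tf Regulator gene id.
#' @return Integer count of distinct targets (0 if `tf` is absent).
#' @export
regulon_size <- function(regulon, tf) {
  length(unique(regulon$target[regulon$regulator == tf]))
}

#' Count each regulator's sole-regulator targets
#'
#' A sole-regulator target of a TF is a gene whose only annotated
#' regulator (counting distinct regulators across the whole table) is
#' that TF.
#'
#' @param regulon Regulon data.frame.
#' @return Named integer vector over all regulators in the table.
#' @export
sole_regulator_counts <- function(regulon) {
  if (!nrow(regulon)) stop("regulon table is empty", call. = FALSE)
  pairs <- unique(regulon[c("regulator", "target")])
  n_reg <- table(pairs$target)
  sole_targets <- names(n_reg)[n_reg == 1]
  tfs <- sort(unique(regulon$regulator))
  counts <- vapply(tfs, function(tf)
    sum(pairs$target[pairs$regulator == tf] %in% sole_targets), integer(1))
  stats::setNames(as.integer(counts), tfs)
}

#' Distinct-regulator counts for a gene set
#'
#' Returns the multiset of distinct-regulator counts for the given genes;
#' genes absent from the table count zero regulators. Useful for
#' contrasting the regulatory redundancy of gene sets, e.g. genes in
#' KO-specific iModulons against genes of ordinary iModulons.
#'
#' @param regulon Regulon data.frame.
#' @param gene_set Non-empty character vector of gene ids.
#' @return Named integer vector (one entry per gene in `gene_set`).
#' @export
regulators_per_gene <- function(regulon, gene_set) {
  if (!length(gene_set)) stop("gene_set is empty", call. = FALSE)
  pairs <- unique(regulon[c("regulator", "target")])
  counts <- vapply(gene_set, function(g)
    length(unique(pairs$regulator[pairs$target == g])), integer(1))
  stats::setNames(as.integer(counts), gene_set)
}
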