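#' Convergent mutations across independent evolution lineages
#'
#' Groups a knockout's mutation records by gene-or-region label and
#' returns the labels mutated in at least `min_lineages` distinct
#' lineages (default 2), the convergence rule for independent evolution
#' experiments. Population records below the frequency floor are ignored
#' (the default floor of 0.05 still counts low-frequency subpopulation
#' mutations, which can carry real adaptations). An optional `gene_set`
#' intersects the result, e.g. with the KO'd regulator's regulon for the
#' regulator-specific flag.
#'
#' @param table Mutation data.frame (`strain`, `ko`, `lineage`, `stage`,
#'   `sample_type`, `gene`, `position`, `allele`, `frequency`).
#' @param ko Knockout background to analyse; must have records.
#' @param min_lineages Minimum distinct lineages (default 2).
#' @param gene_set Optional filter of gene labels.
#' @param min_frequency Frequency floor for counting a record
#'   (default 0.05).
#' @return A data.frame with columns `gene`, `n_lineages`, sorted by
#'   descending lineage count then gene.
#' @export
convergent_mutations <- function(table, ko, min_lineages = 2,
                                 gene_set = NULL, min_frequency = 0.05) {
  sub <- table[table$ko == ko & table$frequency >= min_frequency, ,
               drop = FALSE]
  if (!nrow(sub))
    stop("no mutation records for KO '", ko, "'", call. = FALSE)
  pairs <- unique(sub[c("gene", "lineage")])
  counts <- table(pairs$gene)
  hits <- names(counts)[counts >= min_lineages]
  if (!is.null(gene_set)) hits <- intersect(hits, gene_set)
  out <- data.frame(gene = hits,
                    n_lineages = as.integer(counts[hits]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_lineages, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard agreement between isolate and population mutation sets
#'
#' Mutations are keyed by (position, allele) by default (`key = "gene"`
#' switches to gene-level keys). Returns `|intersection| / |union|`;
#' when both sets are empty the index is undefined and an error is
#' raised.
#'
#' @param isolate,population Mutation record data.frames (subsets of a
#'   mutation table).
#' @param key `"position_allele"` or `"gene"`.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_agreement <- function(isolate, population,
                              key = c("position_allele", "gene")) {
  key <- match.arg(key)
  keys <- function(df) {
    if (!nrow(df)) return(character())
    if (key == "gene") unique(df$gene)
    else unique(paste(df$position, df$allele))
  }
  a <- keys(isolate)
  b <- keys(population)
  if (!length(a) && !length(b))
    stop("both mutation sets are empty; Jaccard index undefined",
         call. = FALSE)
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-isolate mutation counts and their mean
#'
#' Counts mutations per isolate sample (sample type `"isolate"`) and
#' returns the mean after excluding named hypermutator strains.
#'
#' @param table Mutation data.frame.
#' @param exclude Strain ids (optionally suffixed by stage internally) to
#'   exclude, e.g. hypermutators.
#' @return A list with `mean_per_isolate` and `per_strain` (data.frame
#'   `strain`, `stage`, `n_mutations`).
#' @export
mutation_summary <- function(table, exclude = character()) {
  iso <- table[table$sample_type == "isolate", , drop = FALSE]
  if (!nrow(iso)) stop("no isolate records", call. = FALSE)
  id <- paste(iso$strain, iso$stage)
  counts <- as.data.frame(table(id), stringsAsFactors = FALSE)
  names(counts) <- c("id", "n_mutations")
  parts <- do.call(rbind, strsplit(counts$id, " (?=[^ ]+$)", perl = TRUE))
  per_strain <- data.frame(strain = parts[, 1], stage = parts[, 2],
                           n_mutations = as.integer(counts$n_mutations),
                           stringsAsFactors = FALSE)
  keep <- !(per_strain$strain %in% exclude)
  if (!any(keep)) stop("all isolate samples excluded", call. = FALSE)
  list(mean_per_isolate = mean(per_strain$n_mutations[keep]),
       per_strain = per_strain)
}

#' Read and write mutation tables
#'
#' TSV dialect with columns `strain`, `ko`, `lineage`, `stage`,
#' `sample_type`, `gene`, `position`, `allele`, `frequency`; `col_map`
#' adapts exports with other column names.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping file columns
#'   onto the dialect columns.
#' @return `read_mutations()`: the mutation data.frame.
#' @export
read_mutations <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (nm in names(col_map))
      names(df)[names(df) == col_map[[nm]]] <- nm
  need <- c("strain", "ko", "lineage", "stage", "sample_type", "gene",
            "position", "allele", "frequency")
  if (!all(need %in% names(df)))
    stop("mutation table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @param table Mutation data.frame.
#' @rdname read_mutations
#' @export
write_mutations <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
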