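#' Construct and validate an orthologue table
#'
#' An orthologue table maps orthologue group ids to exactly one gene id per
#' species, optionally with per-species paralog copy counts. It is the
#' comparison universe for every cross-species statistic: overlap
#' expectations, enrichments and Venn decompositions are all taken over its
#' 1:1:1 subset.
#'
#' @param df data.frame with a `group_id` column, one `<species>_gene`
#'   column per species, and optional `<species>_copies` integer columns.
#' @param species character vector of species labels.
#' @return The validated data.frame with class `ortholog_table` and a
#'   `species` attribute.
#' @export
ortholog_table <- function(df, species) {
  if (!"group_id" %in% names(df))
    stop("orthologue table format error: missing `group_id` column")
  gene_cols <- paste0(species, "_gene")
  missing <- setdiff(gene_cols, names(df))
  if (length(missing))
    stop("orthologue table format error: missing species column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$group_id))
    stop("orthologue table validation error: duplicated group_id(s): ",
         paste(unique(df$group_id[duplicated(df$group_id)]), collapse = ", "))
  for (cc in gene_cols) {
    dup <- unique(df[[cc]][duplicated(df[[cc]])])
    if (length(dup))
      stop("orthologue table validation error: gene id(s) appearing in more ",
           "than one group in column `", cc, "`: ",
           paste(dup, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  attr(df, "species") <- species
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Read an orthologue table from TSV
#'
#' Expects a tab-separated file with header columns `group_id` and
#' `<species>_gene` for each requested species; `#`-prefixed lines are
#' ignored. Duplicate gene ids within a species are rejected.
#'
#' @param path file path.
#' @param species character vector of species labels to require.
#' @return An [ortholog_table()].
#' @export
load_ortholog_table <- function(path, species) {
  df <- read_tsv_checked(path)
  ortholog_table(df, species)
}

#' Restrict an orthologue table to 1:1:1 groups
#'
#' Keeps only groups whose copy count is exactly 1 in every species
#' (a gene with exactly one counterpart in each compared genome). Tables
#' without copy-count columns are treated as already single-copy. Row order
#' is preserved and the operation is idempotent.
#'
#' @param table an [ortholog_table()].
#' @return The filtered [ortholog_table()].
#' @export
filter_one_to_one <- function(table) {
  stopifnot(inherits(table, "ortholog_table"))
  species <- attr(table, "species")
  keep <- rep(TRUE, nrow(table))
  for (s in species) {
    cc <- paste0(s, "_copies")
    if (cc %in% names(table)) keep <- keep & table[[cc]] == 1L
    gc <- paste0(s, "_gene")
    keep <- keep & !is.na(table[[gc]]) & nzchar(table[[gc]])
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  ortholog_table(out, species)
}

#' Re-key a species expression matrix onto orthologue groups
#'
#' Rows of the matrix (species gene ids) are mapped to orthologue group ids
#' through the table's 1:1:1 subset. Groups whose gene is absent from the
#' matrix are kept with `NA` values (missing, not zero): downstream code
#' drops them pairwise (correlations) or complete-case (DE, overlaps)
#' rather than treating absence as silence.
#'
#' @param matrix an [expr_matrix] keyed by species gene ids.
#' @param table an [ortholog_table()].
#' @param species which species' gene-id column to map through.
#' @return An [expr_matrix] keyed by group ids, one row per 1:1:1 group.
#' @export
map_to_groups <- function(matrix, table, species) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(table, "ortholog_table"))
  if (!species %in% attr(table, "species"))
    stop("species `", species, "` not in orthologue table (has: ",
         paste(attr(table, "species"), collapse = ", "), ")")
  table <- filter_one_to_one(table)
  genes <- table[[paste0(species, "_gene")]]
  idx <- match(genes, rownames(matrix$values))
  if (all(is.na(idx)))
    stop("no orthologues matched the matrix gene ids for species `",
         species, "`")
  vals <- matrix$values[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  vals[is.na(idx), ] <- NA_real_
  rownames(vals) <- table$group_id
  expr_matrix(vals, matrix$samples, unit = matrix$unit)
}

#' Shared complete-case orthologue universe
#'
#' The universe N behind all overlap statistics: 1:1:1 groups quantified
#' (non-missing in every sample) in every supplied matrix.
#'
#' @param ... group-keyed [expr_matrix] objects.
#' @return Character vector of group ids.
#' @export
shared_universe <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  ids <- lapply(mats, function(m) {
    stopifnot(inherits(m, "expr_matrix"))
    rownames(m$values)[stats::complete.cases(m$values)]
  })
  Reduce(intersect, ids)
}
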