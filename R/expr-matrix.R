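#' Expression matrix with sample annotation
#'
#' Light-weight container pairing a genes-by-samples numeric matrix with a
#' sample sheet and a unit tag tracking the transform history
#' (`"raw"` counts, `"cpm"`, or `"log2cpm"`). Rows are gene or orthologue
#' group ids; columns are samples. Missing (unquantified) genes are `NA`,
#' never zero: a zero is an observation, an `NA` is the absence of one.
#'
#' @param values numeric matrix with row names (gene/group ids) and column
#'   names (sample ids). Negative finite values are rejected.
#' @param samples data.frame with one row per column of `values`, containing
#'   at least `sample_id`, `species`, `group` (stage or culture condition)
#'   and `replicate`. Row order must match the column order of `values`.
#' @param unit one of `"raw"`, `"cpm"`, `"log2cpm"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `unit`.
#' @export
expr_matrix <- function(values, samples, unit = c("raw", "cpm", "log2cpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (genes) and column names (samples)")
  if (unit != "log2cpm" && any(values < 0, na.rm = TRUE))
    stop("expression values must be nonnegative")
  required <- c("sample_id", "species", "group", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("sample sheet `sample_id` must match matrix column names, in order")
  if (anyNA(samples[required]))
    stop("sample sheet has incomplete metadata (NA entries)")
  structure(list(values = values,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$samples$species, x$samples$group)
  print(tab)
  n_missing <- sum(!stats::complete.cases(x$values))
  if (n_missing > 0)
    cat(sprintf("%d genes with missing values\n", n_missing))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples
#'
#' @param x an [expr_matrix].
#' @param sample_ids character vector of sample ids to keep, in the order
#'   given.
#' @return An `expr_matrix` restricted to the requested samples.
#' @export
select_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(sample_ids, colnames(x$values))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  idx <- match(sample_ids, colnames(x$values))
  expr_matrix(x$values[, idx, drop = FALSE], x$samples[idx, , drop = FALSE],
              unit = x$unit)
}

#' Sample ids belonging to one annotation group
#'
#' @param x an [expr_matrix].
#' @param group stage or condition label to match against the sample sheet.
#' @param species optional species label to additionally match.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group, species = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- x$samples$group == group
  if (!is.null(species)) keep <- keep & x$samples$species == species
  x$samples$sample_id[keep]
}
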