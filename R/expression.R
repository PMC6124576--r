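#' Normalise an expression matrix
#'
#' Counts-per-million scaling per sample, computed over the quantified
#' (non-missing) genes of the matrix — for group-keyed matrices this is the
#' orthologue universe, which keeps per-sample totals comparable across
#' species. Optionally followed by a log2(x + offset) transform.
#'
#' @param matrix a raw-unit [expr_matrix].
#' @param method `"cpm"` or `"none"` (identity).
#' @param log2_offset if > 0, apply `log2(x + log2_offset)` after scaling
#'   and tag the unit `log2cpm`.
#' @return An [expr_matrix] with updated unit tag.
#' @export
normalize_expr <- function(matrix, method = c("cpm", "none"), log2_offset = 0) {
  stopifnot(inherits(matrix, "expr_matrix"))
  method <- match.arg(method)
  if (log2_offset < 0) stop("`log2_offset` must be >= 0")
  if (method == "none" && log2_offset == 0) return(matrix)
  if (matrix$unit != "raw")
    stop("normalize_expr expects a raw-unit matrix, got `", matrix$unit, "`")
  vals <- matrix$values
  unit <- matrix$unit
  if (method == "cpm") {
    totals <- colSums(vals, na.rm = TRUE)
    if (any(totals == 0))
      stop("all-zero sample(s): ",
           paste(colnames(vals)[totals == 0], collapse = ", "))
    vals <- sweep(vals, 2, totals / 1e6, "/")
    unit <- "cpm"
  }
  if (log2_offset > 0) {
    vals <- log2(vals + log2_offset)
    unit <- if (unit == "cpm") "log2cpm" else unit
  }
  out <- matrix
  out$values <- vals
  out$unit <- unit
  out
}

#' Call the expressed gene set of one stage
#'
#' A gene is called expressed at a stage if its normalised expression is at
#' least `min_level` in at least `min_fraction` of that stage's samples.
#' The defaults (1 CPM in at least half the replicates) are a conventional
#' bulk RNA-seq rule; both are tunable. Missing genes are never called.
#'
#' @param matrix a normalised [expr_matrix].
#' @param stage stage or condition label.
#' @param species optional species label to filter samples.
#' @param min_level expression threshold (same unit as the matrix).
#' @param min_fraction minimum fraction of the stage's samples at or above
#'   `min_level`.
#' @return Character vector of gene/group ids.
#' @export
call_expressed <- function(matrix, stage, species = NULL, min_level = 1,
                           min_fraction = 0.5) {
  stopifnot(inherits(matrix, "expr_matrix"))
  ids <- group_samples(matrix, stage, species)
  if (length(ids) == 0)
    stop("no samples for stage `", stage, "`",
         if (!is.null(species)) paste0(" in species `", species, "`") else "")
  sub <- matrix$values[, ids, drop = FALSE]
  frac <- rowMeans(sub >= min_level)
  rownames(sub)[!is.na(frac) & frac >= min_fraction]
}

#' Three-set Venn decomposition of expressed orthologues
#'
#' Counts the seven exclusive regions of three gene sets and, per set, the
#' shared fraction |A n B n C| / |set| — the "fraction of genes expressed by
#' each species that is expressed by all".
#'
#' @param sets named list of exactly three character vectors over a common
#'   universe.
#' @return A list with `regions` (named integer vector: `<s1>_only`, ...,
#'   `<s1>_<s2>`, ..., `all`), and `shared_fraction` (named numeric, NA for
#'   an empty set).
#' @export
venn_regions <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets)))
    stop("`sets` must be a named list of exactly three sets")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  regions <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
               sum(!inA & !inB & inC), sum(inA & inB & !inC),
               sum(inA & !inB & inC), sum(!inA & inB & inC),
               sum(inA & inB & inC))
  names(regions) <- c(paste0(nm, "_only"),
                      paste(nm[1], nm[2], sep = "_"),
                      paste(nm[1], nm[3], sep = "_"),
                      paste(nm[2], nm[3], sep = "_"), "all")
  triple <- regions[["all"]]
  shared <- vapply(sets, function(s)
    if (length(s) == 0) NA_real_ else triple / length(s), numeric(1))
  list(regions = regions, shared_fraction = shared)
}
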