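#' Pearson correlation heatmap structure with average-linkage clustering
#'
#' Pairwise Pearson correlations between samples over complete-case genes,
#' followed by average-linkage agglomeration on the distance 1 - r.
#' Log-scale expression (e.g. log2 CPM) is recommended so a handful of
#' highly expressed genes does not dominate r.
#'
#' @param matrix an [expr_matrix] with >= 2 samples.
#' @return A list of class `structure_result` with `cor` (samples x samples
#'   matrix) and `hclust` (an `stats::hclust` object, average linkage).
#' @export
correlation_cluster <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- matrix$values[stats::complete.cases(matrix$values), , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (nrow(x) < 2) stop("need at least 2 complete-case genes")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(cor = r, hclust = hc, samples = matrix$samples),
            class = "structure_result")
}

#' Principal component analysis of samples
#'
#' SVD-based PCA of the samples-by-genes matrix (samples as observations),
#' optionally centered and scaled per gene. Returns the fraction of
#' variance carried by each component and the sample scores.
#'
#' @param matrix an [expr_matrix] with >= 2 samples; log2 CPM recommended.
#' @param center,scale. passed to [stats::prcomp()].
#' @return A list of class `structure_result` with `var_fraction` (named,
#'   non-increasing, summing to 1), `scores` (samples x PCs) and `prcomp`.
#' @export
pca_samples <- function(matrix, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  x <- matrix$values[stats::complete.cases(matrix$values), , drop = FALSE]
  if (nrow(x) < 1) stop("no complete-case genes to analyse")
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (scale.) {
    keep <- apply(x, 1, stats::sd) > 0
    x <- x[keep, , drop = FALSE]
  }
  pr <- stats::prcomp(t(x), center = center, scale. = scale.)
  v <- pr$sdev^2
  structure(list(var_fraction = stats::setNames(v / sum(v),
                                                colnames(pr$x)),
                 scores = pr$x, prcomp = pr, samples = matrix$samples),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  if (!is.null(x$cor)) {
    cat(sprintf("sample correlation structure: %d samples, mean r = %.3f\n",
                ncol(x$cor), mean(x$cor[lower.tri(x$cor)])))
  }
  if (!is.null(x$var_fraction)) {
    top <- utils::head(x$var_fraction, 4)
    cat("PCA variance fractions: ",
        paste(sprintf("%s %.0f%%", names(top), 100 * top), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.structure_result <- function(x, pcs = c(1, 2), ...) {
  if (is.null(x$scores)) stop("no PCA scores to plot; run pca_samples()")
  sc <- x$scores[, pcs, drop = FALSE]
  grp <- factor(paste(x$samples$species, x$samples$group))
  graphics::plot(sc, col = as.integer(grp), pch = 19,
                 xlab = sprintf("PC%d (%.0f%%)", pcs[1],
                                100 * x$var_fraction[pcs[1]]),
                 ylab = sprintf("PC%d (%.0f%%)", pcs[2],
                                100 * x$var_fraction[pcs[2]]), ...)
  graphics::legend("topright", legend = levels(grp), col = seq_along(levels(grp)),
                   pch = 19, cex = 0.7)
  invisible(x)
}

#' Replicate-correlation quality control
#'
#' Flags a sample for exclusion when its median Pearson correlation with
#' the other replicates of its own species/stage group falls below
#' `min_median_r` — the rule used to drop degraded embryo samples before
#' differential expression. Exclusion is greedy: the worst offender is
#' removed first and medians are recomputed among the remaining peers, so a
#' single degraded replicate does not drag its healthy neighbours below
#' threshold. Samples without any same-group peer are never excluded (a
#' warning is emitted).
#'
#' @param result a `structure_result` from [correlation_cluster()].
#' @param min_median_r exclusion threshold on the median within-group r
#'   (default 0.7).
#' @return Character vector of excluded sample ids, with a `reasons`
#'   attribute (named numeric vector of the offending median correlations).
#' @export
flag_outliers <- function(result, min_median_r = 0.7) {
  stopifnot(inherits(result, "structure_result"))
  if (is.null(result$cor)) stop("result carries no correlation matrix")
  r <- result$cor
  meta <- result$samples
  grp <- paste(meta$species, meta$group)
  excluded <- character(0)
  reasons <- numeric(0)
  active <- seq_len(nrow(meta))
  medians <- function(active) {
    vapply(active, function(i) {
      peers <- setdiff(active[grp[active] == grp[i]], i)
      if (length(peers) == 0) NA_real_ else stats::median(r[i, peers])
    }, numeric(1))
  }
  singletons <- active[is.na(medians(active))]
  for (i in singletons)
    warning("sample `", meta$sample_id[i],
            "` has no same-group replicates; QC skipped")
  repeat {
    med <- medians(active)
    offending <- which(!is.na(med) & med < min_median_r)
    if (length(offending) == 0) break
    worst <- offending[which.min(med[offending])]
    id <- meta$sample_id[active[worst]]
    excluded <- c(excluded, id)
    reasons <- c(reasons, stats::setNames(med[worst], id))
    active <- active[-worst]
  }
  attr(excluded, "reasons") <- reasons
  excluded
}
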