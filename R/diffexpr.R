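#' Differential-expression call configuration
#'
#' Holds the thresholds applied to per-gene test results. The defaults are
#' the study thresholds: BH q-value at most 0.25 and a minimum linear fold
#' change of 1.5 (in either direction).
#'
#' @param q_max maximum BH-adjusted q-value, in (0, 1].
#' @param fc_min minimum linear fold change (>= 1).
#' @param test `"nb_exact"` (negative-binomial exact test conditioned on
#'   each gene's total count; the default, with good power at 2-3
#'   replicates) or `"welch_log"` (Welch t on log2(CPM + 1)).
#' @param pseudo_mean pseudo-mean c (CPM units) added to both group means in
#'   the fold change `log2((mean_b + c) / (mean_a + c))`.
#' @return A list of class `de_call_config`.
#' @export
de_call_config <- function(q_max = 0.25, fc_min = 1.5,
                           test = c("nb_exact", "welch_log"),
                           pseudo_mean = 0.5) {
  test <- match.arg(test)
  if (q_max <= 0 || q_max > 1) stop("`q_max` must be in (0, 1]")
  if (fc_min < 1) stop("`fc_min` must be >= 1")
  if (pseudo_mean < 0) stop("`pseudo_mean` must be >= 0")
  structure(list(q_max = q_max, fc_min = fc_min, test = test,
                 pseudo_mean = pseudo_mean), class = "de_call_config")
}

#' Per-gene differential expression test between two sample groups
#'
#' Fold changes are computed on CPM group means with a pseudo-mean:
#' `log2FC = log2((mean_b + c) / (mean_a + c))`, so the sign is positive
#' when expression rises from group A to group B and reversing the groups
#' negates it. P-values come from either an exact negative-binomial test
#' (the default; conditions on each gene's total count with a
#' common/tagwise moment-based dispersion fit, the standard engine at 2-3
#' replicates) or a Welch t-test on log2(CPM + 1). Genes that are all-zero
#' in both groups get p = 1 and log2FC = 0;
#' genes with missing values in any used sample are dropped (complete-case).
#'
#' @param matrix a raw-count [expr_matrix].
#' @param group_a,group_b character vectors of sample ids (>= 2 each).
#' @param test `"nb_exact"` or `"welch_log"`.
#' @param pseudo_mean pseudo-mean c in CPM units.
#' @return data.frame with `group_id`, `log2fc`, `p`.
#' @export
de_test <- function(matrix, group_a, group_b,
                    test = c("nb_exact", "welch_log"), pseudo_mean = 0.5) {
  stopifnot(inherits(matrix, "expr_matrix"))
  test <- match.arg(test)
  if (matrix$unit != "raw")
    stop("de_test expects raw counts, got unit `", matrix$unit, "`")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples (got ", length(group_a),
         " and ", length(group_b), ")")
  counts <- matrix$values[, c(group_a, group_b), drop = FALSE]
  keep <- stats::complete.cases(counts)
  counts <- counts[keep, , drop = FALSE]
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)

  cpm <- sweep(counts, 2, colSums(counts) / 1e6, "/")
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + pseudo_mean) / (mean_a + pseudo_mean))

  raw_a <- rowSums(counts[, ia, drop = FALSE])
  raw_b <- rowSums(counts[, ib, drop = FALSE])
  all_zero <- raw_a == 0 & raw_b == 0

  p <- if (test == "welch_log") {
    welch_rows(log2(cpm + 1), ia, ib)
  } else {
    nb_exact_rows(counts, ia, ib)
  }
  p[all_zero] <- 1
  log2fc[all_zero] <- 0
  data.frame(group_id = rownames(counts), log2fc = log2fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

## vectorised Welch t-test across matrix rows; x on log scale
welch_rows <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  ## zero within-group variance: identical groups get p = 1, separated p -> 0
  degen <- se2 == 0
  p[degen & (mb - ma) == 0] <- 1
  p[degen & (mb - ma) != 0] <- 0
  p
}

## exact NB test via edgeR's classic pipeline (common + tagwise dispersion,
## then exactTest conditioning on each gene's total count)
nb_exact_rows <- function(counts, ia, ib) {
  grp <- factor(c(rep("a", length(ia)), rep("b", length(ib))),
                levels = c("a", "b"))
  y <- edgeR::DGEList(counts = counts, group = grp)
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y, pair = c("a", "b"))
  et$table$PValue
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, returned in the input order. Thin validating
#' wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of monotone q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply DE thresholds and produce directional sets
#'
#' Adds BH q-values to a [de_test()] result and calls each gene `up`
#' (q <= q_max and FC >= fc_min), `down` (q <= q_max and FC <= 1/fc_min) or
#' `ns`.
#'
#' @param results data.frame from [de_test()] (columns `group_id`, `log2fc`,
#'   `p`), optionally already carrying `q`.
#' @param config a [de_call_config()].
#' @return A list of class `de_calls`: `table` (results plus `q`,
#'   `direction`), `up` and `down` (character vectors of group ids).
#' @export
call_de <- function(results, config = de_call_config()) {
  stopifnot(is.data.frame(results),
            all(c("group_id", "log2fc", "p") %in% names(results)))
  if (!"q" %in% names(results)) results$q <- bh_adjust(results$p)
  lfc_min <- log2(config$fc_min)
  direction <- rep("ns", nrow(results))
  direction[results$q <= config$q_max & results$log2fc >= lfc_min] <- "up"
  direction[results$q <= config$q_max & results$log2fc <= -lfc_min] <- "down"
  results$direction <- direction
  structure(list(table = results,
                 up = results$group_id[direction == "up"],
                 down = results$group_id[direction == "down"],
                 config = config),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("de_calls: %d genes tested, %d up, %d down (q <= %.2g, FC >= %.2g)\n",
              nrow(x$table), length(x$up), length(x$down),
              x$config$q_max, x$config$fc_min))
  invisible(x)
}

#' Directional DE sets for every species and stage transition
#'
#' Convenience driver: for each species matrix and each ordered transition,
#' runs [de_test()] and [call_de()].
#'
#' @param matrices named list of group-keyed raw [expr_matrix] objects, one
#'   per species.
#' @param transitions list of ordered stage pairs, e.g.
#'   `list(c("ICM", "ERSE"))`.
#' @param config a [de_call_config()].
#' @param exclude character vector of sample ids to leave out (QC
#'   exclusions).
#' @return Nested named list: `de_sets[[species]][[\"ICM->ERSE\"]]` is a
#'   `de_calls` object.
#' @export
de_transitions <- function(matrices, transitions, config = de_call_config(),
                           exclude = character(0)) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  lapply(matrices, function(m) {
    out <- lapply(transitions, function(tr) {
      a <- setdiff(group_samples(m, tr[1]), exclude)
      b <- setdiff(group_samples(m, tr[2]), exclude)
      res <- de_test(m, a, b, test = config$test,
                     pseudo_mean = config$pseudo_mean)
      call_de(res, config)
    })
    names(out) <- vapply(transitions, paste, character(1), collapse = "->")
    out
  })
}
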