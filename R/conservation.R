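#' Expected k-way overlap under independent sampling
#'
#' If k sets of sizes n1..nk are each drawn uniformly at random (without
#' replacement) and independently from a universe of N genes, the expected
#' size of their joint intersection is `prod(n_i) / N^(k-1)`; for two sets
#' this is the familiar `n1 * n2 / N`. Observed overlaps divided by this
#' expectation are the "conservation enrichment" reported throughout.
#'
#' @param set_sizes integer vector of set sizes (k >= 2).
#' @param N universe size (> 0).
#' @return The expectation, a single number.
#' @export
expected_overlap <- function(set_sizes, N) {
  if (length(N) != 1 || N <= 0) stop("universe size N must be positive")
  if (length(set_sizes) < 2) stop("need at least two set sizes")
  if (any(set_sizes < 0)) stop("set sizes must be nonnegative")
  if (any(set_sizes > N))
    stop("set size exceeds universe: ",
         paste(set_sizes[set_sizes > N], collapse = ", "), " > ", N)
  ## log space to stay finite for genome-scale N and k = 3
  exp(sum(log(set_sizes)) - (length(set_sizes) - 1) * log(N))
}

#' Exact hypergeometric p-value for a pairwise overlap
#'
#' Upper-tail probability P(X >= k_obs) of observing at least the given
#' overlap between two independent uniform draws of sizes n1 and n2 from a
#' universe of N, where X ~ Hypergeometric(N, n1, n2). Evaluated in log
#' space via `phyper`.
#'
#' @param k_obs observed overlap.
#' @param n1,n2 set sizes.
#' @param N universe size.
#' @param log.p return the natural-log p-value.
#' @return The p-value (1 when `k_obs` is 0).
#' @export
overlap_pvalue <- function(k_obs, n1, n2, N, log.p = FALSE) {
  if (any(c(n1, n2) > N) || N <= 0) stop("set sizes must lie in [0, N], N > 0")
  if (k_obs < 0 || k_obs > min(n1, n2))
    stop("impossible overlap: k_obs = ", k_obs, " outside [0, min(n1, n2)]")
  lp <- stats::phyper(k_obs - 1, n1, N - n1, n2, lower.tail = FALSE,
                      log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Monte-Carlo p-value for a k-way overlap
#'
#' Null model: each of the k sets is drawn uniformly without replacement
#' from the universe, independently of the others. The joint intersection of
#' such draws can be generated by chained hypergeometric draws — given the
#' running intersection has size m, intersecting the next random set of size
#' n leaves Hypergeometric(N, m, n) genes — which is distribution-identical
#' to materialising the sets and intersecting them, and is how draws are
#' generated here. The p-value uses add-one smoothing:
#' `p = (1 + #\{draws >= k_obs\}) / (B + 1)`.
#'
#' @param k_obs observed k-way overlap.
#' @param set_sizes integer vector of the k set sizes.
#' @param N universe size.
#' @param B number of Monte-Carlo draws (>= 1000).
#' @param seed integer seed for the draws.
#' @return A list with `p`, `se` (binomial standard error), `B`, `seed`.
#' @export
kway_pvalue_mc <- function(k_obs, set_sizes, N, B = 10000L, seed = 1L) {
  if (B < 1000) stop("B must be >= 1000 for a stable Monte-Carlo estimate")
  if (any(set_sizes > N) || N <= 0) stop("set sizes must lie in [0, N], N > 0")
  if (k_obs < 0 || k_obs > min(set_sizes))
    stop("impossible overlap: k_obs = ", k_obs, " outside [0, min(sizes)]")
  set.seed(seed)
  ov <- rep(set_sizes[1], B)
  for (n_next in set_sizes[-1])
    ov <- stats::rhyper(B, ov, N - ov, n_next)
  p <- (1 + sum(ov >= k_obs)) / (B + 1)
  list(p = p, se = sqrt(p * (1 - p) / B), B = as.integer(B),
       seed = as.integer(seed), mean_overlap = mean(ov))
}

## literal set-sampling Monte Carlo; reference route for tests
mc_overlap_sets <- function(set_sizes, N, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(i) {
    sets <- lapply(set_sizes, function(n) sample.int(N, n))
    length(Reduce(intersect, sets))
  }, integer(1))
}

## one enrichment row
enrichment_row <- function(label, sets, N, method, B = NA_integer_,
                           seed = NA_integer_) {
  sizes <- lengths(sets)
  k_obs <- length(Reduce(intersect, sets))
  e <- expected_overlap(sizes, N)
  enr <- if (e > 0) k_obs / e else NA_real_
  p <- if (method == "hypergeometric_exact") {
    overlap_pvalue(k_obs, sizes[1], sizes[2], N)
  } else {
    kway_pvalue_mc(k_obs, sizes, N, B = B, seed = seed)$p
  }
  data.frame(comparison = label, k = length(sets), N = N,
             sizes = paste(sizes, collapse = ","),
             observed = k_obs, expected = e, enrichment = enr,
             log2_enrichment = if (!is.na(enr) && enr > 0) log2(enr) else -Inf,
             p = p, method = method, B = B, seed = seed,
             stringsAsFactors = FALSE)
}

#' Conservation-of-DE profile across species
#'
#' For every stage transition and direction, computes all pairwise
#' species-by-species overlap enrichments (exact hypergeometric p) and the
#' three-way enrichment (Monte-Carlo p), each relative to the expected
#' overlap under independent sampling from the orthologue universe. The
#' genes of each three-way intersection (the central Venn territory) are
#' attached as the `"core_genes"` attribute.
#'
#' @param de_sets nested list `de_sets[[species]][[transition]]`, each a
#'   `de_calls` object or a list with `up` / `down` character sets.
#' @param N universe size (number of complete-case 1:1:1 groups).
#' @param B Monte-Carlo draws for the three-way null.
#' @param seed integer seed for the Monte-Carlo draws.
#' @param directions which directions to profile; `"both"` additionally
#'   pools up and down genes into one set per species.
#' @return data.frame of class `conservation_profile` with one row per
#'   (transition, direction, comparison).
#' @export
conservation_profile <- function(de_sets, N, B = 10000L, seed = 1L,
                                 directions = c("up", "down")) {
  if (N <= 0) stop("empty universe")
  species <- names(de_sets)
  if (length(species) < 2) stop("need at least two species")
  transitions <- names(de_sets[[1]])
  get_set <- function(sp, tr, dir) {
    x <- de_sets[[sp]][[tr]]
    if (inherits(x, "de_calls")) x <- x[c("up", "down")]
    if (dir == "both") unique(c(x$up, x$down)) else x[[dir]]
  }
  rows <- list()
  core <- list()
  for (tr in transitions) {
    for (dir in directions) {
      sets <- lapply(species, get_set, tr = tr, dir = dir)
      names(sets) <- species
      pairs <- utils::combn(species, 2, simplify = FALSE)
      for (pr in pairs) {
        lab <- paste(pr, collapse = "&")
        rows[[length(rows) + 1]] <- cbind(
          data.frame(transition = tr, direction = dir,
                     stringsAsFactors = FALSE),
          enrichment_row(lab, sets[pr], N, "hypergeometric_exact"))
      }
      if (length(species) >= 3) {
        rows[[length(rows) + 1]] <- cbind(
          data.frame(transition = tr, direction = dir,
                     stringsAsFactors = FALSE),
          enrichment_row(paste(species, collapse = "&"), sets, N,
                         "monte_carlo", B = as.integer(B),
                         seed = as.integer(seed)))
        core[[paste(tr, dir, sep = ":")]] <- Reduce(intersect, sets)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "core_genes") <- core
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' @export
print.conservation_profile <- function(x, digits = 3, ...) {
  cat("conservation of differential expression (observed / expected overlap)\n")
  df <- as.data.frame(x)
  df$expected <- signif(df$expected, digits)
  df$enrichment <- signif(df$enrichment, digits)
  df$log2_enrichment <- signif(df$log2_enrichment, digits)
  df$p <- signif(df$p, digits)
  print(df[, c("transition", "direction", "comparison", "observed",
               "expected", "enrichment", "p", "method")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.conservation_profile <- function(x, ...) {
  df <- as.data.frame(x)
  lab <- paste(df$transition, df$direction, df$comparison)
  graphics::barplot(df$enrichment, names.arg = lab, las = 2,
                    ylab = "overlap enrichment (obs / exp)",
                    cex.names = 0.6, ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' In vivo versus in vitro DE-overlap grid
#'
#' Crosses every (in vivo transition, direction) set with every (in vitro
#' transition, direction) set and reports the log2 overlap enrichment with
#' an exact pairwise hypergeometric p-value. Cells with zero observed
#' overlap but positive expectation carry a `-Inf` log2 enrichment sentinel
#' (their p is 1).
#'
#' @param invivo_sets named list `[[transition]]` of `de_calls` or
#'   `list(up=, down=)` — e.g. the conserved cross-species sets.
#' @param invitro_sets same structure for the culture-state transitions
#'   (2i->serum, serum->EpiSC, 2i->EpiSC).
#' @param N universe size.
#' @return data.frame of class `overlap_grid`: one row per cell with
#'   `invivo`, `invivo_direction`, `invitro`, `invitro_direction`,
#'   `observed`, `expected`, `log2_enrichment`, `p`.
#' @export
invivo_invitro_overlap <- function(invivo_sets, invitro_sets, N) {
  if (N <= 0) stop("empty universe")
  pull <- function(x, dir) {
    if (inherits(x, "de_calls")) x <- x[c("up", "down")]
    x[[dir]]
  }
  rows <- list()
  for (vivo in names(invivo_sets)) for (dv in c("up", "down")) {
    a <- pull(invivo_sets[[vivo]], dv)
    for (vitro in names(invitro_sets)) for (dt in c("up", "down")) {
      b <- pull(invitro_sets[[vitro]], dt)
      k_obs <- length(intersect(a, b))
      e <- expected_overlap(c(length(a), length(b)), N)
      p <- if (length(a) && length(b)) {
        overlap_pvalue(k_obs, length(a), length(b), N)
      } else 1
      l2 <- if (e > 0 && k_obs > 0) log2(k_obs / e) else -Inf
      rows[[length(rows) + 1]] <- data.frame(
        invivo = vivo, invivo_direction = dv, invitro = vitro,
        invitro_direction = dt, n_invivo = length(a), n_invitro = length(b),
        observed = k_obs, expected = e, log2_enrichment = l2, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("overlap_grid", "data.frame")
  out
}

#' @export
print.overlap_grid <- function(x, digits = 3, ...) {
  cat("in vivo x in vitro DE overlap enrichment (log2 obs/exp)\n")
  df <- as.data.frame(x)
  df$expected <- signif(df$expected, digits)
  df$log2_enrichment <- signif(df$log2_enrichment, digits)
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-species conserved directional DE sets
#'
#' Genes called DE in the same direction in at least `min_species` of the
#' profiled species, per transition.
#'
#' @param de_sets nested list as for [conservation_profile()].
#' @param min_species minimum number of species agreeing (default all).
#' @return Named list `[[transition]]$up` / `$down` of group-id vectors.
#' @export
conserved_sets <- function(de_sets, min_species = length(de_sets)) {
  species <- names(de_sets)
  transitions <- names(de_sets[[1]])
  pull <- function(sp, tr, dir) {
    x <- de_sets[[sp]][[tr]]
    if (inherits(x, "de_calls")) x <- x[c("up", "down")]
    x[[dir]]
  }
  out <- lapply(transitions, function(tr) {
    one <- lapply(c(up = "up", down = "down"), function(dir) {
      ids <- unlist(lapply(species, pull, tr = tr, dir = dir))
      tab <- table(ids)
      names(tab)[tab >= min_species]
    })
    one
  })
  names(out) <- transitions
  out
}
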