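# counts crafted so every column totals 1e6, making CPM equal to raw counts
cpm_exact_em <- function(gene_counts, groups) {
  filler <- 1e6 - colSums(gene_counts)
  counts <- rbind(gene_counts, filler = filler)
  toy_em(counts, groups = groups)
}

test_that("identical groups give log2FC 0 everywhere and reversal negates it", {
  set.seed(1)
  g <- matrix(rnbinom(40, mu = 50, size = 10), nrow = 10)
  em <- cpm_exact_em(cbind(g, g), groups = rep(c("a", "b"), each = 4))
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  res <- de_test(em, a, b, test = "welch_log")
  expect_true(all(res$log2fc == 0))
  rev <- de_test(em, b, a, test = "welch_log")
  expect_equal(rev$log2fc, -res$log2fc)
})

test_that("fold change is the pseudo-mean log ratio of CPM means", {
  g <- matrix(c(10, 10, 20, 20,
                5, 15, 30, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  em <- cpm_exact_em(g, groups = rep(c("a", "b"), each = 2))
  res <- de_test(em, c("s1", "s2"), c("s3", "s4"), test = "welch_log",
                 pseudo_mean = 0)
  expect_equal(res$log2fc[res$group_id == "g1"], 1)      # means 10 vs 20
  expect_equal(res$log2fc[res$group_id == "g2"], 1)      # means 10 vs 20
  # suppressed: edgeR's dispersion loess complains on a 3-gene matrix
  res5 <- suppressWarnings(de_test(em, c("s1", "s2"), c("s3", "s4"),
                                   pseudo_mean = 0.5))
  expect_equal(res5$log2fc[res5$group_id == "g1"], log2(20.5 / 10.5))
})

test_that("all-zero genes get p = 1 and FC 0; single-sample groups error", {
  g <- matrix(c(0, 0, 0, 0, 10, 12, 9, 11), nrow = 2, byrow = TRUE,
              dimnames = list(c("dead", "live"), NULL))
  em <- cpm_exact_em(g, groups = rep(c("a", "b"), each = 2))
  for (tst in c("welch_log", "nb_exact")) {
    # suppressed: edgeR's dispersion loess complains on a 3-gene matrix
    res <- suppressWarnings(de_test(em, c("s1", "s2"), c("s3", "s4"),
                                    test = tst))
    expect_equal(res$p[res$group_id == "dead"], 1)
    expect_equal(res$log2fc[res$group_id == "dead"], 0)
  }
  expect_error(de_test(em, "s1", c("s3", "s4")), "at least 2 samples")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.017), 0.017)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("BH agrees with a brute-force step-up oracle on random vectors", {
  # oracle: sort, q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- numeric(n)
    for (i in seq_len(n))
      q_sorted[i] <- min(1, min(sort(p)[i:n] * n / (i:n)))
    q <- numeric(n)
    q[o] <- q_sorted
    q
  }
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    p <- runif(n)
    if (rep %% 3 == 0) p <- round(p, 1)  # provoke ties
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("directional calls respect both thresholds and stay disjoint", {
  res <- data.frame(group_id = c("a", "b", "c", "d"),
                    log2fc = c(log2(3), log2(1.4), 1, -2),
                    p = c(0.2, 0.001, 0.01, 0.01),
                    q = c(0.30, 0.01, 0.10, 0.02))
  calls <- call_de(res, de_call_config(q_max = 0.25, fc_min = 1.5))
  tab <- calls$table
  expect_equal(tab$direction[tab$group_id == "a"], "ns")  # q above 0.25
  expect_equal(tab$direction[tab$group_id == "b"], "ns")  # FC below 1.5
  expect_equal(tab$direction[tab$group_id == "c"], "up")
  expect_equal(tab$direction[tab$group_id == "d"], "down")
  expect_length(intersect(calls$up, calls$down), 0)
})

test_that("swapping group labels maps the up set onto the down set", {
  set.seed(5)
  em <- null_counts(300, 3)
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  fwd <- call_de(de_test(em, a, b), de_call_config(q_max = 0.6, fc_min = 1.2))
  bwd <- call_de(de_test(em, b, a), de_call_config(q_max = 0.6, fc_min = 1.2))
  expect_setequal(fwd$up, bwd$down)
  expect_setequal(fwd$down, bwd$up)
})

test_that("both tests hold their size on null negative-binomial data", {
  # planted-null simulation: fold 1, phi = 0.1, 3 vs 3 replicates; the
  # empirical type-I error at p < 0.05 must sit in [0.03, 0.07]
  set.seed(314)
  type_one <- function(test, reps, n_genes) {
    hits <- 0; total <- 0
    for (r in seq_len(reps)) {
      em <- null_counts(n_genes, 3)
      p <- de_test(em, paste0("s", 1:3), paste0("s", 4:6), test = test)$p
      hits <- hits + sum(p < 0.05)
      total <- total + length(p)
    }
    hits / total
  }
  welch <- type_one("welch_log", reps = 200, n_genes = 2000)
  expect_gt(welch, 0.03); expect_lt(welch, 0.07)
  nb <- type_one("nb_exact", reps = 60, n_genes = 2000)
  expect_gt(nb, 0.03); expect_lt(nb, 0.07)
})
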