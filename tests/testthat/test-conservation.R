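# direct-summation hypergeometric oracle, built from binomial coefficients
# only (independent of phyper)
hyper_upper_oracle <- function(k_obs, n1, n2, N) {
  lo <- max(0, n1 + n2 - N)
  hi <- min(n1, n2)
  if (k_obs <= lo) return(1)
  x <- k_obs:hi
  sum(choose(n1, x) * choose(N - n1, n2 - x)) / choose(N, n2)
}

test_that("expected overlap matches the independence closed form", {
  expect_equal(expected_overlap(c(200, 300), 10000), 6)
  expect_equal(expected_overlap(c(100, 100, 100), 1000), 1)
  expect_equal(expected_overlap(c(5000, 37), 5000), 37)  # one set = universe
  expect_error(expected_overlap(c(20, 5), 10), "exceeds universe")
  expect_error(expected_overlap(c(5, 5), 0), "positive")
})

test_that("pairwise p-values are exact hypergeometric upper tails", {
  expect_equal(overlap_pvalue(0, 5, 5, 10), 1)
  expect_equal(overlap_pvalue(5, 5, 5, 10), 1 / choose(10, 5))  # 1/252
  expect_equal(overlap_pvalue(5, 10, 10, 100),
               hyper_upper_oracle(5, 10, 10, 100))
  set.seed(8)
  for (rep in 1:30) {
    N <- sample(5:60, 1)
    n1 <- sample(0:N, 1); n2 <- sample(0:N, 1)
    k <- sample(0:min(n1, n2), 1)
    expect_equal(overlap_pvalue(k, n1, n2, N),
                 hyper_upper_oracle(k, n1, n2, N))
  }
  expect_error(overlap_pvalue(6, 5, 5, 10), "impossible")
  expect_error(overlap_pvalue(1, 11, 5, 10), "\\[0, N\\]")
})

test_that("Monte-Carlo p-values hit the trivial extremes", {
  expect_equal(kway_pvalue_mc(40, c(40, 40, 40), 40, B = 1000)$p, 1)
  expect_equal(kway_pvalue_mc(0, c(5, 6, 7), 100, B = 1000)$p, 1)
  expect_error(kway_pvalue_mc(2, c(5, 6), 100, B = 500), "1000")
  expect_error(kway_pvalue_mc(6, c(5, 6), 100, B = 1000), "impossible")
})

test_that("chained hypergeometric draws match literal set sampling", {
  # the same null realised two ways: chained conditional draws (the
  # implementation) versus materialising the k sets and intersecting
  sizes <- c(12, 15, 18); N <- 40; B <- 4000
  lit <- orthoDE:::mc_overlap_sets(sizes, N, B, seed = 31)
  res <- kway_pvalue_mc(1, sizes, N, B = B, seed = 77)
  expect_lt(abs(mean(lit) - res$mean_overlap),
            3 * sqrt(2 * var(lit) / B))
  for (k in c(2, 4, 6)) {
    p_lit <- (1 + sum(lit >= k)) / (B + 1)
    p_imp <- kway_pvalue_mc(k, sizes, N, B = B, seed = 77)$p
    expect_lt(abs(p_imp - p_lit),
              3 * sqrt(2 * p_imp * (1 - p_imp) / B))
  }
})

test_that("the mean Monte-Carlo overlap converges to the expectation", {
  res <- kway_pvalue_mc(1, c(30, 40, 50), 200, B = 20000, seed = 4)
  expect_lt(abs(res$mean_overlap - expected_overlap(c(30, 40, 50), 200)),
            0.05)
})

test_that("two-set Monte-Carlo p agrees with the exact pairwise p", {
  set.seed(12)
  for (rep in 1:5) {
    N <- sample(100:400, 1)
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    k <- rhyper(1, n1, N - n1, n2) + 1
    k <- min(k, n1, n2)
    exact <- overlap_pvalue(k, n1, n2, N)
    mc <- kway_pvalue_mc(k, c(n1, n2), N, B = 20000, seed = rep)
    expect_lt(abs(mc$p - exact), 3 * max(mc$se, 1 / mc$B))
  }
})

test_that("conservation profile flags planted conservation and is label-invariant", {
  set.seed(2)
  universe <- sprintf("G%04d", 1:2000)
  core <- sample(universe, 50)
  de_sets <- lapply(c(mouse = 1, pig = 2, bovine = 3), function(i)
    list("ICM->ERSE" = list(
      up = union(core, sample(setdiff(universe, core), 150)),
      down = sample(universe, 120))))
  prof <- conservation_profile(de_sets, N = 2000, B = 2000, seed = 9)
  three_up <- prof[prof$comparison == "mouse&pig&bovine" &
                     prof$direction == "up", ]
  expect_gte(three_up$observed, 50)
  expect_gt(three_up$enrichment, 10)
  expect_lte(three_up$p, 0.001)
  expect_true(all(attr(prof, "core_genes")[["ICM->ERSE:up"]] %in%
                    de_sets$mouse[["ICM->ERSE"]]$up))

  # relabelling the universe leaves every statistic unchanged
  perm <- setNames(sample(universe), universe)
  de_perm <- lapply(de_sets, function(sp) lapply(sp, function(tr)
    lapply(tr, function(s) unname(perm[s]))))
  prof_perm <- conservation_profile(de_perm, N = 2000, B = 2000, seed = 9)
  expect_equal(prof_perm$observed, prof$observed)
  expect_equal(prof_perm$enrichment, prof$enrichment)
  expect_equal(prof_perm$p, prof$p)
})

test_that("identical sets achieve the maximal enrichment", {
  s <- sprintf("G%03d", 1:40)
  de_sets <- lapply(c(a = 1, b = 2, c = 3), function(i)
    list(tr = list(up = s, down = character(0))))
  prof <- conservation_profile(de_sets, N = 400, B = 1000, seed = 1,
                               directions = "up")
  row3 <- prof[prof$k == 3, ]
  expect_equal(row3$observed, 40)
  expect_equal(row3$enrichment, 40 / expected_overlap(c(40, 40, 40), 400))
  expect_equal(row3$p, 1 / 1001)  # never reached by the null draws
})

test_that("in vivo / in vitro grid handles identity and disjoint cells", {
  universe <- sprintf("G%03d", 1:500)
  a <- universe[1:30]
  vivo <- list("ICM->ERSE" = list(up = a, down = universe[31:50]))
  vitro <- list("2i->serum" = list(up = a, down = universe[101:120]))
  grid <- invivo_invitro_overlap(vivo, vitro, N = 500)
  ident <- grid[grid$invivo_direction == "up" & grid$invitro_direction == "up", ]
  expect_equal(ident$observed, 30)
  expect_equal(ident$log2_enrichment, log2(30 / (30 * 30 / 500)))
  expect_lt(ident$p, 1e-20)
  disj <- grid[grid$invivo_direction == "down" &
                 grid$invitro_direction == "down", ]
  expect_equal(disj$observed, 0)
  expect_equal(disj$log2_enrichment, -Inf)
  expect_equal(disj$p, 1)
})

test_that("conserved_sets honours the min-species rule", {
  mk <- function(up) list(tr = list(up = up, down = character(0)))
  de_sets <- list(a = mk(c("g1", "g2")), b = mk(c("g1", "g3")),
                  c = mk(c("g1", "g2")))
  expect_equal(conserved_sets(de_sets)$tr$up, "g1")
  expect_setequal(conserved_sets(de_sets, min_species = 2)$tr$up,
                  c("g1", "g2"))
})
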