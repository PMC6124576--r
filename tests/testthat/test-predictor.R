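toy_panel_inputs <- function() {
  # hand-built gene patterns mirroring the marker archetypes:
  #   klf4-like: conserved down in vivo, down 2i->EpiSC, expressed in serum
  #   spic-like: naive pattern but expressed only in 2i
  #   dusp6-like: conserved up in vivo, up already at 2i->serum
  #   sema6a-like: conserved up, up 2i->EpiSC only
  conserved <- list(up = c("dusp6", "sema6a", "lin28b"),
                    down = c("klf4", "spic", "scpep1"))
  invitro_de <- list(
    "2i->serum" = list(up = c("dusp6"), down = c("spic")),
    "serum->EpiSC" = list(up = c("sema6a", "lin28b"), down = c("klf4")),
    "2i->EpiSC" = list(up = c("dusp6", "sema6a", "lin28b"),
                       down = c("klf4", "spic", "scpep1")))
  expressed <- list(
    "2i" = c("klf4", "spic", "scpep1", "dusp6"),
    "serum" = c("klf4", "scpep1", "dusp6", "sema6a"),
    "EpiSC" = c("dusp6", "sema6a", "lin28b"))
  list(conserved = conserved, invitro_de = invitro_de, expressed = expressed)
}

test_that("panel classes follow the in vivo / in vitro evidence rules", {
  x <- toy_panel_inputs()
  panel <- derive_panel(x$conserved, x$invitro_de, x$expressed)
  cls <- setNames(panel$class, panel$group_id)
  expect_equal(cls[["klf4"]], "naive")
  expect_equal(cls[["scpep1"]], "naive")
  expect_equal(cls[["spic"]], "ground_state_restricted")
  expect_equal(cls[["dusp6"]], "transition")
  expect_equal(cls[["sema6a"]], "primed")
  expect_equal(cls[["lin28b"]], "primed")
  # mutually exclusive classes
  expect_equal(anyDuplicated(panel$group_id), 0L)
  # evidence flags reflect the inputs
  expect_true(panel$up_2i_serum[panel$group_id == "dusp6"])
  expect_false(panel$expressed_serum[panel$group_id == "spic"])
})

test_that("genes without the full pattern are omitted", {
  x <- toy_panel_inputs()
  # a conserved-down gene not moving in vitro must not qualify
  x$conserved$down <- c(x$conserved$down, "gata6")
  panel <- derive_panel(x$conserved, x$invitro_de, x$expressed)
  expect_false("gata6" %in% panel$group_id)
  empty <- derive_panel(list(up = character(0), down = character(0)),
                        x$invitro_de, x$expressed)
  expect_equal(nrow(empty), 0)
})

test_that("transitional fractions count shared directional members", {
  expect_equal(unname(transitional_fraction(
    epi_up = c("a", "b", "c", "d"), serum_up = c("a", "b", "e"),
    epi_down = character(0), serum_down = character(0))),
    c(2, 4, 0, 0))
  s <- c("x", "y", "z")
  expect_equal(unname(transitional_fraction(s, s, s, s)), c(3, 3, 3, 3))
  expect_equal(unname(transitional_fraction(c("a"), c("b"), c("c"), c("d"))),
               c(0, 1, 0, 1))
  # restriction to the conserved pool first
  expect_equal(unname(transitional_fraction(
    epi_up = c("a", "b", "c"), serum_up = c("a", "b"),
    epi_down = character(0), serum_down = character(0),
    conserved_up = c("a", "c"))), c(1, 2, 0, 0))
})

score_fixture <- function() {
  set.seed(10)
  naive_g <- paste0("n", 1:4)
  primed_g <- paste0("p", 1:4)
  other_g <- paste0("o", 1:10)
  vals <- rbind(
    matrix(rep(c(10, 10, 2, 2), times = 4), nrow = 4, byrow = TRUE),
    matrix(rep(c(2, 2, 10, 10), times = 4), nrow = 4, byrow = TRUE),
    matrix(6 + rnorm(40, 0, 0.2), nrow = 10))
  dimnames(vals) <- list(c(naive_g, primed_g, other_g), paste0("s", 1:4))
  em <- toy_em(vals, groups = c("2i", "2i", "EpiSC", "EpiSC"),
               unit = "log2cpm")
  panel <- data.frame(group_id = c(naive_g, primed_g),
                      class = rep(c("naive", "primed"), each = 4),
                      stringsAsFactors = FALSE)
  list(em = em, panel = panel)
}

test_that("samples expressing one side of the panel are called accordingly", {
  f <- score_fixture()
  sc <- score_samples(f$em, f$panel)
  expect_equal(sc$call, c("naive-like", "naive-like", "primed-like",
                          "primed-like"))
  expect_equal(sc$delta, sc$naive_score - sc$primed_score)
  # identical samples get identical scores
  expect_equal(sc$naive_score[1], sc$naive_score[2])
  expect_equal(sc$delta[3], sc$delta[4])
})

test_that("scoring ignores gene order and non-panel genes", {
  f <- score_fixture()
  sc <- score_samples(f$em, f$panel)
  shuffled <- f$em
  ord <- rev(seq_len(nrow(shuffled$values)))
  shuffled$values <- shuffled$values[ord, , drop = FALSE]
  expect_equal(score_samples(shuffled, f$panel)$delta, sc$delta)
  trimmed <- f$em
  trimmed$values <- trimmed$values[f$panel$group_id, , drop = FALSE]
  expect_equal(score_samples(trimmed, f$panel)$delta, sc$delta)
})

test_that("insufficient panel coverage is an error, missing genes reported", {
  f <- score_fixture()
  small <- f$panel[c(1, 2, 5, 6, 7), ]  # only 2 naive-side genes
  expect_error(score_samples(f$em, small), "panel coverage insufficient")
  panel2 <- rbind(f$panel,
                  data.frame(group_id = "absent", class = "naive"))
  sc <- score_samples(f$em, panel2)
  expect_equal(attr(sc, "missing_genes"), "absent")
})
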