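#' Derive the naive / primed pluripotency predictor panel
#'
#' Classifies genes by combining conserved in vivo differential expression
#' (ICM to late epiblast, agreeing across species) with the mouse in vitro
#' culture-state transitions:
#' \describe{
#'   \item{naive}{conserved down ICM->late AND down 2i->EpiSC (Klf4-like).}
#'   \item{primed}{conserved up ICM->late AND up 2i->EpiSC (Sema6a-like).}
#'   \item{transition}{primed-pattern genes already up in 2i->serum
#'     (Dusp6-like); removed from the plain primed class.}
#'   \item{ground_state_restricted}{naive-pattern genes expressed in
#'     2i-mESCs but in neither serum-mESCs nor mEpiSCs (Spic-like); removed
#'     from the plain naive class.}
#' }
#' Non-qualifying genes are omitted. The classes are therefore mutually
#' exclusive in the output.
#'
#' @param conserved_sets list with `up` and `down` character vectors: genes
#'   whose ICM->late DE is conserved across species (see [conserved_sets()]).
#' @param invitro_de named list of the in vitro transitions (`"2i->serum"`,
#'   `"serum->EpiSC"`, `"2i->EpiSC"`), each a `de_calls` or
#'   `list(up=, down=)`.
#' @param invitro_expressed named list of expressed gene sets per condition
#'   (`"2i"`, `"serum"`, `"EpiSC"`), from [call_expressed()].
#' @return data.frame of class `predictor_panel`: `group_id`, `class`, and
#'   logical evidence columns (`conserved_up_invivo`, `conserved_down_invivo`,
#'   `up_2i_serum`, `down_2i_serum`, `up_2i_episc`, `down_2i_episc`,
#'   `expressed_2i`, `expressed_serum`, `expressed_episc`).
#' @export
derive_panel <- function(conserved_sets, invitro_de, invitro_expressed) {
  pull <- function(x, dir) {
    if (inherits(x, "de_calls")) x <- x[c("up", "down")]
    x[[dir]]
  }
  epi_up <- pull(invitro_de[["2i->EpiSC"]], "up")
  epi_down <- pull(invitro_de[["2i->EpiSC"]], "down")
  serum_up <- pull(invitro_de[["2i->serum"]], "up")
  serum_down <- pull(invitro_de[["2i->serum"]], "down")

  naive_pattern <- intersect(conserved_sets$down, epi_down)
  primed_pattern <- intersect(conserved_sets$up, epi_up)
  transition <- intersect(primed_pattern, serum_up)
  ground <- setdiff(intersect(naive_pattern, invitro_expressed[["2i"]]),
                    union(invitro_expressed[["serum"]],
                          invitro_expressed[["EpiSC"]]))
  naive <- setdiff(naive_pattern, ground)
  primed <- setdiff(primed_pattern, transition)

  ids <- c(naive, ground, primed, transition)
  if (length(ids) == 0) {
    out <- data.frame(group_id = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      group_id = ids,
      class = c(rep("naive", length(naive)),
                rep("ground_state_restricted", length(ground)),
                rep("primed", length(primed)),
                rep("transition", length(transition))),
      stringsAsFactors = FALSE)
  }
  out$conserved_up_invivo <- out$group_id %in% conserved_sets$up
  out$conserved_down_invivo <- out$group_id %in% conserved_sets$down
  out$up_2i_serum <- out$group_id %in% serum_up
  out$down_2i_serum <- out$group_id %in% serum_down
  out$up_2i_episc <- out$group_id %in% epi_up
  out$down_2i_episc <- out$group_id %in% epi_down
  out$expressed_2i <- out$group_id %in% invitro_expressed[["2i"]]
  out$expressed_serum <- out$group_id %in% invitro_expressed[["serum"]]
  out$expressed_episc <- out$group_id %in% invitro_expressed[["EpiSC"]]
  class(out) <- c("predictor_panel", "data.frame")
  out
}

#' @export
print.predictor_panel <- function(x, ...) {
  cat("pluripotency predictor panel:\n")
  print(table(x$class))
  invisible(x)
}

#' Transitional-state fractions of the culture transitions
#'
#' Of the genes directional in the 2i->EpiSC transition (optionally
#' restricted to the conserved in vivo pool), how many are already
#' directional in 2i->serum — the evidence that serum-mESCs sit between the
#' naive and primed states.
#'
#' @param epi_up,epi_down directional 2i->EpiSC gene sets.
#' @param serum_up,serum_down directional 2i->serum gene sets.
#' @param conserved_up,conserved_down optional conserved in vivo sets to
#'   intersect with first.
#' @return Named integer vector `c(k_up, n_up, k_down, n_down)`: n is the
#'   (restricted) 2i->EpiSC set size, k the members shared with 2i->serum.
#' @export
transitional_fraction <- function(epi_up, serum_up, epi_down, serum_down,
                                  conserved_up = NULL, conserved_down = NULL) {
  if (!is.null(conserved_up)) epi_up <- intersect(epi_up, conserved_up)
  if (!is.null(conserved_down)) epi_down <- intersect(epi_down, conserved_down)
  c(k_up = length(intersect(epi_up, serum_up)),
    n_up = length(unique(epi_up)),
    k_down = length(intersect(epi_down, serum_down)),
    n_down = length(unique(epi_down)))
}

#' Score samples against a predictor panel
#'
#' Each gene's expression is z-scored across the scored samples; a sample's
#' naive score is the mean z over naive-side panel genes (classes `naive`
#' and `ground_state_restricted`) and its primed score the mean over
#' primed-side genes (`primed` and `transition`). Samples are called
#' `naive-like` when naive - primed exceeds `delta_threshold`,
#' `primed-like` below `-delta_threshold`, otherwise `intermediate`.
#'
#' @param matrix an [expr_matrix]; log2 CPM recommended.
#' @param panel a `predictor_panel` from [derive_panel()].
#' @param delta_threshold symmetric call threshold on the score difference
#'   (default 0.5).
#' @return data.frame of class `panel_scores`: `sample_id`, `naive_score`,
#'   `primed_score`, `delta`, `call`. Panel genes absent from the matrix
#'   are reported in the `"missing_genes"` attribute.
#' @export
score_samples <- function(matrix, panel, delta_threshold = 0.5) {
  stopifnot(inherits(matrix, "expr_matrix"), is.data.frame(panel))
  naive_side <- panel$group_id[panel$class %in%
                                 c("naive", "ground_state_restricted")]
  primed_side <- panel$group_id[panel$class %in% c("primed", "transition")]
  present <- rownames(matrix$values)[stats::complete.cases(matrix$values)]
  missing <- setdiff(c(naive_side, primed_side), present)
  naive_side <- intersect(naive_side, present)
  primed_side <- intersect(primed_side, present)
  if (length(naive_side) < 3 || length(primed_side) < 3)
    stop("panel coverage insufficient: need >= 3 naive-side and >= 3 ",
         "primed-side genes in the matrix (have ", length(naive_side),
         " and ", length(primed_side), ")")
  x <- matrix$values[c(naive_side, primed_side), , drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  sd[sd == 0] <- 1  # constant gene: z = 0 everywhere
  z <- (x - mu) / sd
  naive_score <- colMeans(z[naive_side, , drop = FALSE])
  primed_score <- colMeans(z[primed_side, , drop = FALSE])
  delta <- naive_score - primed_score
  call <- ifelse(delta > delta_threshold, "naive-like",
                 ifelse(delta < -delta_threshold, "primed-like",
                        "intermediate"))
  out <- data.frame(sample_id = colnames(x), naive_score = naive_score,
                    primed_score = primed_score, delta = delta, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- missing
  class(out) <- c("panel_scores", "data.frame")
  out
}

#' @export
print.panel_scores <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$naive_score <- signif(df$naive_score, digits)
  df$primed_score <- signif(df$primed_score, digits)
  df$delta <- signif(df$delta, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
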