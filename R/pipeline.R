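#' Run the full cross-species comparison pipeline
#'
#' Executes every stage in order — orthologue mapping, normalisation,
#' replicate QC, per-transition differential expression, cross-species
#' conservation enrichment, the in vivo / in vitro overlap grid, predictor
#' panel derivation and in vitro sample scoring — and (optionally) writes
#' every stage's tables plus a run manifest. A stage failure aborts with the
#' stage name prepended to the underlying error.
#'
#' @param species_matrices named list of per-species raw [expr_matrix]
#'   objects keyed by species gene ids (or already by group ids, see
#'   `mapped`).
#' @param invitro_matrix raw [expr_matrix] of the culture conditions, keyed
#'   like the first species.
#' @param orthologs an [ortholog_table()].
#' @param out_dir output directory; `NULL` to skip writing.
#' @param de_config a [de_call_config()].
#' @param transitions in vivo stage transitions to test.
#' @param invitro_transitions culture transitions to test.
#' @param expressed_min_level,expressed_min_fraction expressed-call rule.
#' @param qc_min_median_r replicate-QC threshold ([flag_outliers()]).
#' @param mc_draws,seed Monte-Carlo settings for the three-way nulls.
#' @param mapped set `TRUE` when the matrices are already group-keyed.
#' @return A list of class `orthoDE_run` with elements `universe_size`,
#'   `qc` (excluded samples per species), `de` (nested de_calls),
#'   `conservation` ([conservation_profile()]), `conserved`
#'   ([conserved_sets()]), `invitro_de`, `grid`
#'   ([invivo_invitro_overlap()]), `transitional`, `panel`
#'   ([derive_panel()]), `scores` ([score_samples()]), and `files` when
#'   `out_dir` was given.
#' @export
run_pipeline <- function(species_matrices, invitro_matrix, orthologs,
                         out_dir = NULL,
                         de_config = de_call_config(),
                         transitions = list(c("ICM", "ERSE"), c("ICM", "APE"),
                                            c("ERSE", "APE")),
                         invitro_transitions = list(c("2i", "serum"),
                                                    c("serum", "EpiSC"),
                                                    c("2i", "EpiSC")),
                         expressed_min_level = 1,
                         expressed_min_fraction = 0.5,
                         qc_min_median_r = 0.7,
                         mc_draws = 10000L, seed = 1L, mapped = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  species <- names(species_matrices)

  mats <- stage("orthology", {
    if (mapped) species_matrices
    else {
      out <- lapply(species, function(s)
        map_to_groups(species_matrices[[s]], orthologs, s))
      names(out) <- species
      out
    }
  })
  vitro <- stage("orthology", {
    if (mapped) invitro_matrix
    else map_to_groups(invitro_matrix, orthologs, species[1])
  })

  universe <- stage("expression", do.call(shared_universe, c(mats, list(vitro))))
  N <- length(universe)
  if (N == 0) stop("pipeline stage `expression` failed: empty shared universe")

  norm <- stage("expression", lapply(mats, normalize_expr, method = "cpm",
                                     log2_offset = 1))
  vitro_norm <- stage("expression", normalize_expr(vitro, method = "cpm",
                                                   log2_offset = 1))

  qc <- stage("qc", lapply(norm, function(m)
    flag_outliers(correlation_cluster(m), min_median_r = qc_min_median_r)))
  excluded <- unlist(qc, use.names = FALSE)

  de <- stage("diffexpr", de_transitions(mats, transitions, de_config,
                                         exclude = excluded))
  conserved <- stage("conservation", conserved_sets(de))
  profile <- stage("conservation",
                   conservation_profile(de, N, B = mc_draws, seed = seed))

  invitro_de <- stage("diffexpr",
                      de_transitions(list(invitro = vitro), invitro_transitions,
                                     de_config)$invitro)
  grid <- stage("conservation",
                invivo_invitro_overlap(conserved, invitro_de, N))

  expressed <- stage("expression", {
    conds <- unique(vitro_norm$samples$group)
    out <- lapply(conds, function(g)
      call_expressed(vitro_norm, g, min_level = expressed_min_level,
                     min_fraction = expressed_min_fraction))
    names(out) <- conds
    out
  })

  late_key <- intersect(c("ICM->ERSE", "ICM->APE"), names(conserved))
  conserved_late <- list(
    up = unique(unlist(lapply(conserved[late_key], `[[`, "up"))),
    down = unique(unlist(lapply(conserved[late_key], `[[`, "down"))))

  panel <- stage("predictor",
                 derive_panel(conserved_late, invitro_de, expressed))
  trans_frac <- stage("predictor", transitional_fraction(
    epi_up = invitro_de[["2i->EpiSC"]]$up,
    serum_up = invitro_de[["2i->serum"]]$up,
    epi_down = invitro_de[["2i->EpiSC"]]$down,
    serum_down = invitro_de[["2i->serum"]]$down,
    conserved_up = conserved_late$up, conserved_down = conserved_late$down))
  scores <- stage("predictor", {
    if (sum(panel$class %in% c("naive", "ground_state_restricted")) >= 3 &&
        sum(panel$class %in% c("primed", "transition")) >= 3)
      score_samples(vitro_norm, panel)
    else NULL
  })

  result <- structure(list(universe_size = N, qc = qc, de = de,
                           conserved = conserved, conservation = profile,
                           invitro_de = invitro_de, grid = grid,
                           transitional = trans_frac, panel = panel,
                           scores = scores, seed = seed),
                      class = "orthoDE_run")
  if (!is.null(out_dir))
    result$files <- stage("output", write_run(result, out_dir, seed))
  result
}

write_run <- function(result, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = seed, universe = result$universe_size)
  files <- c()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_commented(as.data.frame(df), p, meta)
    files <<- c(files, p)
  }
  de_tab <- do.call(rbind, lapply(names(result$de), function(sp) {
    do.call(rbind, lapply(names(result$de[[sp]]), function(tr) {
      tab <- result$de[[sp]][[tr]]$table
      cbind(data.frame(species = sp, transition = tr,
                       stringsAsFactors = FALSE), tab)
    }))
  }))
  emit(de_tab, "differential_expression.tsv")
  emit(result$conservation, "conservation_profile.tsv")
  emit(result$grid, "invivo_invitro_grid.tsv")
  emit(result$panel, "predictor_panel.tsv")
  if (!is.null(result$scores)) emit(result$scores, "panel_scores.tsv")
  manifest <- list(
    tool = paste0("orthoDE ", as.character(utils::packageVersion("orthoDE"))),
    seed = seed, universe_size = result$universe_size,
    excluded_samples = result$qc,
    transitional_fraction = as.list(result$transitional),
    files = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, manifest = mp)
}

#' @export
print.orthoDE_run <- function(x, ...) {
  cat(sprintf("orthoDE run: universe of %d orthologue groups\n",
              x$universe_size))
  excl <- unlist(x$qc, use.names = FALSE)
  cat(sprintf("QC-excluded samples: %s\n",
              if (length(excl)) paste(excl, collapse = ", ") else "none"))
  cat(sprintf("predictor panel: %d genes\n", nrow(x$panel)))
  tf <- x$transitional
  cat(sprintf("transitional fractions: up %d/%d, down %d/%d\n",
              tf["k_up"], tf["n_up"], tf["k_down"], tf["n_down"]))
  invisible(x)
}
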