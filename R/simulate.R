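#' Configuration for the multi-species embryo count simulator
#'
#' Defines the study layout the simulator emulates: three species profiled at
#' three in vivo epiblast stages (ICM, ERSE, APE) plus three mouse in vitro
#' pluripotent states (2i-mESC, serum-mESC, mEpiSC), negative-binomial counts
#' over a shared 1:1:1 orthologue universe with planted conserved,
#' species-specific and culture-state effects.
#'
#' Planted gene classes:
#' \describe{
#'   \item{conserved_up / conserved_down}{differentially expressed in the same
#'     direction in all three species at the ICM to ERSE transition; the
#'     effect persists through APE. Conserved genes are mirrored in vitro:
#'     up genes rise from 2i to EpiSC, down genes fall.}
#'   \item{transition}{the fraction `transition_fraction` of conserved-up
#'     genes whose primed-state upregulation is already present in
#'     serum-mESCs (Dusp6/Trip6-like).}
#'   \item{ground_state_restricted}{naive-pattern genes expressed only in the
#'     ICM and in 2i-mESCs (Spic-like); elsewhere the mean drops to a small
#'     leak mean rather than exactly zero.}
#'   \item{species_specific}{differentially expressed in exactly one species
#'     (half up, half down per species); not propagated in vitro.}
#'   \item{null}{no planted effect.}
#' }
#'
#' @param n_orthologs universe size N (default 11444, the scale of a
#'   three-mammal 1:1:1 orthologue set).
#' @param species character vector of exactly three species labels.
#' @param stages ordered in vivo stage labels (subset of the default allowed,
#'   must start at the first stage).
#' @param conditions ordered in vitro condition labels.
#' @param replicates replicates per species/stage and per condition (>= 2).
#' @param baseline_mean_log,baseline_sd_log log-normal parameters of the
#'   per-gene baseline mean expression (natural-log scale).
#' @param dispersion negative-binomial dispersion phi (> 0), giving
#'   variance mu + phi * mu^2.
#' @param library_size_range range of uniform per-sample library-size
#'   factors.
#' @param n_conserved_up,n_conserved_down numbers of conserved DE genes.
#' @param n_species_specific species-specific DE genes per species.
#' @param planted_fold linear fold change f (>= 1) of planted effects.
#' @param n_ground_state number of ground-state-restricted genes.
#' @param transition_fraction fraction of conserved-up genes already elevated
#'   in serum-mESCs (default 29/44).
#' @param leak_mean mean count of "off" groups of ground-state genes.
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_orthologs = 11444L,
                       species = c("mouse", "pig", "bovine"),
                       stages = c("ICM", "ERSE", "APE"),
                       conditions = c("2i", "serum", "EpiSC"),
                       replicates = 3L,
                       baseline_mean_log = log(100),
                       baseline_sd_log = 1,
                       dispersion = 0.1,
                       library_size_range = c(0.7, 1.3),
                       n_conserved_up = 50L,
                       n_conserved_down = 50L,
                       n_species_specific = 150L,
                       planted_fold = 4,
                       n_ground_state = 5L,
                       transition_fraction = 29 / 44,
                       leak_mean = 0.05,
                       seed = 1L) {
  cfg <- list(n_orthologs = as.integer(n_orthologs), species = species,
              stages = stages, conditions = conditions,
              replicates = as.integer(replicates),
              baseline_mean_log = baseline_mean_log,
              baseline_sd_log = baseline_sd_log, dispersion = dispersion,
              library_size_range = library_size_range,
              n_conserved_up = as.integer(n_conserved_up),
              n_conserved_down = as.integer(n_conserved_down),
              n_species_specific = as.integer(n_species_specific),
              planted_fold = planted_fold,
              n_ground_state = as.integer(n_ground_state),
              transition_fraction = transition_fraction,
              leak_mean = leak_mean, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, why) stop("invalid simulation config: `", field,
                                   "` ", why, call. = FALSE)
  if (cfg$n_orthologs < 1) err("n_orthologs", "must be positive")
  if (length(cfg$species) != 3) err("species", "must list exactly 3 species")
  if (anyDuplicated(cfg$species)) err("species", "must be distinct")
  if (length(cfg$stages) < 2) err("stages", "must contain at least 2 stages")
  if (cfg$replicates < 2) err("replicates", "must be >= 2")
  if (cfg$baseline_sd_log < 0) err("baseline_sd_log", "must be >= 0")
  if (cfg$dispersion <= 0) err("dispersion", "must be > 0")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    err("library_size_range", "must be an increasing pair of positive reals")
  for (f in c("n_conserved_up", "n_conserved_down", "n_species_specific",
              "n_ground_state"))
    if (cfg[[f]] < 0) err(f, "must be >= 0")
  if (cfg$planted_fold < 1) err("planted_fold", "must be >= 1")
  if (cfg$transition_fraction < 0 || cfg$transition_fraction > 1)
    err("transition_fraction", "must be in [0, 1]")
  if (cfg$leak_mean < 0) err("leak_mean", "must be >= 0")
  n_planted <- cfg$n_conserved_up + cfg$n_conserved_down +
    cfg$n_ground_state + 3L * cfg$n_species_specific
  if (n_planted > cfg$n_orthologs)
    err("n_orthologs", sprintf(
      "too small: %d planted genes exceed the universe of %d",
      n_planted, cfg$n_orthologs))
  invisible(cfg)
}

#' Simulate a three-species embryo / stem-cell expression study
#'
#' Draws negative-binomial counts (mean mu, variance mu + phi * mu^2) for
#' each species over the in vivo stages and for the mouse in vitro
#' conditions, over a shared orthologue universe with planted effects as
#' described in [sim_config()]. Per-gene baseline means are log-normal and
#' shared across species; each sample gets an independent uniform
#' library-size factor.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `epiblast_sim` with elements:
#' \describe{
#'   \item{species}{named list of per-species [expr_matrix] objects (raw
#'     counts, keyed by species gene ids).}
#'   \item{invitro}{[expr_matrix] of the in vitro conditions (keyed by the
#'     first species' gene ids).}
#'   \item{orthologs}{orthologue table mapping group ids to one gene id per
#'     species (see [ortholog_table()]).}
#'   \item{truth}{data.frame with one row per gene: `group_id`, `class`,
#'     `species` (for species-specific genes), `direction`, `fold`.}
#'   \item{config}{the config used.}
#' }
#' @export
simulate_epiblast <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  N <- config$n_orthologs
  f <- config$planted_fold
  group_ids <- sprintf("OG%05d", seq_len(N))

  ## gene class assignment
  cls <- rep("null", N)
  direction <- rep(NA_character_, N)
  cls_species <- rep(NA_character_, N)
  n_trans <- round(config$transition_fraction * config$n_conserved_up)
  take <- sample.int(N, config$n_conserved_up + config$n_conserved_down +
                       config$n_ground_state +
                       3L * config$n_species_specific)
  pos <- 0L
  grab <- function(n) {
    out <- take[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  i_up <- grab(config$n_conserved_up)
  i_down <- grab(config$n_conserved_down)
  i_ground <- grab(config$n_ground_state)
  i_species <- lapply(config$species, function(s) grab(config$n_species_specific))
  names(i_species) <- config$species
  i_trans <- i_up[seq_len(n_trans)]

  cls[i_up] <- "conserved_up"; direction[i_up] <- "up"
  cls[i_trans] <- "transition"
  cls[i_down] <- "conserved_down"; direction[i_down] <- "down"
  cls[i_ground] <- "ground_state_restricted"; direction[i_ground] <- "down"
  for (s in config$species) {
    idx <- i_species[[s]]
    cls[idx] <- "species_specific"
    cls_species[idx] <- s
    half <- seq_len(length(idx)) <= length(idx) / 2
    direction[idx[half]] <- "up"
    direction[idx[!half]] <- "down"
  }

  baseline <- stats::rlnorm(N, config$baseline_mean_log, config$baseline_sd_log)

  late <- setdiff(config$stages, config$stages[1])
  mean_for <- function(species, grp) {
    mu <- baseline
    is_late <- grp %in% late
    if (is_late) {
      mu[i_up] <- baseline[i_up] * f
      mu[i_down] <- baseline[i_down] / f
      mu[i_ground] <- config$leak_mean
      idx <- i_species[[species]]
      up <- idx[direction[idx] == "up"]
      dn <- idx[direction[idx] == "down"]
      mu[up] <- baseline[up] * f
      mu[dn] <- baseline[dn] / f
    }
    mu
  }
  mean_for_condition <- function(cond) {
    mu <- baseline
    if (cond == "serum") {
      mu[i_trans] <- baseline[i_trans] * f
      mu[i_ground] <- config$leak_mean
    } else if (cond == "EpiSC") {
      mu[i_up] <- baseline[i_up] * f
      mu[i_down] <- baseline[i_down] / f
      mu[i_ground] <- config$leak_mean
    }
    mu
  }

  draw_counts <- function(mu_by_group, gene_ids, species_label) {
    groups <- names(mu_by_group)
    n_samp <- length(groups) * config$replicates
    lib <- stats::runif(n_samp, config$library_size_range[1],
                        config$library_size_range[2])
    counts <- matrix(0L, nrow = N, ncol = n_samp)
    meta <- data.frame(sample_id = character(n_samp),
                       species = species_label,
                       group = rep(groups, each = config$replicates),
                       replicate = rep(seq_len(config$replicates),
                                       times = length(groups)),
                       stringsAsFactors = FALSE)
    meta$sample_id <- paste(species_label, meta$group, meta$replicate,
                            sep = "_")
    for (j in seq_len(n_samp)) {
      mu <- mu_by_group[[meta$group[j]]] * lib[j]
      counts[, j] <- stats::rnbinom(N, mu = mu, size = 1 / config$dispersion)
    }
    rownames(counts) <- gene_ids
    colnames(counts) <- meta$sample_id
    expr_matrix(counts, meta, unit = "raw")
  }

  gene_ids_for <- function(species) paste0(substr(species, 1, 3), "_", group_ids)

  species_mats <- lapply(config$species, function(s) {
    mus <- lapply(config$stages, function(g) mean_for(s, g))
    names(mus) <- config$stages
    draw_counts(mus, gene_ids_for(s), s)
  })
  names(species_mats) <- config$species

  mus_vitro <- lapply(config$conditions, mean_for_condition)
  names(mus_vitro) <- config$conditions
  invitro <- draw_counts(mus_vitro, gene_ids_for(config$species[1]),
                         config$species[1])

  ortho <- data.frame(group_id = group_ids, stringsAsFactors = FALSE)
  for (s in config$species) ortho[[paste0(s, "_gene")]] <- gene_ids_for(s)
  ortho <- ortholog_table(ortho, species = config$species)

  truth <- data.frame(group_id = group_ids, class = cls,
                      species = cls_species, direction = direction,
                      fold = ifelse(cls == "null", 1, f),
                      stringsAsFactors = FALSE)

  structure(list(species = species_mats, invitro = invitro,
                 orthologs = ortho, truth = truth, config = config),
            class = "epiblast_sim")
}

#' @export
print.epiblast_sim <- function(x, ...) {
  cat(sprintf("epiblast_sim: %d orthologue groups, species %s\n",
              x$config$n_orthologs, paste(x$config$species, collapse = ", ")))
  cat("planted classes:\n")
  print(table(x$truth$class))
  invisible(x)
}
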