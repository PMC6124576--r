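# Fixtures built in code: tiny expression matrices and small simulation
# configs shared across test files.

toy_em <- function(counts, groups, species = "mouse", unit = "raw") {
  n <- ncol(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(n))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  reps <- stats::ave(seq_len(n), groups, FUN = seq_along)
  expr_matrix(counts,
              data.frame(sample_id = colnames(counts), species = species,
                         group = groups, replicate = reps,
                         stringsAsFactors = FALSE),
              unit = unit)
}

# random two-group NB count matrix under the null
null_counts <- function(n_genes, n_per_group, mu_meanlog = log(100),
                        phi = 0.1) {
  mu <- stats::rlnorm(n_genes, mu_meanlog, 1)
  counts <- matrix(stats::rnbinom(n_genes * 2 * n_per_group,
                                  mu = rep(mu, 2 * n_per_group),
                                  size = 1 / phi),
                   nrow = n_genes)
  toy_em(counts, groups = rep(c("a", "b"), each = n_per_group))
}

small_null_config <- function(seed, n = 2000L) {
  sim_config(n_orthologs = n, n_conserved_up = 0L, n_conserved_down = 0L,
             n_species_specific = 0L, n_ground_state = 0L,
             stages = c("ICM", "ERSE"), seed = seed)
}

recovery_config <- function(seed, n = 2000L, stages = c("ICM", "ERSE")) {
  sim_config(n_orthologs = n, n_conserved_up = 50L, n_conserved_down = 50L,
             n_species_specific = 0L, n_ground_state = 0L,
             planted_fold = 4, dispersion = 0.1, replicates = 3L,
             transition_fraction = 0, stages = stages, seed = seed)
}

toy_ortho_df <- function(n = 3, species = c("mouse", "pig", "bovine")) {
  df <- data.frame(group_id = sprintf("OG%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (s in species)
    df[[paste0(s, "_gene")]] <- sprintf("%s_g%03d", substr(s, 1, 3), seq_len(n))
  df
}
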