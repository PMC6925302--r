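# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# small noisy two-study pair (NB counts) for module-level tests
small_sim <- function() {
  if (is.null(fixture_env$small_sim)) {
    fixture_env$small_sim <- simulate_pair(sim_config(
      n_genes = 200, n_lines = 30, n_late_essential = 10, n_ssd = 4,
      n_decoy_features = 5, n_expression_background = 30, seed = 101))
  }
  fixture_env$small_sim
}

# noiseless pair: deterministic expected counts, no batch terms, perfect
# guides, no line effects; scores must reproduce the truth exactly
noiseless_sim <- function() {
  if (is.null(fixture_env$noiseless_sim)) {
    fixture_env$noiseless_sim <- simulate_pair(sim_config(
      n_genes = 300, n_lines = 30, n_late_essential = 15, n_ssd = 5,
      count_model = "expected", line_effect_sd = 0,
      batch_shift_sd = 0, batch_scale_sd = 0, noise_sd_range = c(0, 0),
      guide_efficacy_params = list(A = NULL, B = NULL),
      n_decoy_features = 3, n_expression_background = 20, seed = 7))
  }
  fixture_env$noiseless_sim
}

sim_refs <- function(sim) {
  reference_sets(sim$truth$essential_genes, sim$truth$nonessential_genes)
}

sim_map <- function(sim, lib) sim$guide_map[sim$guide_map$library == lib, ]

sim_scores <- function(sim, which = "study_a") {
  lib <- unique(sim[[which]]$meta$library)
  score_screen(sim[[which]], sim_map(sim, lib), sim_refs(sim))
}

# deterministic toy gene x line matrix with named dims
toy_matrix <- function(values, genes = NULL, lines = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(lines)) lines <- sprintf("l%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, lines)
  m
}
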