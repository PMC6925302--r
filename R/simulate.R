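#' Configuration for the two-study synthetic screen generator
#'
#' Defines the ground-truth structure and nuisance parameters of a pair of
#' pooled CRISPR-Cas9 dropout screens of the same cell-line panel performed
#' with different sgRNA libraries and assay lengths, mirroring the contrasts
#' between two independently run institute pipelines: different guide
#' efficacies (4 vs 5 guides per gene), a longer time point in study B that
#' further depletes late-acting essential genes, shared common essentials,
#' strongly selective dependencies (SSDs) driven by binary biomarkers, and
#' additive/multiplicative per-gene batch effects plus per-screen noise.
#'
#' @param n_genes number of genes.
#' @param n_lines number of cell lines (screened by both studies).
#' @param n_guides_per_gene named integer vector, guides per gene per library
#'   (default `c(A = 4, B = 5)`).
#' @param frac_common_essential fraction of genes essential in every line.
#' @param n_late_essential number of late-acting essential genes: moderately
#'   depleted at the 14-day readout, further depleted by
#'   `effect_late_extra` at study B's 21-day readout.
#' @param n_ssd number of strongly selective dependency genes, each depleted
#'   only in the lines positive for its planted binary biomarker.
#' @param effect_essential true log2 fold change of common essentials
#'   (default -1, the scale the reference-set normalization anchors to).
#' @param effect_late_base depletion of late essentials at the short (14-day)
#'   time point.
#' @param effect_late_extra additional depletion of late essentials at the
#'   long (21-day) time point (study B).
#' @param ssd_effect depletion of an SSD gene in its biomarker-positive lines.
#' @param frac_ssd_expression fraction of SSD genes that additionally get a
#'   planted expression correlate (random sign) in the expression matrix.
#' @param guide_efficacy_params per-library `c(shape1, shape2)` of the Beta
#'   distribution guide efficacies are drawn from; efficacy scales the gene
#'   effect multiplicatively (low-efficacy guides deplete less). A `NULL`
#'   entry gives a library of perfectly efficient guides (efficacy 1).
#' @param line_effect_sd SD of the shared per-gene-per-line biological
#'   variability (true cell-line-specific dependency signal, identical in
#'   both studies; this is what makes a line's profile recognizable).
#' @param batch_shift_sd SD of the per-gene additive batch shift applied to
#'   study B.
#' @param batch_scale_sd SD of the per-gene multiplicative batch effect
#'   (study B gene effects are scaled by `1 + scale_g`).
#' @param noise_sd_range interval the per-screen residual SD is drawn from
#'   uniformly (one draw per study x line; controls screen quality).
#' @param dispersion negative-binomial dispersion of read counts
#'   (`size = 1/dispersion`); 0 means Poisson.
#' @param reads_per_sample sequencing depth per sample.
#' @param n_replicates screen replicates per cell line.
#' @param n_pdna_samples pDNA reference profiles per library batch.
#' @param pdna_sdlog log-normal SD of relative pDNA guide abundance.
#' @param n_decoy_features number of planted biomarker-free binary features.
#' @param n_expression_background number of background expression genes.
#' @param count_model "nb" (default), "poisson", or "expected" (deterministic
#'   expected counts, used for noiseless identity checks).
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600, n_lines = 147,
                       n_guides_per_gene = c(A = 4L, B = 5L),
                       frac_common_essential = 0.15,
                       n_late_essential = 30, n_ssd = 10,
                       effect_essential = -1,
                       effect_late_base = -0.5, effect_late_extra = -0.4,
                       ssd_effect = -2, frac_ssd_expression = 0.5,
                       guide_efficacy_params = list(A = c(8, 2), B = c(7, 2)),
                       line_effect_sd = 0.1,
                       batch_shift_sd = 0.1, batch_scale_sd = 0.05,
                       noise_sd_range = c(0.1, 0.3),
                       dispersion = 0.1, reads_per_sample = 5e5,
                       n_replicates = 2, n_pdna_samples = 2, pdna_sdlog = 0.5,
                       n_decoy_features = 20, n_expression_background = 100,
                       count_model = c("nb", "poisson", "expected"),
                       seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
              n_guides_per_gene = n_guides_per_gene,
              frac_common_essential = frac_common_essential,
              n_late_essential = as.integer(n_late_essential),
              n_ssd = as.integer(n_ssd),
              effect_essential = effect_essential,
              effect_late_base = effect_late_base,
              effect_late_extra = effect_late_extra,
              ssd_effect = ssd_effect,
              frac_ssd_expression = frac_ssd_expression,
              guide_efficacy_params = guide_efficacy_params,
              line_effect_sd = line_effect_sd,
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              noise_sd_range = noise_sd_range,
              dispersion = dispersion,
              reads_per_sample = reads_per_sample,
              n_replicates = as.integer(n_replicates),
              n_pdna_samples = as.integer(n_pdna_samples),
              pdna_sdlog = pdna_sdlog,
              n_decoy_features = as.integer(n_decoy_features),
              n_expression_background = as.integer(n_expression_background),
              count_model = count_model, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg)
  stopifnot_msg(cfg$n_genes > 0 && cfg$n_lines > 0, "counts must be positive")
  stopifnot_msg(all(cfg$n_guides_per_gene >= 1), "need >=1 guide per gene")
  stopifnot_msg(length(cfg$n_guides_per_gene) == 2 &&
                !is.null(names(cfg$n_guides_per_gene)),
                "n_guides_per_gene must name two libraries")
  stopifnot_msg(cfg$frac_common_essential >= 0 && cfg$frac_common_essential <= 1,
                "frac_common_essential must be in [0,1]")
  stopifnot_msg(cfg$frac_ssd_expression >= 0 && cfg$frac_ssd_expression <= 1,
                "frac_ssd_expression must be in [0,1]")
  n_ess <- round(cfg$frac_common_essential * cfg$n_genes)
  stopifnot_msg(n_ess + cfg$n_late_essential + cfg$n_ssd <= cfg$n_genes,
                "essential + late + SSD genes exceed n_genes")
  stopifnot_msg(cfg$reads_per_sample > 0, "reads_per_sample must be positive")
  stopifnot_msg(cfg$dispersion >= 0, "dispersion must be >= 0")
  stopifnot_msg(length(cfg$noise_sd_range) == 2 &&
                cfg$noise_sd_range[1] <= cfg$noise_sd_range[2] &&
                cfg$noise_sd_range[1] >= 0,
                "noise_sd_range must be a non-negative interval")
  stopifnot_msg(cfg$n_lines >= 8 || cfg$n_ssd == 0,
                "need >= 8 lines to plant biomarker-driven SSDs")
  invisible(cfg)
}

#' Simulate a pair of two-study CRISPR screens with known ground truth
#'
#' Generates raw sgRNA read counts for two studies ("A", 14-day readout,
#' library A; "B", 21-day readout, library B) screening the same cell lines,
#' together with the noiseless true gene effects, planted biomarker features
#' and an expression matrix carrying expression-dependency correlates for a
#' subset of SSD genes. Fully reproducible from `config$seed`.
#'
#' The generative model, per guide g targeting gene j in line l of study s:
#' expected log2 fold change
#' `FC = efficacy_g * effect_s[j,l] * (1 + scale_j * [s == B]) + shift_j * [s == B]`
#' plus N(0, noise_sd[s,l]) screen noise per replicate; observed counts are
#' negative binomial around `depth * pDNA_share_g * 2^FC` (Poisson when
#' `dispersion = 0`, exact expectation when `count_model = "expected"`).
#'
#' @param config a [sim_config()].
#' @return list with elements `study_a`, `study_b` ([count_screen()]s),
#'   `guide_map` (data.frame sgrna/gene/library/efficacy), `truth` (gene sets,
#'   biomarker map, per-study true gene-effect matrices, guide efficacies),
#'   `features` (binary feature x line matrix) and `expression` (list of
#'   per-study expression matrices).
#' @export
simulate_pair <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  lines <- sprintf("LINE%03d", seq_len(cfg$n_lines))
  libs <- names(cfg$n_guides_per_gene)

  n_ess <- round(cfg$frac_common_essential * cfg$n_genes)
  essential <- genes[seq_len(n_ess)]
  late <- genes[n_ess + seq_len(cfg$n_late_essential)]
  ssd <- if (cfg$n_ssd > 0) genes[n_ess + cfg$n_late_essential + seq_len(cfg$n_ssd)] else character(0)
  noness <- setdiff(genes, c(essential, late, ssd))

  # shared true biology -------------------------------------------------
  base_effect <- matrix(0, cfg$n_genes, cfg$n_lines, dimnames = list(genes, lines))
  base_effect[essential, ] <- cfg$effect_essential
  base_effect[late, ] <- cfg$effect_late_base

  ssd_biomarker <- list()
  # SSD-driving biomarkers are minority events: a strongly selective
  # dependency has a tight nondependent majority mode
  ssd_max_pos <- max(3L, floor(0.2 * cfg$n_lines))
  max_pos <- max(3L, floor(0.5 * cfg$n_lines) - 1L)
  for (g in ssd) {
    n_pos <- if (ssd_max_pos > 3L) sample(3:ssd_max_pos, 1) else 3L
    pos <- sort(sample(lines, n_pos))
    base_effect[g, pos] <- cfg$ssd_effect
    ssd_biomarker[[g]] <- list(feature = paste0("F_", g), lines = pos)
  }
  line_effect <- matrix(stats::rnorm(cfg$n_genes * cfg$n_lines, 0, cfg$line_effect_sd),
                        cfg$n_genes, cfg$n_lines, dimnames = list(genes, lines))
  effect_a <- base_effect + line_effect
  effect_b <- effect_a
  effect_b[late, ] <- effect_b[late, ] + cfg$effect_late_extra

  # per-gene batch terms (applied to study B) ---------------------------
  batch_shift <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
  batch_scale <- stats::rnorm(cfg$n_genes, 0, cfg$batch_scale_sd)
  names(batch_shift) <- names(batch_scale) <- genes

  # guide maps ----------------------------------------------------------
  guide_map <- do.call(rbind, lapply(libs, function(lb) {
    k <- cfg$n_guides_per_gene[[lb]]
    par <- cfg$guide_efficacy_params[[lb]]
    eff <- if (is.null(par)) rep(1, cfg$n_genes * k) else
      stats::rbeta(cfg$n_genes * k, par[1], par[2])
    data.frame(sgrna = paste0(lb, "_", rep(genes, each = k), "_", seq_len(k)),
               gene = rep(genes, each = k), library = lb,
               efficacy = eff, stringsAsFactors = FALSE)
  }))
  rownames(guide_map) <- NULL

  # per-screen noise SDs ------------------------------------------------
  noise_sd <- matrix(stats::runif(2 * cfg$n_lines, cfg$noise_sd_range[1],
                                  cfg$noise_sd_range[2]),
                     2, cfg$n_lines, dimnames = list(c("A", "B"), lines))

  draw_counts <- function(mu) {
    if (cfg$count_model == "expected") return(mu)
    if (cfg$count_model == "poisson" || cfg$dispersion == 0)
      return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
  }

  build_study <- function(study, lib, effect, is_b) {
    gm <- guide_map[guide_map$library == lib, , drop = FALSE]
    n_g <- nrow(gm)
    pdna_rel <- stats::rlnorm(n_g, meanlog = 0, sdlog = cfg$pdna_sdlog)
    pdna_rel <- pdna_rel / sum(pdna_rel)
    gene_idx <- match(gm$gene, genes)

    # expected FC per guide x line (noiseless)
    eff_mat <- effect[gene_idx, , drop = FALSE]
    scale_term <- if (is_b) 1 + batch_scale[gene_idx] else rep(1, n_g)
    shift_term <- if (is_b) batch_shift[gene_idx] else rep(0, n_g)
    fc_expected <- gm$efficacy * eff_mat * scale_term + shift_term

    pdna_names <- sprintf("%s_pDNA_%d", study, seq_len(cfg$n_pdna_samples))
    samp_names <- as.vector(t(outer(lines, seq_len(cfg$n_replicates),
                                    function(l, r) sprintf("%s_%s_R%d", study, l, r))))
    counts <- matrix(0, n_g, cfg$n_pdna_samples + length(samp_names),
                     dimnames = list(gm$sgrna, c(pdna_names, samp_names)))
    for (p in pdna_names)
      counts[, p] <- draw_counts(cfg$reads_per_sample * pdna_rel)
    col <- cfg$n_pdna_samples
    for (li in seq_along(lines)) {
      for (r in seq_len(cfg$n_replicates)) {
        col <- col + 1
        fc <- fc_expected[, li]
        sdev <- noise_sd[study, li]
        if (sdev > 0 && cfg$count_model != "expected")
          fc <- fc + stats::rnorm(n_g, 0, sdev)
        abund <- pdna_rel * 2^fc
        mu <- cfg$reads_per_sample * abund / sum(abund)
        counts[, col] <- draw_counts(mu)
      }
    }
    meta <- data.frame(
      sample = colnames(counts),
      cell_line = c(rep(NA_character_, cfg$n_pdna_samples),
                    rep(lines, each = cfg$n_replicates)),
      replicate = c(rep(NA_integer_, cfg$n_pdna_samples),
                    rep(seq_len(cfg$n_replicates), times = cfg$n_lines)),
      is_pdna = c(rep(TRUE, cfg$n_pdna_samples), rep(FALSE, length(samp_names))),
      pdna_batch = paste0(lib, "_batch1"),
      study = study, library = lib,
      timepoint = if (is_b) 21 else 14,
      media = "RPMI", clone = "default",
      stringsAsFactors = FALSE)
    count_screen(counts, meta)
  }

  study_a <- build_study("A", libs[1], effect_a, is_b = FALSE)
  study_b <- build_study("B", libs[2], effect_b, is_b = TRUE)

  # biomarker feature matrix --------------------------------------------
  feat_names <- c(vapply(ssd_biomarker, function(x) x$feature, character(1)),
                  if (cfg$n_decoy_features > 0)
                    sprintf("DECOY%03d", seq_len(cfg$n_decoy_features)))
  features <- matrix(0L, length(feat_names), cfg$n_lines,
                     dimnames = list(feat_names, lines))
  for (g in names(ssd_biomarker))
    features[ssd_biomarker[[g]]$feature, ssd_biomarker[[g]]$lines] <- 1L
  if (cfg$n_decoy_features > 0) {
    for (f in grep("^DECOY", feat_names, value = TRUE)) {
      n_pos <- if (max_pos > 3L) sample(3:max_pos, 1) else 3L
      features[f, sample(lines, n_pos)] <- 1L
    }
  }

  # expression with planted dependency correlates -----------------------
  n_expr_ssd <- round(cfg$frac_ssd_expression * length(ssd))
  expr_ssd <- if (n_expr_ssd > 0) ssd[seq_len(n_expr_ssd)] else character(0)
  expr_genes <- c(expr_ssd,
                  if (cfg$n_expression_background > 0)
                    sprintf("BG%04d", seq_len(cfg$n_expression_background)))
  expr_sign <- stats::setNames(sample(c(-1, 1), length(expr_ssd), replace = TRUE),
                               expr_ssd)
  shared <- matrix(stats::rnorm(length(expr_genes) * cfg$n_lines, 5, 1),
                   length(expr_genes), cfg$n_lines,
                   dimnames = list(expr_genes, lines))
  for (g in expr_ssd) {
    dep <- (effect_a[g, ] + effect_b[g, ]) / 2
    shared[g, ] <- 5 + expr_sign[[g]] * 1.5 * scale(dep)[, 1] +
      stats::rnorm(cfg$n_lines, 0, 0.3)
  }
  expr_noise <- function() matrix(stats::rnorm(length(shared), 0, 0.1),
                                  nrow(shared), ncol(shared))
  expression <- list(A = shared + expr_noise(), B = shared + expr_noise())

  truth <- list(essential_genes = essential,
                late_essential_genes = late,
                nonessential_genes = noness,
                ssd_genes = ssd,
                ssd_biomarker = ssd_biomarker,
                ssd_expression_genes = expr_ssd,
                ssd_expression_sign = expr_sign,
                true_gene_effect = list(A = effect_a, B = effect_b),
                guide_efficacy = stats::setNames(guide_map$efficacy, guide_map$sgrna),
                batch_shift = batch_shift, batch_scale = batch_scale,
                noise_sd = noise_sd)

  list(study_a = study_a, study_b = study_b, guide_map = guide_map,
       truth = truth, features = features, expression = expression,
       config = cfg)
}

#' Write a simulated screen pair to plain-text files
#'
#' Emits count and guide-map TSVs, the feature/expression matrices and a
#' JSON encoding of the ground truth under `outdir`.
#'
#' @param sim result of [simulate_pair()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in c("study_a", "study_b")) {
    p <- file.path(outdir, paste0(s, "_counts.tsv"))
    m <- file.path(outdir, paste0(s, "_meta.tsv"))
    write_count_screen(sim[[s]], p, m)
    paths <- c(paths, p, m)
  }
  gm <- file.path(outdir, "guide_map.tsv")
  utils::write.table(sim$guide_map, gm, sep = "\t", quote = FALSE, row.names = FALSE)
  fm <- file.path(outdir, "features.tsv")
  write_matrix_tsv(sim$features, fm, id_col = "feature")
  ex <- vapply(names(sim$expression), function(s) {
    p <- file.path(outdir, paste0("expression_", s, ".tsv"))
    write_matrix_tsv(sim$expression[[s]], p, id_col = "gene")
    p
  }, character(1))
  tr <- file.path(outdir, "truth.json")
  truth <- sim$truth
  truth$true_gene_effect <- lapply(truth$true_gene_effect, function(m)
    list(genes = rownames(m), lines = colnames(m), values = unname(m)))
  truth$noise_sd <- list(study = rownames(truth$noise_sd),
                         lines = colnames(truth$noise_sd),
                         values = unname(truth$noise_sd))
  jsonlite::write_json(truth, tr, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, gm, fm, ex, tr))
}
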