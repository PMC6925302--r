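#' Run the full two-study concordance analysis on a simulated pair
#'
#' End-to-end driver: simulates (or accepts) a two-study screen pair,
#' computes unprocessed gene scores, batch-corrects, and evaluates every
#' concordance surface — score correlations, common-essential agreement,
#' FDR-binarized dependency agreement, NormLRT/SSD classification,
#' cell-line counterpart recall before and after correction, screen
#' quality versus agreement, biomarker association recovery, and the
#' early/late time-point resampling test.
#'
#' @param config [sim_config()] (or a list of its arguments); ignored when
#'   `sim` is given.
#' @param sim optional pre-built [simulate_pair()] result.
#' @param n_perm resamples for the time-point test (default 2000).
#' @param fdr FDR level used throughout (default 0.05).
#' @param run_normlrt compute per-gene NormLRT tables (the slowest stage;
#'   default TRUE).
#' @return list with the intermediate matrices and a `summary` list of
#'   scalar metrics.
#' @export
run_concordance <- function(config = sim_config(), sim = NULL,
                            n_perm = 2000, fdr = 0.05, run_normlrt = TRUE) {
  if (is.null(sim)) sim <- simulate_pair(config)
  truth <- sim$truth
  refs <- reference_sets(truth$essential_genes, truth$nonessential_genes)
  map_a <- sim$guide_map[sim$guide_map$library == unique(sim$study_a$meta$library), ]
  map_b <- sim$guide_map[sim$guide_map$library == unique(sim$study_b$meta$library), ]

  # unprocessed scores ---------------------------------------------------
  scores_a <- score_screen(sim$study_a, map_a, refs)
  scores_b <- score_screen(sim$study_b, map_b, refs)
  al <- align_studies(scores_a, scores_b)

  # batch correction ------------------------------------------------------
  fc_a <- log_fold_change(counts_to_rpm(sim$study_a), sim$study_a$meta)
  fc_b <- log_fold_change(counts_to_rpm(sim$study_b), sim$study_b$meta)
  corr <- correct_pipeline(fc_a, fc_b, map_a, map_b)
  n_lines <- ncol(corr$a)
  unc_a <- corr$uncorrected[, seq_len(n_lines), drop = FALSE]
  unc_b <- corr$uncorrected[, n_lines + seq_len(n_lines), drop = FALSE]
  colnames(unc_a) <- colnames(corr$a); colnames(unc_b) <- colnames(corr$b)

  # correlations ----------------------------------------------------------
  cors_unproc <- correlation_suite(al$a, al$b)
  cors_corr <- correlation_suite(corr$a, corr$b)

  # common essentials -----------------------------------------------------
  ce_a <- common_essentials(al$a)
  ce_b <- common_essentials(al$b)
  joint_ce <- intersect(ce_a$common_essential, ce_b$common_essential)

  # global FDR binarization on the joint unprocessed matrix ---------------
  joint_unproc <- cbind(score_matrix(al$a), score_matrix(al$b))
  colnames(joint_unproc) <- c(paste0("A:", colnames(al$a)),
                              paste0("B:", colnames(al$b)))
  glob <- global_fdr_binarize(joint_unproc, refs, fdr = fdr)
  calls_a <- glob$calls[, seq_len(n_lines), drop = FALSE]
  calls_b <- glob$calls[, n_lines + seq_len(n_lines), drop = FALSE]
  colnames(calls_a) <- colnames(al$a); colnames(calls_b) <- colnames(al$b)
  variable_genes <- rownames(glob$calls)[rowSums(glob$calls) > 0]

  # NormLRT / SSDs --------------------------------------------------------
  normlrt_a <- normlrt_b <- NULL
  ssd <- character(0)
  if (run_normlrt) {
    normlrt_a <- normlrt_scores(al$a)
    normlrt_b <- normlrt_scores(al$b)
    ssd <- classify_ssd(normlrt_a, normlrt_b)
  }

  # counterpart recall ----------------------------------------------------
  knn_unc <- knn_recall_nauc(unc_a, unc_b, gene_subset = variable_genes)
  knn_cor <- knn_recall_nauc(score_matrix(corr$a), score_matrix(corr$b),
                             gene_subset = variable_genes)

  # per-line calls, quality, agreement ------------------------------------
  pl_a <- per_line_fdr_binarize(al$a, refs, fdr = fdr)
  pl_b <- per_line_fdr_binarize(al$b, refs, fdr = fdr)
  jac <- per_line_jaccard(pl_a, pl_b)
  tpr_a <- screen_quality_tpr(al$a, refs,
                              common = if (length(joint_ce)) joint_ce else refs$essential,
                              fdr = fdr)
  tpr_b <- screen_quality_tpr(al$b, refs,
                              common = if (length(joint_ce)) joint_ce else refs$essential,
                              fdr = fdr)
  qva <- quality_vs_agreement(tpr_a, tpr_b,
                              stats::setNames(jac$jaccard, jac$cell_line))

  # binarized SSD agreement ----------------------------------------------
  ssd_for_binary <- if (length(ssd) >= 2) ssd else truth$ssd_genes
  bin <- if (length(ssd_for_binary) >= 1)
    binarized_agreement(calls_a[ssd_for_binary, , drop = FALSE],
                        calls_b[ssd_for_binary, , drop = FALSE],
                        scores_a = al$a[ssd_for_binary, , drop = FALSE],
                        scores_b = al$b[ssd_for_binary, , drop = FALSE])
  else NULL

  # biomarker associations ------------------------------------------------
  test_genes <- if (length(ssd) >= 1) ssd else truth$ssd_genes
  feats <- filter_features(sim$features, min_pos = 3,
                           max_pos = ncol(al$a) - 3)
  assoc_a <- differential_dependency(al$a[test_genes, , drop = FALSE], feats)
  assoc_b <- differential_dependency(al$b[test_genes, , drop = FALSE], feats)
  shared_assoc <- intersect(
    paste(assoc_a$feature, assoc_a$gene)[assoc_a$significant],
    paste(assoc_b$feature, assoc_b$gene)[assoc_b$significant])

  # early/late resampling -------------------------------------------------
  means_a <- rowMeans(score_matrix(al$a))
  means_b <- rowMeans(score_matrix(al$b))
  late_test <- early_late_resampling_test(means_a, means_b,
                                          truth$late_essential_genes,
                                          n_perm = n_perm)
  early_test <- early_late_resampling_test(means_a, means_b,
                                           truth$essential_genes,
                                           n_perm = n_perm)

  summary <- list(
    overall_pearson_unprocessed = cors_unproc$overall_pearson,
    overall_spearman_unprocessed = cors_unproc$overall_spearman,
    overall_pearson_corrected = cors_corr$overall_pearson,
    gene_mean_pearson_unprocessed = cors_unproc$gene_mean_pearson,
    gene_mean_pearson_corrected = cors_corr$gene_mean_pearson,
    n_common_essential_joint = length(joint_ce),
    common_essential_recall = if (length(truth$essential_genes))
      mean(truth$essential_genes %in% joint_ce) else NA_real_,
    global_fdr_threshold = glob$threshold,
    n_ssd_detected = length(ssd),
    ssd_recall = if (length(truth$ssd_genes))
      mean(truth$ssd_genes %in% ssd) else NA_real_,
    nauc_uncorrected = knn_unc$nauc,
    nauc_corrected = knn_cor$nauc,
    top1_uncorrected = knn_unc$top1,
    top1_corrected = knn_cor$top1,
    median_jaccard = stats::median(jac$jaccard),
    quality_agreement_slope = qva$slope,
    quality_agreement_p = qva$p,
    quality_agreement_adj_r2 = qva$adj_r_squared,
    median_ssd_kappa = if (!is.null(bin)) bin$median_gene_kappa else NA_real_,
    n_assoc_a = sum(assoc_a$significant, na.rm = TRUE),
    n_assoc_b = sum(assoc_b$significant, na.rm = TRUE),
    n_assoc_shared = length(shared_assoc),
    late_delta = late_test$delta, late_p_gaussian = late_test$p_gaussian,
    early_delta = early_test$delta, early_p_gaussian = early_test$p_gaussian)

  list(sim = sim, refs = refs, scores = al, corrected = corr,
       uncorrected = list(a = unc_a, b = unc_b),
       common_essentials = list(a = ce_a, b = ce_b, joint = joint_ce),
       global_calls = glob, calls = list(a = calls_a, b = calls_b),
       per_line_calls = list(a = pl_a, b = pl_b),
       normlrt = list(a = normlrt_a, b = normlrt_b), ssd = ssd,
       knn = list(uncorrected = knn_unc, corrected = knn_cor),
       jaccard = jac, tpr = list(a = tpr_a, b = tpr_b),
       quality_vs_agreement = qva, binarized = bin,
       associations = list(a = assoc_a, b = assoc_b, shared = shared_assoc),
       timepoint_tests = list(late = late_test, early = early_test),
       summary = summary)
}
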