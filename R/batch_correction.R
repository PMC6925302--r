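#' Empirical-Bayes location/scale batch adjustment (parametric ComBat)
#'
#' Removes a single batch factor from a gene x sample matrix by the
#' standard parametric empirical-Bayes procedure: each gene is standardized
#' against its pooled mean and variance, per-batch per-gene location and
#' scale effects are estimated, shrunk toward method-of-moments hyperpriors
#' (normal prior on the additive effect, inverse-gamma on the
#' multiplicative one), and the adjusted data back-transformed. Only an
#' intercept and the batch factor enter the model.
#'
#' Genes with zero variance within any batch cannot be standardized
#' reliably; they are passed through unadjusted and flagged in the
#' `"unadjusted_genes"` attribute of the result.
#'
#' @param m gene x sample matrix.
#' @param batch factor/character of length `ncol(m)`; >= 2 batches with
#'   >= 2 samples each.
#' @param conv relative-change convergence tolerance of the EB fixed-point
#'   iteration (default 1e-4, the standard stopping rule of this
#'   procedure; the change statistic is `max((g' - g)/g, (d' - d)/d)` in
#'   absolute numerator form).
#' @param max_iter iteration cap (default 100).
#' @return adjusted matrix, same dimensions and dimnames.
#' @export
combat_correct <- function(m, batch, conv = 1e-4, max_iter = 100) {
  m <- score_matrix(m)
  batch <- as.factor(batch)
  if (length(batch) != ncol(m)) stop("batch must label every column")
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  n_i <- table(batch)
  if (any(n_i < 2)) stop("every batch needs >= 2 samples")
  idx <- split(seq_len(ncol(m)), batch)
  N <- ncol(m)

  batch_means <- vapply(idx, function(j) rowMeans(m[, j, drop = FALSE]),
                        numeric(nrow(m)))
  batch_vars <- vapply(idx, function(j) apply(m[, j, drop = FALSE], 1, stats::var),
                       numeric(nrow(m)))
  grand_mean <- as.vector(batch_means %*% (as.vector(n_i) / N))
  fit <- batch_means[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((m - fit)^2) / N

  skip <- var_pooled == 0 | apply(batch_vars == 0, 1, any)
  out <- m
  if (all(skip)) {
    attr(out, "unadjusted_genes") <- rownames(m)[skip]
    return(out)
  }
  d <- m[!skip, , drop = FALSE]
  gm <- grand_mean[!skip]
  vp <- var_pooled[!skip]
  s_data <- (d - gm) / sqrt(vp)

  bayes <- s_data
  for (b in levels(batch)) {
    j <- idx[[b]]
    n <- length(j)
    sb <- s_data[, j, drop = FALSE]
    g_hat <- rowMeans(sb)
    d_hat <- apply(sb, 1, stats::var)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m_d <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m_d^2) / s2
    b_prior <- (m_d * s2 + m_d^3) / s2

    g_old <- g_hat
    d_old <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
      sum2 <- rowSums((sb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    bayes[, j] <- (sb - g_old) / sqrt(d_old)
  }
  out[!skip, ] <- bayes * sqrt(vp) + gm
  attr(out, "unadjusted_genes") <- rownames(m)[skip]
  out
}

#' Batch-correction pipeline for a pair of studies
#'
#' Reproduces the four-step correction of cross-study gene scores:
#' (1) sgRNA log fold changes are mean-collapsed by gene and then by
#' replicates; (2) each study is quantile normalized separately; (3) the
#' two matrices, aligned on shared genes and lines, are adjusted with
#' single-factor ComBat (batch = study); (4) the corrected joint matrix is
#' quantile normalized.
#'
#' @param fc_a,fc_b [log_fold_change()] results (or guide x replicate
#'   matrices plus `meta_a`/`meta_b`).
#' @param map_a,map_b guide maps for the two libraries.
#' @param meta_a,meta_b sample metadata; defaults taken from the
#'   fold-change objects.
#' @param conv,max_iter passed to [combat_correct()].
#' @return list: `joint` (gene x 2n matrix, columns "study:line"),
#'   `batch` (study label per column), `a`, `b` (per-study
#'   [gene_score_matrix()]s, level "corrected"), `uncorrected`
#'   (the step-2 joint matrix, for before/after comparisons).
#' @export
correct_pipeline <- function(fc_a, fc_b, map_a, map_b,
                             meta_a = NULL, meta_b = NULL,
                             conv = 1e-4, max_iter = 100) {
  get_meta <- function(fc, meta) {
    if (!is.null(meta)) return(meta)
    if (inherits(fc, "fold_change_matrix")) return(fc$meta)
    stop("sample metadata required when fold changes are a plain matrix")
  }
  ma <- get_meta(fc_a, meta_a); mb <- get_meta(fc_b, meta_b)
  gene_a <- collapse_replicates(collapse_guides(fc_a, map_a, stat = "mean"),
                                ma$cell_line, stat = "mean")
  gene_b <- collapse_replicates(collapse_guides(fc_b, map_b, stat = "mean"),
                                mb$cell_line, stat = "mean")
  al <- align_studies(gene_a, gene_b)
  qa <- quantile_normalize(al$a)
  qb <- quantile_normalize(al$b)
  joint <- cbind(qa, qb)
  colnames(joint) <- c(paste0("A:", colnames(qa)), paste0("B:", colnames(qb)))
  batch <- rep(c("A", "B"), times = c(ncol(qa), ncol(qb)))
  uncorrected <- joint
  corrected <- combat_correct(joint, batch, conv = conv, max_iter = max_iter)
  corrected <- quantile_normalize(corrected)
  n <- ncol(qa)
  a_cor <- corrected[, seq_len(n), drop = FALSE]
  b_cor <- corrected[, n + seq_len(ncol(qb)), drop = FALSE]
  colnames(a_cor) <- colnames(qa); colnames(b_cor) <- colnames(qb)
  tp <- function(meta) unique(meta$timepoint[!meta$is_pdna])[1]
  list(joint = corrected, batch = batch,
       a = gene_score_matrix(a_cor, study = "A", level = "corrected",
                             library = unique(ma$library)[1], timepoint = tp(ma)),
       b = gene_score_matrix(b_cor, study = "B", level = "corrected",
                             library = unique(mb$library)[1], timepoint = tp(mb)),
       uncorrected = uncorrected)
}
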