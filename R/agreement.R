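#' Correlation summary of two aligned score matrices
#'
#' Overall Pearson and Spearman correlation over all (gene, line) pairs,
#' per-gene Pearson correlation across lines, and the Pearson correlation
#' of per-gene means. Constant profiles yield NA per-gene correlations.
#'
#' @param a,b aligned gene x cell-line matrices ([align_studies()]).
#' @return list: `overall_pearson`, `overall_spearman`, `per_gene`
#'   (data.frame gene/r), `gene_mean_pearson`.
#' @export
correlation_suite <- function(a, b) {
  ma <- score_matrix(a); mb <- score_matrix(b)
  if (!identical(dimnames(ma), dimnames(mb)))
    stop("matrices are not aligned; run align_studies() first")
  va <- as.vector(ma); vb <- as.vector(mb)
  ok <- is.finite(va) & is.finite(vb)
  per_gene <- vapply(seq_len(nrow(ma)), function(i) {
    x <- ma[i, ]; y <- mb[i, ]
    k <- is.finite(x) & is.finite(y)
    if (sum(k) < 3 || stats::sd(x[k]) == 0 || stats::sd(y[k]) == 0)
      return(NA_real_)
    stats::cor(x[k], y[k])
  }, numeric(1))
  list(overall_pearson = stats::cor(va[ok], vb[ok]),
       overall_spearman = stats::cor(rank(va[ok]), rank(vb[ok])),
       per_gene = data.frame(gene = rownames(ma), r = per_gene,
                             stringsAsFactors = FALSE),
       gene_mean_pearson = stats::cor(rowMeans(ma, na.rm = TRUE),
                                      rowMeans(mb, na.rm = TRUE)))
}

#' Cohen's kappa for two logical vectors
#' @param x,y logical vectors of equal length.
#' @return kappa in [-1, 1]; NA when a margin is degenerate.
#' @export
cohens_kappa <- function(x, y) {
  n <- length(x)
  p_o <- mean(x == y)
  p_yes <- mean(x) * mean(y)
  p_no <- mean(!x) * mean(!y)
  p_e <- p_yes + p_no
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' AUROC by the rank (Mann-Whitney) identity
#'
#' Probability that a randomly chosen positive scores lower than a random
#' negative is computed via midranks, so ties are handled exactly. Here
#' "positive" means dependent, i.e. lower (more depleted) scores should
#' predict positives, and the returned AUROC is for that orientation.
#'
#' @param scores numeric predictor (lower = more likely positive).
#' @param labels logical vector of the same length.
#' @return AUROC in [0, 1]; NA if either class is empty.
#' @export
auroc <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  # low scores should rank positives first
  (sum(r[!labels]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' Agreement metrics for two binary dependency-call matrices
#'
#' Cross-tabulates the calls and reports Cohen's kappa, the two-sided
#' Fisher exact p-value, and precision/recall treating study A's calls as
#' the reference. With `per_gene = TRUE`, kappa is additionally computed
#' gene by gene. If continuous scores for one study are supplied, the
#' AUROC for recovering the other study's binary calls is included.
#'
#' @param calls_a,calls_b `dependency_calls` or logical matrices of
#'   identical shape.
#' @param per_gene also compute per-gene kappa (default TRUE).
#' @param scores_a,scores_b optional score matrices for AUROC (scores of
#'   one study against the calls of the other).
#' @return list of metrics.
#' @export
binarized_agreement <- function(calls_a, calls_b, per_gene = TRUE,
                                scores_a = NULL, scores_b = NULL) {
  ca <- if (inherits(calls_a, "dependency_calls")) calls_a$calls else calls_a
  cb <- if (inherits(calls_b, "dependency_calls")) calls_b$calls else calls_b
  if (!identical(dim(ca), dim(cb))) stop("call matrices differ in shape")
  va <- as.vector(ca); vb <- as.vector(cb)
  tab <- table(factor(va, c(TRUE, FALSE)), factor(vb, c(TRUE, FALSE)))
  fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    stats::fisher.test(tab)$p.value
  prec <- if (sum(vb) == 0) NA_real_ else sum(va & vb) / sum(vb)
  rec <- if (sum(va) == 0) NA_real_ else sum(va & vb) / sum(va)
  out <- list(table = tab, kappa = cohens_kappa(va, vb),
              fisher_p = fisher_p, precision = prec, recall = rec)
  if (per_gene) {
    pg <- vapply(seq_len(nrow(ca)), function(i) cohens_kappa(ca[i, ], cb[i, ]),
                 numeric(1))
    out$per_gene_kappa <- stats::setNames(pg, rownames(ca))
    out$median_gene_kappa <- stats::median(pg, na.rm = TRUE)
  }
  if (!is.null(scores_a))
    out$auroc_a_predicts_b <- auroc(as.vector(score_matrix(scores_a)), vb)
  if (!is.null(scores_b))
    out$auroc_b_predicts_a <- auroc(as.vector(score_matrix(scores_b)), va)
  out
}

#' Counterpart recall curve and nAUC for cross-study cell-line matching
#'
#' Concatenates the two studies' cell-line dependency profiles (optionally
#' restricted to a gene subset), ranks, for each profile, all other
#' profiles by correlation distance (1 - Pearson; ties broken by profile
#' name), and records at which rank the profile's counterpart in the other
#' study appears. recall(k) is the percentage of profiles whose
#' counterpart lies within their k nearest neighbors; nAUC is the mean
#' recall over k = 1..2n-1, scaled to [0, 1].
#'
#' @param a,b aligned gene x cell-line matrices for the two studies.
#' @param gene_subset optional character vector restricting the genes used
#'   for the correlation distance.
#' @return list of class `recall_curve`: `k`, `recall` (percent), `nauc`,
#'   `top1` (count of profiles whose counterpart is the single nearest
#'   neighbor), `n_profiles`.
#' @export
knn_recall_nauc <- function(a, b, gene_subset = NULL) {
  ma <- score_matrix(a); mb <- score_matrix(b)
  if (!identical(dimnames(ma), dimnames(mb)))
    stop("matrices are not aligned")
  if (anyDuplicated(colnames(ma)) > 0)
    stop("duplicate cell-line labels within a study")
  if (!is.null(gene_subset)) {
    gene_subset <- intersect(gene_subset, rownames(ma))
    if (length(gene_subset) < 2) stop("gene subset too small")
    ma <- ma[gene_subset, , drop = FALSE]
    mb <- mb[gene_subset, , drop = FALSE]
  }
  joint <- cbind(ma, mb)
  n <- ncol(ma)
  labels <- c(paste0("A:", colnames(ma)), paste0("B:", colnames(mb)))
  colnames(joint) <- labels
  counterpart <- c(paste0("B:", colnames(ma)), paste0("A:", colnames(mb)))
  cm <- stats::cor(joint)
  m2 <- ncol(joint)
  ranks <- vapply(seq_len(m2), function(i) {
    d <- 1 - cm[, i]
    d <- d[-i]
    ord <- order(d, names(d)) # deterministic tie-break by profile name
    which(names(d)[ord] == counterpart[i])
  }, integer(1))
  k <- seq_len(m2 - 1)
  recall <- vapply(k, function(kk) 100 * mean(ranks <= kk), numeric(1))
  structure(list(k = k, recall = recall, nauc = mean(recall) / 100,
                 top1 = sum(ranks == 1), n_profiles = m2,
                 counterpart_rank = stats::setNames(ranks, labels)),
            class = "recall_curve")
}

#' Per-line Jaccard agreement of dependency calls
#'
#' For each cell line, the Jaccard index `J = |A n B| / |A u B|` of the
#' two studies' called dependency gene sets, and the disagreement `1 - J`.
#' Two empty call sets are identical, so J is defined as 1 there (flagged).
#'
#' @param calls_a,calls_b `dependency_calls` or logical matrices, aligned.
#' @return data.frame: cell_line, jaccard, disagreement, both_empty.
#' @export
per_line_jaccard <- function(calls_a, calls_b) {
  ca <- if (inherits(calls_a, "dependency_calls")) calls_a$calls else calls_a
  cb <- if (inherits(calls_b, "dependency_calls")) calls_b$calls else calls_b
  if (!identical(dimnames(ca), dimnames(cb))) stop("call matrices not aligned")
  inter <- colSums(ca & cb)
  uni <- colSums(ca | cb)
  both_empty <- uni == 0
  if (any(both_empty))
    warning(sum(both_empty), " line(s) with no calls in either study; J = 1")
  j <- ifelse(both_empty, 1, inter / uni)
  data.frame(cell_line = colnames(ca), jaccard = j, disagreement = 1 - j,
             both_empty = both_empty, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Regress per-line agreement on mean screen quality
#'
#' Ordinary least squares of a per-line agreement measure on the mean of
#' the two studies' per-line screen-quality TPRs; reports the slope, its
#' t-test p-value and the adjusted R-squared.
#'
#' @param tpr_a,tpr_b named per-line TPR vectors ([screen_quality_tpr()]).
#' @param agreement named per-line agreement vector (e.g. Jaccard).
#' @return list: `slope`, `p`, `adj_r_squared`, `fit` (the lm object).
#' @export
quality_vs_agreement <- function(tpr_a, tpr_b, agreement) {
  lines <- Reduce(intersect, list(names(tpr_a), names(tpr_b), names(agreement)))
  if (length(lines) < 3) stop("need >= 3 cell lines")
  mean_tpr <- (tpr_a[lines] + tpr_b[lines]) / 2
  if (stats::sd(mean_tpr) == 0) stop("constant screen quality; slope undefined")
  fit <- stats::lm(agreement[lines] ~ mean_tpr)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p = s$coefficients[2, 4],
       adj_r_squared = s$adj.r.squared, fit = fit)
}
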