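#' Filter binary molecular features by prevalence
#'
#' Keeps features present in at least `min_pos` and fewer than `max_pos`
#' cell lines, the prevalence window within which a two-group comparison
#' is informative.
#'
#' @param features binary feature x cell-line matrix.
#' @param min_pos minimum positives, inclusive (default 3).
#' @param max_pos maximum positives, exclusive (default 144).
#' @return the filtered matrix.
#' @export
filter_features <- function(features, min_pos = 3, max_pos = 144) {
  features <- as.matrix(features)
  if (!all(features %in% c(0, 1))) stop("feature matrix must be binary")
  n_pos <- rowSums(features)
  features[n_pos >= min_pos & n_pos < max_pos, , drop = FALSE]
}

#' Differential dependency of genes across binary feature dichotomies
#'
#' For every (feature, gene) pair, splits the cell lines by feature status
#' and runs an unpaired equal-variance Student's t-test on the gene's
#' scores, with effect size Cohen's delta
#' `dfc = (mean_pos - mean_neg) / pooled SD` (negative = stronger
#' dependency in feature-positive lines). p-values are BH-corrected over
#' all executed tests. Pairs with fewer than 2 lines in either group or
#' zero pooled variance are skipped and flagged.
#'
#' @param scores gene x cell-line matrix (typically restricted to SSDs).
#' @param features binary feature x cell-line matrix (same lines).
#' @param fdr_cut,dfc_cut significance rule applied to the `significant`
#'   column (defaults FDR < 0.05 and delta < -1).
#' @return data.frame of class `association_table`: feature, gene, n_pos,
#'   n_neg, t, p, fdr, dfc, significant, skipped.
#' @export
differential_dependency <- function(scores, features, fdr_cut = 0.05,
                                    dfc_cut = -1) {
  m <- score_matrix(scores)
  features <- as.matrix(features)
  lines <- intersect(colnames(m), colnames(features))
  if (length(lines) < 4) stop("need >= 4 shared cell lines")
  m <- m[, lines, drop = FALSE]
  features <- features[, lines, drop = FALSE]
  res <- list()
  for (f in rownames(features)) {
    pos <- features[f, ] == 1
    n1 <- sum(pos); n0 <- sum(!pos)
    xp <- m[, pos, drop = FALSE]
    xn <- m[, !pos, drop = FALSE]
    m1 <- rowMeans(xp); m0 <- rowMeans(xn)
    v1 <- apply(xp, 1, stats::var); v0 <- apply(xn, 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
    dfc <- (m1 - m0) / sqrt(sp2)
    skipped <- n1 < 2 | n0 < 2 | sp2 == 0
    res[[f]] <- data.frame(feature = f, gene = rownames(m),
                           n_pos = n1, n_neg = n0,
                           t = ifelse(skipped, NA, tt),
                           p = ifelse(skipped, NA, p),
                           dfc = ifelse(skipped, NA, dfc),
                           skipped = skipped, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  run <- !out$skipped
  out$fdr[run] <- stats::p.adjust(out$p[run], method = "BH")
  out$significant <- !out$skipped & out$fdr < fdr_cut & out$dfc < dfc_cut
  class(out) <- c("association_table", class(out))
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 over the lambda grid 0.05-0.95 (step
#' 0.05) with a df-3 smoothing spline evaluated at the largest lambda,
#' then converts BH-style adjusted p-values to q-values
#' `q_i = pi0 * min_{j: p_j >= p_i} (m * p_j / rank_j)`.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values.
#' @export
qvalue_storey <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  lambda <- seq(0.05, 0.95, 0.05)
  pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
  pi0 <- if (m < 100) 1 else {
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    min(1, max(stats::predict(sp, x = max(lambda))$y, 0))
  }
  if (pi0 <= 0) pi0 <- 1e-8
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pi0 * cummin(pv[o] * m / rank(pv, ties.method = "max")[o])[ro]
  q[ok] <- pmin(qv, 1)
  q
}

#' Expression-dependency correlation mining
#'
#' Pearson correlation of each expression profile against each dependency
#' (SSD) profile over the shared cell lines; significance from the
#' t-distribution with n - 2 degrees of freedom,
#' `t = r sqrt((n-2)/(1-r^2))`, corrected with Storey q-values. Constant
#' expression profiles are skipped.
#'
#' @param expr expression gene x cell-line matrix.
#' @param scores dependency gene x cell-line matrix (SSDs).
#' @return data.frame: expr_gene, dep_gene, n, r, p, q.
#' @export
expression_dependency_correlation <- function(expr, scores) {
  expr <- as.matrix(expr)
  m <- score_matrix(scores)
  lines <- intersect(colnames(expr), colnames(m))
  if (length(lines) < 4) stop("need >= 4 shared cell lines")
  expr <- expr[, lines, drop = FALSE]
  m <- m[, lines, drop = FALSE]
  keep <- apply(expr, 1, stats::sd) > 0
  expr <- expr[keep, , drop = FALSE]
  n <- length(lines)
  r <- stats::cor(t(expr), t(m))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(expr_gene = rep(rownames(r), times = ncol(r)),
                    dep_gene = rep(colnames(r), each = nrow(r)),
                    n = n, r = as.vector(r), p = as.vector(p),
                    stringsAsFactors = FALSE)
  out$q <- qvalue_storey(out$p)
  out
}

#' Intersect the most variable expression genes of two studies
#'
#' @param expr_a,expr_b expression matrices over the same lines.
#' @param k how many top-variance genes to take per study (default 2000).
#' @return character vector: intersection of the two per-study top-k sets.
#' @export
select_variable_expression <- function(expr_a, expr_b, k = 2000) {
  top_k <- function(e) {
    v <- apply(as.matrix(e), 1, stats::var)
    names(sort(v, decreasing = TRUE))[seq_len(min(k, length(v)))]
  }
  intersect(top_k(expr_a), top_k(expr_b))
}

#' Cross-study recovery of biomarker associations
#'
#' Treats increasingly stringent subsets (top 20/40/60/80/100% most
#' significant) of one study's FDR-significant associations as positive
#' controls and scores how well a rank classifier over the other study's
#' p-values recovers them: precision/recall/specificity along the ranked
#' list plus the AUROC. Computed in both directions.
#'
#' @param assoc_a,assoc_b association tables over the same (feature, gene)
#'   test universe, with columns `feature`, `gene`, `p`, `fdr`.
#' @param quantiles fractions of the significant set used as positives
#'   (default `c(0.2, 0.4, 0.6, 0.8, 1)`).
#' @param fdr_cut significance cut defining the positive pool (default 0.05).
#' @return nested list `a_to_b` / `b_to_a`, one element per quantile with
#'   `n_pos`, `auroc`, and a `curve` data.frame (rank, precision, recall,
#'   specificity). Quantiles with no positives are skipped.
#' @export
cross_study_recovery <- function(assoc_a, assoc_b,
                                 quantiles = c(0.2, 0.4, 0.6, 0.8, 1),
                                 fdr_cut = 0.05) {
  key <- function(d) paste(d$feature, d$gene, sep = "|")
  ka <- key(assoc_a); kb <- key(assoc_b)
  if (!setequal(ka, kb)) stop("association tables cover different tests")
  assoc_b <- assoc_b[match(ka, kb), , drop = FALSE]
  one_direction <- function(truth_tab, pred_tab) {
    hits <- which(!is.na(truth_tab$fdr) & truth_tab$fdr < fdr_cut)
    hits <- hits[order(truth_tab$p[hits])]
    pred_p <- pred_tab$p
    pred_p[is.na(pred_p)] <- 1
    out <- list()
    for (q in quantiles) {
      n_pos <- ceiling(q * length(hits))
      if (n_pos == 0) next
      pos <- rep(FALSE, nrow(truth_tab))
      pos[hits[seq_len(n_pos)]] <- TRUE
      ord <- order(pred_p)
      tp <- cumsum(pos[ord])
      k <- seq_along(ord)
      fp <- k - tp
      n_neg <- sum(!pos)
      out[[sprintf("q%d", round(100 * q))]] <- list(
        n_pos = n_pos,
        auroc = auroc(pred_p, pos),
        curve = data.frame(rank = k, precision = tp / k,
                           recall = tp / n_pos,
                           specificity = (n_neg - fp) / n_neg))
    }
    out
  }
  list(a_to_b = one_direction(assoc_a, assoc_b),
       b_to_a = one_direction(assoc_b, assoc_a))
}
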