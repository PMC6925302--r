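#' 90th-percentile rankings of gene dependency
#'
#' For each gene, locate its 90th-percentile least-depleted cell line (the
#' line whose score is closest to the linear-interpolation 90th percentile
#' of that gene's scores, ties resolved toward the less depleted line) and
#' return the gene's score rank among all genes within that line,
#' normalized by the number of genes. A gene that is a strong dependency
#' even in its least dependent lines gets a ranking near 1/n_genes; a gene
#' never depleted ranks near 1.
#'
#' @param m gene x cell-line score matrix.
#' @return named numeric vector of rankings in (0, 1]; genes with all
#'   scores missing are excluded.
#' @export
ninetieth_percentile_rankings <- function(m) {
  m <- score_matrix(m)
  if (ncol(m) < 10)
    warning("fewer than 10 cell lines; 90th-percentile ranking is coarse")
  n_genes <- nrow(m)
  # per-line ascending rank of each gene (most depleted = 1); ties by
  # average then broken deterministically by gene-name order via
  # rank(ties.method = "first") on name-sorted rows
  ord <- order(rownames(m))
  m_sorted <- m[ord, , drop = FALSE]
  line_rank <- apply(m_sorted, 2, rank, ties.method = "first", na.last = "keep")
  rownames(line_rank) <- rownames(m_sorted)
  out <- rep(NA_real_, n_genes)
  names(out) <- rownames(m_sorted)
  for (g in rownames(m_sorted)) {
    x <- m_sorted[g, ]
    ok <- !is.na(x)
    if (!any(ok)) next
    q <- stats::quantile(x[ok], 0.9, type = 7, names = FALSE)
    d <- abs(x - q)
    cand <- which(d == min(d, na.rm = TRUE))
    # tie toward the less depleted (higher-scoring) line
    pick <- cand[which.max(x[cand])]
    out[g] <- line_rank[g, pick] / n_genes
  }
  out[!is.na(out)]
}

#' Central density-minimum threshold of a bimodal ranking distribution
#'
#' Estimates the density of the rankings with a Gaussian kernel of width
#' 0.1 on a 512-point grid over [0, 1] and returns the grid point of
#' minimum density strictly between the two outermost local density
#' maxima. A unimodal density is an error (no natural threshold).
#'
#' @param rankings numeric vector in [0, 1].
#' @param bw kernel width (default 0.1).
#' @param n_grid evaluation grid size (default 512).
#' @return the threshold (scalar).
#' @export
density_minimum_threshold <- function(rankings, bw = 0.1, n_grid = 512) {
  rankings <- rankings[is.finite(rankings)]
  if (length(rankings) < 2) stop("need >= 2 rankings")
  dens <- stats::density(rankings, bw = bw, from = 0, to = 1, n = n_grid)
  y <- dens$y
  k <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              y[k] > y[k - 1])
  maxima <- which(is_max)
  if (length(maxima) < 2)
    stop("ranking density is unimodal; supply a manual threshold")
  lo <- min(maxima); hi <- max(maxima)
  inner <- (lo + 1):(hi - 1)
  dens$x[inner[which.min(y[inner])]]
}

#' Identify common-essential genes
#'
#' Composes [ninetieth_percentile_rankings()] with
#' [density_minimum_threshold()]: genes whose 90th-percentile ranking falls
#' below the central density minimum are labelled common essential.
#'
#' @param m gene x cell-line score matrix.
#' @param bw,n_grid passed to [density_minimum_threshold()].
#' @return list of class `common_essential_result`: `rankings`,
#'   `threshold`, `common_essential` (character vector), `label` (named
#'   logical).
#' @export
common_essentials <- function(m, bw = 0.1, n_grid = 512) {
  r <- ninetieth_percentile_rankings(m)
  thr <- density_minimum_threshold(r, bw = bw, n_grid = n_grid)
  lab <- r < thr
  structure(list(rankings = r, threshold = thr,
                 common_essential = names(r)[lab], label = lab),
            class = "common_essential_result")
}

#' Binarize dependencies against a global empirical null
#'
#' Takes the scores of the reference nonessential genes across all cell
#' lines (and, if a joint matrix is given, both studies) as the null
#' distribution; assigns every score the left-tailed empirical p-value
#' `p = (#null <= x + 1) / (N_null + 1)`, corrects across all scores with
#' Benjamini-Hochberg, and calls dependent every score at or below the
#' largest score whose FDR is <= the requested level.
#'
#' @param m gene x column score matrix (concatenate studies beforehand for
#'   a joint null).
#' @param refs [reference_sets()].
#' @param fdr FDR level (default 0.05).
#' @return list of class `dependency_calls`: `calls` (logical matrix),
#'   `threshold` (score threshold, NA if nothing passes), `fdr`,
#'   `rule = "global"`.
#' @export
global_fdr_binarize <- function(m, refs, fdr = 0.05) {
  m <- score_matrix(m)
  null_genes <- intersect(refs$nonessential, rownames(m))
  if (length(null_genes) == 0) stop("no nonessential reference genes in matrix")
  null_scores <- sort(as.vector(m[null_genes, ]))
  null_scores <- null_scores[is.finite(null_scores)]
  n_null <- length(null_scores)
  x <- as.vector(m)
  p <- (findInterval(x, null_scores) + 1) / (n_null + 1)
  p[is.na(x)] <- NA
  q <- stats::p.adjust(p, method = "BH")
  passing <- !is.na(q) & q <= fdr
  if (!any(passing)) {
    warning("no score reaches FDR <= ", fdr, "; empty calls")
    threshold <- NA_real_
    calls <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    threshold <- max(x[passing])
    calls <- m <= threshold
    calls[is.na(calls)] <- FALSE
  }
  structure(list(calls = calls, threshold = threshold, fdr = fdr,
                 rule = "global"), class = "dependency_calls")
}

#' Per-line rank/precision dependency calling
#'
#' Ranks a cell line's genes by score (most depleted first) and walks the
#' precision PPV(k) = |P(k) n E| / |P(k)| over the reference essential (E)
#' and nonessential (N) genes, where P(k) is the set of reference genes in
#' the top k. k* is the largest rank with PPV(k) >= 1 - fdr; F* is the
#' score at rank k*; every gene with score strictly below F* is called
#' dependent.
#'
#' @param scores named numeric vector: one cell line's gene scores.
#' @param refs [reference_sets()].
#' @param fdr FDR level (default 0.05: PPV >= 0.95).
#' @return list: `k_star`, `f_star` (NA if precision never reaches the
#'   bar), `called` (character vector of dependent genes), `ppv` (precision
#'   at each reference-gene rank, for inspection).
#' @export
per_line_rank_fdr <- function(scores, refs, fdr = 0.05) {
  scores <- scores[is.finite(scores)]
  genes <- names(scores)
  is_e <- genes %in% refs$essential
  is_n <- genes %in% refs$nonessential
  if (!any(is_e) || !any(is_n))
    stop("cell line lacks reference essential or nonessential genes")
  ord <- order(scores, genes) # deterministic tie-break by gene name
  e_sorted <- is_e[ord]
  ref_sorted <- (is_e | is_n)[ord]
  cum_e <- cumsum(e_sorted)
  cum_ref <- cumsum(ref_sorted)
  ppv <- ifelse(cum_ref > 0, cum_e / cum_ref, NA_real_)
  ok <- which(!is.na(ppv) & ppv >= 1 - fdr)
  if (length(ok) == 0) {
    return(list(k_star = NA_integer_, f_star = NA_real_,
                called = character(0), ppv = ppv))
  }
  k_star <- max(ok)
  f_star <- scores[ord][k_star]
  called <- genes[scores < f_star]
  list(k_star = k_star, f_star = f_star, called = sort(called), ppv = ppv)
}

#' Binarize a score matrix with the per-line rank/precision rule
#'
#' @param m gene x cell-line score matrix.
#' @param refs [reference_sets()].
#' @param fdr FDR level.
#' @return `dependency_calls` with per-line `f_star` recorded.
#' @export
per_line_fdr_binarize <- function(m, refs, fdr = 0.05) {
  m <- score_matrix(m)
  calls <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  f_star <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (l in colnames(m)) {
    res <- per_line_rank_fdr(m[, l], refs, fdr = fdr)
    f_star[l] <- res$f_star
    calls[res$called, l] <- TRUE
  }
  structure(list(calls = calls, threshold = f_star, fdr = fdr,
                 rule = "per_line"), class = "dependency_calls")
}

#' Per-line screen quality as the recall of common essentials
#'
#' For each cell line, the fraction of the given common-essential genes
#' called dependent at the per-line rank/precision FDR rule; a direct
#' true-positive-rate measure of screen quality.
#'
#' @param m gene x cell-line score matrix.
#' @param refs [reference_sets()] defining the per-line FDR rule.
#' @param common character vector of common-essential genes to recover.
#' @param fdr FDR level (default 0.05).
#' @return named numeric vector of per-line TPRs.
#' @export
screen_quality_tpr <- function(m, refs, common, fdr = 0.05) {
  m <- score_matrix(m)
  common <- intersect(common, rownames(m))
  if (length(common) == 0) stop("common-essential set is empty")
  vapply(colnames(m), function(l) {
    res <- per_line_rank_fdr(m[, l], refs, fdr = fdr)
    mean(common %in% res$called)
  }, numeric(1))
}
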