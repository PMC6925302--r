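#' PCA of screen-level dependency profiles
#'
#' Principal components of the transposed gene x screen matrix (each row a
#' screen), centered, unscaled. Returns screen coordinates, gene loadings
#' and the variance-explained ratios (the natural aspect ratio for
#' plotting the first two components).
#'
#' @param m gene x screen score matrix (>= 3 screens).
#' @param meta optional data.frame of per-screen condition labels, carried
#'   through unchanged.
#' @return list: `coords` (screen x PC), `loadings` (gene x PC),
#'   `var_explained`, `meta`.
#' @export
pca_screens <- function(m, meta = NULL) {
  m <- score_matrix(m)
  if (ncol(m) < 3) stop("need >= 3 screens")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  list(coords = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), meta = meta)
}

#' Hypergeometric tail p-value for a set overlap
#'
#' P(X >= k) where X is the overlap of a random draw of `n_list` genes
#' from a universe of `n_universe` containing `n_set` set members.
#' @param k observed overlap. @param n_set set size in universe.
#' @param n_list drawn list size. @param n_universe universe size.
#' @return upper-tail probability.
#' @export
hypergeom_test <- function(k, n_set, n_list, n_universe) {
  stats::phyper(k - 1, n_set, n_universe - n_set, n_list, lower.tail = FALSE)
}

#' Gene-set enrichment in the extreme loadings of principal components
#'
#' For each component, takes the `top_frac` most extreme genes per tail of
#' the loading vector and tests each gene set for over-representation in
#' that list with the hypergeometric tail test, BH-corrected per
#' component.
#'
#' @param loadings gene x PC loading matrix ([pca_screens()]).
#' @param sets named list of gene sets.
#' @param components which components to test (default 1:2).
#' @param top_frac fraction of genes per tail (default 0.05).
#' @return data.frame: component, set, overlap, set_size, list_size, p,
#'   adj_p, enriched.
#' @export
loading_enrichment <- function(loadings, sets, components = 1:2,
                               top_frac = 0.05) {
  universe <- rownames(loadings)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stop("no gene set overlaps the loading universe")
  n_tail <- max(1, round(top_frac * length(universe)))
  res <- list()
  for (pc in components) {
    l <- loadings[, pc]
    ord <- order(l)
    top <- unique(c(universe[utils::head(ord, n_tail)],
                    universe[utils::tail(ord, n_tail)]))
    p <- vapply(sets, function(s)
      hypergeom_test(length(intersect(s, top)), length(s), length(top),
                     length(universe)), numeric(1))
    res[[as.character(pc)]] <- data.frame(
      component = pc, set = names(sets),
      overlap = vapply(sets, function(s) length(intersect(s, top)), integer(1)),
      set_size = lengths(sets), list_size = length(top),
      p = p, adj_p = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$enriched <- out$adj_p < 0.05
  rownames(out) <- NULL
  out
}

#' Within- and between-study correlations of co-targeting sgRNAs
#'
#' For each gene: the mean off-diagonal pairwise Pearson correlation of
#' its guides' fold-change profiles within each study, their average
#' (mean-within), and the mean correlation over all cross-study guide
#' pairs.
#'
#' @param fc_a,fc_b guide x cell-line fold-change matrices (replicates
#'   already collapsed).
#' @param map_a,map_b guide maps.
#' @return data.frame: gene, within_a, within_b, mean_within, between.
#'   Within-study values are NA for single-guide genes.
#' @export
cotargeting_correlations <- function(fc_a, fc_b, map_a, map_b) {
  fa <- fc_matrix(fc_a); fb <- fc_matrix(fc_b)
  lines <- intersect(colnames(fa), colnames(fb))
  fa <- fa[, lines, drop = FALSE]; fb <- fb[, lines, drop = FALSE]
  genes <- intersect(unique(map_a$gene[map_a$sgrna %in% rownames(fa)]),
                     unique(map_b$gene[map_b$sgrna %in% rownames(fb)]))
  mean_offdiag <- function(cm) {
    if (is.null(dim(cm)) || nrow(cm) < 2) return(NA_real_)
    mean(cm[upper.tri(cm)])
  }
  rows <- lapply(genes, function(g) {
    ga <- intersect(map_a$sgrna[map_a$gene == g], rownames(fa))
    gb <- intersect(map_b$sgrna[map_b$gene == g], rownames(fb))
    wa <- if (length(ga) >= 2) mean_offdiag(stats::cor(t(fa[ga, , drop = FALSE]))) else NA_real_
    wb <- if (length(gb) >= 2) mean_offdiag(stats::cor(t(fb[gb, , drop = FALSE]))) else NA_real_
    btw <- if (length(ga) >= 1 && length(gb) >= 1)
      mean(stats::cor(t(fa[ga, , drop = FALSE]), t(fb[gb, , drop = FALSE])))
    else NA_real_
    data.frame(gene = g, within_a = wa, within_b = wb,
               mean_within = mean(c(wa, wb), na.rm = TRUE), between = btw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean_within[is.nan(out$mean_within)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Median estimated sgRNA efficacy (MESE) per gene and library
#'
#' @param map guide map with an `efficacy` column.
#' @return data.frame: gene, library, mese (NA when no efficacies).
#' @export
mese <- function(map) {
  if (!"efficacy" %in% names(map)) stop("guide map lacks an efficacy column")
  agg <- stats::aggregate(efficacy ~ gene + library, data = map,
                          FUN = function(x) stats::median(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  names(agg)[3] <- "mese"
  agg$mese[is.nan(agg$mese)] <- NA_real_
  agg[order(agg$gene, agg$library), , drop = FALSE]
}

#' Remove study-exclusive genes whose guide efficacies differ
#'
#' Builds the null distribution of per-gene mean-efficacy differences from
#' genes in neither study-exclusive set and removes, from each exclusive
#' set, genes whose efficacy difference lies more than 2 null SDs from the
#' null mean — so downstream functional enrichment of exclusive
#' dependencies is not confounded by reagent quality.
#'
#' @param eff_a,eff_b named per-gene mean efficacy vectors for the two
#'   libraries.
#' @param exclusive_a,exclusive_b study-exclusive gene sets.
#' @param n_sd exclusion width (default 2).
#' @return list: filtered `exclusive_a`/`exclusive_b`, `removed`,
#'   `null_mean`, `null_sd`.
#' @export
efficacy_difference_filter <- function(eff_a, eff_b, exclusive_a, exclusive_b,
                                       n_sd = 2) {
  genes <- intersect(names(eff_a), names(eff_b))
  diffs <- eff_a[genes] - eff_b[genes]
  null_genes <- setdiff(genes, union(exclusive_a, exclusive_b))
  if (length(null_genes) < 2) stop("null gene set is empty or too small")
  mu <- mean(diffs[null_genes]); sdev <- stats::sd(diffs[null_genes])
  keep <- function(g) {
    g <- intersect(g, genes)
    g[abs(diffs[g] - mu) <= n_sd * sdev]
  }
  removed <- setdiff(union(exclusive_a, exclusive_b),
                     union(keep(exclusive_a), keep(exclusive_b)))
  list(exclusive_a = keep(exclusive_a), exclusive_b = keep(exclusive_b),
       removed = removed, null_mean = mu, null_sd = sdev)
}

#' Functional enrichment of study-exclusive dependencies, per cell line
#'
#' For each cell line, identifies genes called dependent in exactly one
#' study (within the supplied universe), tests every gene set for
#' over-representation in each exclusive list (hypergeometric tail),
#' BH-corrects across all tests of a study, and summarizes each set by the
#' fraction of lines in which it is enriched (adjusted p < 0.05).
#'
#' @param calls_a,calls_b aligned `dependency_calls` or logical matrices.
#' @param sets named list of gene sets.
#' @param universe gene universe (default: the call matrix rows), e.g.
#'   after [efficacy_difference_filter()].
#' @return list with `tests` (long data.frame) and `summary` (per set and
#'   study, fraction of lines enriched). Lines without exclusive genes are
#'   skipped.
#' @export
exclusive_dependency_enrichment <- function(calls_a, calls_b, sets,
                                            universe = NULL) {
  ca <- if (inherits(calls_a, "dependency_calls")) calls_a$calls else calls_a
  cb <- if (inherits(calls_b, "dependency_calls")) calls_b$calls else calls_b
  if (!identical(dimnames(ca), dimnames(cb))) stop("call matrices not aligned")
  if (is.null(universe)) universe <- rownames(ca)
  universe <- intersect(universe, rownames(ca))
  ca <- ca[universe, , drop = FALSE]; cb <- cb[universe, , drop = FALSE]
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0)
    return(list(tests = data.frame(), summary = data.frame()))
  rows <- list()
  for (l in colnames(ca)) {
    for (study in c("A", "B")) {
      excl <- if (study == "A") universe[ca[, l] & !cb[, l]] else
        universe[cb[, l] & !ca[, l]]
      if (length(excl) == 0) next
      p <- vapply(sets, function(s)
        hypergeom_test(length(intersect(s, excl)), length(s), length(excl),
                       length(universe)), numeric(1))
      rows[[paste(l, study)]] <- data.frame(
        cell_line = l, study = study, set = names(sets),
        overlap = vapply(sets, function(s) length(intersect(s, excl)), integer(1)),
        n_exclusive = length(excl), p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(list(tests = data.frame(), summary = data.frame()))
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$adj_p <- NA_real_
  for (study in c("A", "B")) {
    i <- tests$study == study
    tests$adj_p[i] <- stats::p.adjust(tests$p[i], "BH")
  }
  tests$enriched <- tests$adj_p < 0.05
  n_lines_tested <- tapply(tests$cell_line, paste(tests$study, tests$set),
                           function(x) length(unique(x)))
  enr <- tapply(tests$enriched, paste(tests$study, tests$set), sum)
  key <- strsplit(names(enr), " ", fixed = TRUE)
  summary <- data.frame(study = vapply(key, `[[`, character(1), 1),
                        set = vapply(key, function(k)
                          paste(k[-1], collapse = " "), character(1)),
                        frac_lines_enriched = as.vector(enr / n_lines_tested),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(tests = tests, summary = summary)
}

#' Resampling test for differential depletion of a gene set across studies
#'
#' Observed statistic: the difference between the two studies' median
#' per-gene mean scores over the set
#' (`median_A(set) - median_B(set)` on gene-mean profiles). The null draws
#' size-matched random gene sets from the universe; both the empirical
#' p-value and a Gaussian-tail p-value extrapolated from the null's
#' mean/SD are reported (the extrapolation covers observed differences
#' more extreme than any resample).
#'
#' @param means_a,means_b named per-gene mean score vectors.
#' @param set gene set to test.
#' @param n_perm resamples (default 10000).
#' @param alternative "two.sided" (default), "less" or "greater"
#'   (direction of `delta`).
#' @return list: `delta`, `p_empirical`, `p_gaussian`, `null_mean`,
#'   `null_sd`, `n_perm`.
#' @export
early_late_resampling_test <- function(means_a, means_b, set,
                                       n_perm = 10000,
                                       alternative = c("two.sided", "less",
                                                       "greater")) {
  alternative <- match.arg(alternative)
  genes <- intersect(names(means_a), names(means_b))
  set <- intersect(set, genes)
  if (length(set) == 0) stop("gene set absent from universe")
  if (length(set) > length(genes)) stop("set larger than universe")
  a <- means_a[genes]; b <- means_b[genes]
  delta <- stats::median(a[set]) - stats::median(b[set])
  n <- length(set)
  null <- vapply(seq_len(n_perm), function(i) {
    g <- sample(genes, n)
    stats::median(a[g]) - stats::median(b[g])
  }, numeric(1))
  mu <- mean(null); sdev <- stats::sd(null)
  z <- (delta - mu) / sdev
  p_emp <- switch(alternative,
                  two.sided = (sum(abs(null - mu) >= abs(delta - mu)) + 1) / (n_perm + 1),
                  less = (sum(null <= delta) + 1) / (n_perm + 1),
                  greater = (sum(null >= delta) + 1) / (n_perm + 1))
  p_gauss <- switch(alternative,
                    two.sided = 2 * stats::pnorm(-abs(z)),
                    less = stats::pnorm(z),
                    greater = stats::pnorm(-z))
  list(delta = delta, p_empirical = p_emp, p_gaussian = p_gauss,
       null_mean = mu, null_sd = sdev, n_perm = n_perm)
}

#' Difference profiles between screens differing in one condition
#'
#' Given a gene x screen score matrix and per-screen condition metadata
#' (`screen`, `cell_line`, `library`, `timepoint`, `clone`, `site`), finds
#' all screen pairs that differ in exactly one declared condition, forms
#' the per-gene difference profile (second minus first level of the
#' varying condition), and reports the pairwise correlation matrix of
#' these profiles. If a `reference` screen and a mean cross-study
#' difference profile are supplied, also reports, per contrast, the SD of
#' the difference against the reference and its correlation with the mean
#' difference profile (detrending statistics).
#'
#' @param m gene x screen matrix.
#' @param meta data.frame with a `screen` column matching `colnames(m)`
#'   plus condition columns.
#' @param conditions condition columns to scan (default
#'   `c("library", "timepoint", "clone", "site")`).
#' @param reference optional screen name: each other screen's difference
#'   from it is summarized.
#' @param mean_difference optional named per-gene vector (mean inter-study
#'   difference) to correlate reference differences against.
#' @return list: `profiles` (gene x contrast matrix), `contrasts`
#'   (data.frame describing each), `correlations` (contrast correlation
#'   matrix), and `detrending` (per-screen SD and correlation versus the
#'   reference) when a reference is given.
#' @export
condition_difference_analysis <- function(m, meta,
                                          conditions = c("library", "timepoint",
                                                         "clone", "site"),
                                          reference = NULL,
                                          mean_difference = NULL) {
  m <- score_matrix(m)
  meta <- as.data.frame(meta)
  if (!"screen" %in% names(meta)) stop("meta needs a `screen` column")
  meta <- meta[match(colnames(m), meta$screen), , drop = FALSE]
  conditions <- intersect(conditions, names(meta))
  match_cols <- c("cell_line", conditions)
  profiles <- list(); desc <- list()
  n <- ncol(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- vapply(match_cols, function(cc)
        identical(meta[[cc]][i], meta[[cc]][j]), logical(1))
      differing <- match_cols[!same]
      if (length(differing) != 1 || !(differing %in% conditions)) next
      # orient: higher-sorted level minus lower, so profiles are comparable
      lev <- order(as.character(meta[[differing]][c(i, j)]))
      hi <- c(i, j)[lev[2]]; lo <- c(i, j)[lev[1]]
      nm <- sprintf("%s-%s|%s", meta$screen[hi], meta$screen[lo], differing)
      profiles[[nm]] <- m[, hi] - m[, lo]
      desc[[nm]] <- data.frame(contrast = nm, cell_line = meta$cell_line[i],
                               condition = differing,
                               level_hi = as.character(meta[[differing]][hi]),
                               level_lo = as.character(meta[[differing]][lo]),
                               stringsAsFactors = FALSE)
    }
  }
  if (length(profiles) == 0) stop("no screen pairs differ in exactly one condition")
  prof <- do.call(cbind, profiles)
  out <- list(profiles = prof,
              contrasts = do.call(rbind, c(desc, make.row.names = FALSE)),
              correlations = if (ncol(prof) > 1) stats::cor(prof) else NULL)
  if (!is.null(reference)) {
    if (!reference %in% colnames(m)) stop("reference screen not found")
    others <- setdiff(colnames(m), reference)
    det <- do.call(rbind, lapply(others, function(s) {
      d <- m[, s] - m[, reference]
      data.frame(screen = s, sd_difference = stats::sd(d),
                 var_difference = stats::var(d),
                 cor_with_mean_difference = if (is.null(mean_difference))
                   NA_real_ else stats::cor(d, mean_difference[rownames(m)]),
                 stringsAsFactors = FALSE)
    }))
    out$detrending <- det
  }
  out
}
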