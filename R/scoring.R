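#' Reads-per-million normalization with pseudocount
#'
#' Scales each sample column to reads per million and adds a pseudocount
#' (default 1) afterwards, so downstream log fold changes are always
#' defined.
#'
#' @param screen [count_screen()] or a plain count matrix.
#' @param pseudocount value added to the RPM (default 1).
#' @return numeric matrix of RPM + pseudocount, same shape as the counts.
#' @export
counts_to_rpm <- function(screen, pseudocount = 1) {
  counts <- if (inherits(screen, "count_screen")) screen$counts else as.matrix(screen)
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, cs, "/") * 1e6 + pseudocount
}

#' Log2 fold change of each screen sample versus its pDNA reference
#'
#' Multiple pDNA RPM profiles within a batch are median-collapsed to a
#' single reference profile; every non-pDNA sample is compared to the
#' reference of its own pDNA batch:
#' `FC = log2(sample RPM) - log2(pDNA reference RPM)` (pseudocount already
#' applied by [counts_to_rpm()]).
#'
#' @param rpm matrix from [counts_to_rpm()].
#' @param meta sample metadata (`sample`, `is_pdna`, `pdna_batch`, ...).
#' @return list of class `fold_change_matrix`: `fc` (sgRNA x replicate
#'   matrix, pDNA columns removed) and `meta` (metadata of the retained
#'   columns, with the pDNA batch used recorded).
#' @export
log_fold_change <- function(rpm, meta) {
  meta <- as.data.frame(meta)
  meta <- meta[match(colnames(rpm), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("metadata missing for some rpm columns")
  pdna_ref <- list()
  for (b in unique(meta$pdna_batch[meta$is_pdna])) {
    cols <- meta$sample[meta$is_pdna & meta$pdna_batch == b]
    prof <- rpm[, cols, drop = FALSE]
    pdna_ref[[b]] <- if (ncol(prof) == 1) prof[, 1] else
      apply(prof, 1, stats::median)
  }
  smeta <- meta[!meta$is_pdna, , drop = FALSE]
  missing_b <- setdiff(unique(smeta$pdna_batch), names(pdna_ref))
  if (length(missing_b) > 0)
    stop("no pDNA profile for batch(es): ", paste(missing_b, collapse = ", "))
  fc <- matrix(NA_real_, nrow(rpm), nrow(smeta),
               dimnames = list(rownames(rpm), smeta$sample))
  for (i in seq_len(nrow(smeta)))
    fc[, i] <- log2(rpm[, smeta$sample[i]]) - log2(pdna_ref[[smeta$pdna_batch[i]]])
  structure(list(fc = fc, meta = smeta), class = "fold_change_matrix")
}

fc_matrix <- function(fc) if (inherits(fc, "fold_change_matrix")) fc$fc else as.matrix(fc)

#' Collapse guide-level fold changes to gene level
#'
#' Applies the chosen statistic (median for minimally processed scores,
#' mean ahead of batch correction) over the sgRNAs targeting each gene.
#' Guides absent from the map, and genes left with zero guides, are dropped
#' (the latter with a warning).
#'
#' @param fc [log_fold_change()] result or sgRNA x sample matrix.
#' @param map guide map data.frame (`sgrna`, `gene`).
#' @param stat "median" or "mean".
#' @return gene x sample matrix.
#' @export
collapse_guides <- function(fc, map, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  m <- fc_matrix(fc)
  idx <- match(rownames(m), map$sgrna)
  if (all(is.na(idx))) stop("no fold-change rows found in guide map")
  keep <- !is.na(idx)
  m <- m[keep, , drop = FALSE]
  gene <- map$gene[idx[keep]]
  mapped_genes <- unique(map$gene)
  lost <- setdiff(mapped_genes, gene)
  if (length(lost) > 0)
    warning(length(lost), " gene(s) dropped: no retained guides")
  collapse_by(m, gene, stat)
}

collapse_by <- function(m, groups, stat) {
  g <- factor(groups, levels = sort(unique(groups)))
  if (stat == "mean") {
    out <- rowsum(m, g) / as.vector(table(g))
    rownames(out) <- levels(g)
    return(out)
  }
  idx <- split(seq_along(groups), g)
  out <- do.call(rbind, lapply(idx, function(i) {
    if (length(i) == 1) m[i, ] else apply(m[i, , drop = FALSE], 2, stats::median)
  }))
  dimnames(out) <- list(names(idx), colnames(m))
  out
}

#' Anchor gene scores to reference essential / nonessential medians
#'
#' Shifts and scales each column (replicate or cell line) so the median of
#' the nonessential reference genes is exactly 0 and the median of the
#' essential reference genes exactly -1:
#' `x' = (x - med_noness) / (med_noness - med_ess)`.
#' In `mode = "global"` a single factor rescales the whole matrix so the
#' essential-gene median across all columns is -1 (no per-column shift).
#'
#' @param m gene x column matrix.
#' @param refs [reference_sets()].
#' @param mode "per_column" (default) or "global".
#' @return matrix of the same shape, anchored.
#' @export
scale_to_reference <- function(m, refs, mode = c("per_column", "global")) {
  mode <- match.arg(mode)
  m <- score_matrix(m)
  ess <- intersect(refs$essential, rownames(m))
  non <- intersect(refs$nonessential, rownames(m))
  if (length(ess) == 0 || length(non) == 0)
    stop("reference genes absent from matrix")
  if (mode == "global") {
    med_e <- stats::median(m[ess, ])
    if (med_e == 0) stop("degenerate scale: essential median is 0")
    return(m / -med_e)
  }
  med_n <- apply(m[non, , drop = FALSE], 2, stats::median)
  med_e <- apply(m[ess, , drop = FALSE], 2, stats::median)
  if (any(med_n == med_e))
    stop("degenerate scale: essential and nonessential medians equal in column ",
         colnames(m)[which(med_n == med_e)[1]])
  sweep(sweep(m, 2, med_n, "-"), 2, med_n - med_e, "/")
}

#' Collapse replicate columns to one column per cell line
#'
#' @param m gene x replicate matrix.
#' @param cell_line character vector: the cell line of each column.
#' @param stat "median" (default) or "mean".
#' @return gene x cell-line matrix.
#' @export
collapse_replicates <- function(m, cell_line, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  m <- score_matrix(m)
  if (length(cell_line) != ncol(m))
    stop("cell_line must label every column")
  t(collapse_by(t(m), cell_line, stat))
}

#' Quantile normalization
#'
#' Forces every column onto the common distribution whose sorted values are
#' the across-column means of the input's sorted values; within-column ranks
#' are preserved and ties receive the mean of their tied target values.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- score_matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 columns")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Full scoring pipeline: counts to an unprocessed gene score matrix
#'
#' Chains RPM conversion, pDNA-referenced log fold change, guide collapse,
#' reference-set anchoring per replicate and replicate collapse, yielding
#' the minimally processed gene-by-cell-line score matrix.
#'
#' @param screen [count_screen()].
#' @param map guide map (see [read_guide_map()]).
#' @param refs [reference_sets()].
#' @param guide_stat,replicate_stat collapse statistics (defaults: median).
#' @param scale_mode passed to [scale_to_reference()].
#' @param pseudocount passed to [counts_to_rpm()].
#' @return [gene_score_matrix()] with level "unprocessed".
#' @export
score_screen <- function(screen, map, refs,
                         guide_stat = "median", replicate_stat = "median",
                         scale_mode = "per_column", pseudocount = 1) {
  rpm <- counts_to_rpm(screen, pseudocount = pseudocount)
  fc <- log_fold_change(rpm, screen$meta)
  gene_rep <- collapse_guides(fc, map, stat = guide_stat)
  scaled <- scale_to_reference(gene_rep, refs, mode = scale_mode)
  scores <- collapse_replicates(scaled, fc$meta$cell_line, stat = replicate_stat)
  gene_score_matrix(scores,
                    study = unique(fc$meta$study)[1], level = "unprocessed",
                    library = unique(fc$meta$library)[1],
                    timepoint = unique(fc$meta$timepoint)[1])
}
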