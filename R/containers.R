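#' Construct a count screen
#'
#' Bundles an sgRNA-by-sample read count matrix with its sample metadata.
#' Metadata must contain one row per count column, keyed by `sample`, and
#' carry the experimental annotations needed downstream: cell line,
#' replicate, pDNA flag and batch, study, library and time point.
#'
#' @param counts numeric matrix, sgRNAs in rows (named), samples in columns
#'   (named). Values must be non-negative and finite.
#' @param meta data.frame with at least columns `sample`, `cell_line`,
#'   `replicate`, `is_pdna` (logical), `pdna_batch`, `study`, `library`,
#'   `timepoint`. Extra columns (e.g. `media`, `clone`) are preserved.
#' @return An object of class `count_screen`: a list with elements `counts`
#'   and `meta`, metadata ordered to match the count columns.
#' @export
count_screen <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have sgRNA rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sgRNA ids in count matrix")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite count at sgRNA '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  meta <- as.data.frame(meta)
  required <- c("sample", "cell_line", "replicate", "is_pdna", "pdna_batch",
                "study", "library", "timepoint")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(colnames(counts), meta$sample)
  if (length(unknown) > 0)
    stop("no metadata for sample(s): ", paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  # every non-pDNA sample must be able to reach a pDNA reference profile
  pdna_batches <- unique(meta$pdna_batch[meta$is_pdna])
  orphan <- meta$sample[!meta$is_pdna & !(meta$pdna_batch %in% pdna_batches)]
  if (length(orphan) > 0)
    stop("sample(s) with no pDNA profile in their batch: ",
         paste(orphan, collapse = ", "))
  structure(list(counts = counts, meta = meta), class = "count_screen")
}

#' @export
print.count_screen <- function(x, ...) {
  n_pdna <- sum(x$meta$is_pdna)
  cat(sprintf("count_screen: %d sgRNAs x %d samples (%d pDNA), study %s, library %s\n",
              nrow(x$counts), ncol(x$counts), n_pdna,
              paste(unique(x$meta$study), collapse = "/"),
              paste(unique(x$meta$library), collapse = "/")))
  invisible(x)
}

#' Construct a gene score matrix
#'
#' A gene-by-cell-line matrix of dependency scores (log2 fold changes,
#' possibly normalized), tagged with its provenance: study of origin,
#' processing level, sgRNA library and assay time point.
#'
#' @param scores numeric matrix, genes in rows, cell lines in columns, both
#'   named and free of duplicates.
#' @param study,level,library,timepoint provenance tags; `level` is one of
#'   "unprocessed", "processed", "corrected".
#' @return The matrix with class `gene_score_matrix` and provenance
#'   attributes. Behaves as a plain matrix in arithmetic.
#' @export
gene_score_matrix <- function(scores, study = NA_character_,
                              level = c("unprocessed", "processed", "corrected"),
                              library = NA_character_, timepoint = NA_real_) {
  scores <- as.matrix(scores)
  level <- match.arg(level)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must have gene rownames and cell-line colnames")
  if (anyDuplicated(rownames(scores))) stop("duplicate gene rows")
  if (anyDuplicated(colnames(scores))) stop("duplicate cell-line columns")
  if (any(is.infinite(scores))) stop("infinite score values")
  structure(scores,
            study = study, level = level,
            screen_library = library, timepoint = timepoint,
            class = c("gene_score_matrix", class(scores)))
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat(sprintf("gene_score_matrix: %d genes x %d cell lines [study %s, %s]\n",
              nrow(x), ncol(x), attr(x, "study"), attr(x, "level")))
  invisible(x)
}

# strip the class/attributes for internal numeric work
score_matrix <- function(x) {
  if (inherits(x, "gene_score_matrix")) {
    attrs <- c("study", "level", "screen_library", "timepoint")
    for (a in attrs) attr(x, a) <- NULL
    class(x) <- "matrix"
    x <- unclass(x)
  }
  as.matrix(x)
}

#' Reference essential / nonessential gene sets
#'
#' @param essential,nonessential character vectors of gene symbols; must be
#'   disjoint and non-empty.
#' @return list of class `reference_sets`.
#' @export
reference_sets <- function(essential, nonessential) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  if (length(essential) == 0 || length(nonessential) == 0)
    stop("reference sets must be non-empty")
  if (length(intersect(essential, nonessential)) > 0)
    stop("essential and nonessential sets overlap")
  structure(list(essential = essential, nonessential = nonessential),
            class = "reference_sets")
}
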