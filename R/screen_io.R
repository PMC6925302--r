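#' @keywords internal
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_matrix_file <- function(path, what = "matrix") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                         check.names = FALSE, quote = "",
                         stringsAsFactors = FALSE, comment.char = "")
  if (ncol(d) < 2) stop(what, " file needs an id column plus >=1 data column: ", path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", what, " file ", path, ": ",
         paste(utils::head(ids[duplicated(ids)], 3), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an sgRNA count screen
#'
#' The count file holds sgRNA ids in the first column and one column per
#' sample; the metadata file one row per sample (columns `sample`,
#' `cell_line`, `replicate`, `is_pdna`, `pdna_batch`, `study`, `library`,
#' `timepoint`, optionally `media`, `clone`). Delimiter is inferred from the
#' extension (.tsv tab, .csv comma). Negative counts and samples without
#' metadata or pDNA references are rejected with the offending sample named.
#'
#' @param path count matrix file.
#' @param metadata_path sample metadata file.
#' @return [count_screen()] object.
#' @export
read_count_screen <- function(path, metadata_path) {
  m <- read_matrix_file(path, "count")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative count in %s at row '%s', column '%s'",
                 path, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  meta <- utils::read.table(metadata_path, sep = delim_for(metadata_path),
                            header = TRUE, stringsAsFactors = FALSE, quote = "",
                            na.strings = c("NA", ""))
  if (!"is_pdna" %in% names(meta)) stop("metadata lacks is_pdna column")
  meta$is_pdna <- as.logical(meta$is_pdna)
  count_screen(m, meta)
}

#' @rdname read_count_screen
#' @param screen [count_screen()] to write.
#' @export
write_count_screen <- function(screen, path, metadata_path) {
  write_matrix_tsv(screen$counts, path, id_col = "sgrna")
  utils::write.table(screen$meta, metadata_path, sep = delim_for(metadata_path),
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a guide-to-gene map
#'
#' Expects columns `sgrna`, `gene`, `library` and optionally `efficacy`
#' (on-target efficacy in [0,1], may be missing). Guides mapping to more
#' than one gene within a library (duplicated sgrna ids) are dropped, so
#' only guides with one exact gene match are retained.
#'
#' @param path TSV/CSV file.
#' @return data.frame guide map.
#' @export
read_guide_map <- function(path) {
  gm <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sgrna", "gene", "library")
  if (!all(need %in% names(gm)))
    stop("guide map needs columns: ", paste(need, collapse = ", "))
  if (!"efficacy" %in% names(gm)) gm$efficacy <- NA_real_
  multi <- unique(gm$sgrna[duplicated(paste(gm$library, gm$sgrna))])
  if (length(multi) > 0) {
    warning(length(multi), " multi-target sgRNA(s) dropped")
    gm <- gm[!(gm$sgrna %in% multi), , drop = FALSE]
  }
  bad_eff <- !is.na(gm$efficacy) & (gm$efficacy < 0 | gm$efficacy > 1)
  if (any(bad_eff)) stop("efficacy outside [0,1] for sgRNA ",
                         gm$sgrna[which(bad_eff)[1]])
  gm
}

#' Read a gene score matrix with provenance metadata
#'
#' @param path TSV/CSV, genes in the first column, cell lines as headers.
#' @param study,level,library,timepoint provenance tags (see
#'   [gene_score_matrix()]).
#' @param mapping optional two-column data.frame (from, to) applied to gene
#'   ids before constructing the matrix; duplicate genes after mapping are
#'   mean-collapsed with a warning.
#' @return [gene_score_matrix()].
#' @export
read_gene_scores <- function(path, study = NA_character_, level = "unprocessed",
                             library = NA_character_, timepoint = NA_real_,
                             mapping = NULL) {
  m <- read_matrix_file(path, "gene score")
  if (!is.null(mapping)) {
    mapped <- mapping[[2]][match(rownames(m), mapping[[1]])]
    keep <- !is.na(mapped)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- mapped[keep]
  }
  if (anyDuplicated(rownames(m))) {
    warning("duplicate gene rows mean-collapsed")
    m <- collapse_rows_mean(m)
  }
  gene_score_matrix(m, study = study, level = level,
                    library = library, timepoint = timepoint)
}

collapse_rows_mean <- function(m) {
  g <- factor(rownames(m), levels = unique(rownames(m)))
  out <- rowsum(m, g) / as.vector(table(g))
  out[levels(g), , drop = FALSE]
}

#' @rdname read_gene_scores
#' @param scores matrix to write.
#' @export
write_gene_scores <- function(scores, path) {
  write_matrix_tsv(score_matrix(scores), path, id_col = "gene")
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' set names and empty member lists are rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0 | lengths(parts) < 3
  if (any(empty)) stop("gene set with empty member list: ", nm[empty][1])
  stats::setNames(sets, nm)
}

#' Read a plain-text gene list (one symbol per line)
#' @param path text file.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' Align two gene score matrices on shared genes and cell lines
#'
#' Restricts both matrices to the intersection of genes and lines, in a
#' common (sorted) order. Errors if either intersection is empty.
#'
#' @param a,b gene score matrices (or plain matrices).
#' @return list of the two aligned matrices.
#' @export
align_studies <- function(a, b) {
  ma <- score_matrix(a); mb <- score_matrix(b)
  genes <- intersect(rownames(ma), rownames(mb))
  lines <- intersect(colnames(ma), colnames(mb))
  if (length(genes) == 0) stop("no genes in common between studies")
  if (length(lines) == 0) stop("no cell lines in common between studies")
  genes <- sort(genes); lines <- sort(lines)
  restore <- function(orig, m) {
    if (inherits(orig, "gene_score_matrix"))
      gene_score_matrix(m, study = attr(orig, "study"), level = attr(orig, "level"),
                        library = attr(orig, "screen_library"),
                        timepoint = attr(orig, "timepoint"))
    else m
  }
  list(a = restore(a, ma[genes, lines, drop = FALSE]),
       b = restore(b, mb[genes, lines, drop = FALSE]))
}
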