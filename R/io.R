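# Readers/writers for the plain-text formats the pipeline consumes. All
# coordinates on disk and in memory are 0-based half-open. readr transparently
# handles gzip-compressed paths.

#' Read a methylome table
#'
#' Reads a bedGraph-like TSV of per-CpG methylation calls with columns
#' `chrom`, `pos` (0-based), `beta`, `coverage` and applies the read-depth
#' filter: only CpGs covered by at least `min_coverage` reads are retained
#' (the conventional WGBS cutoff of five reads by default).
#'
#' @param path TSV file, optionally gzipped, without header.
#' @param min_coverage Minimum read coverage for a CpG to be kept.
#' @return Tibble with `chrom`, `pos`, `beta`, `coverage`, sorted by position
#'   within chromosome.
#' @export
read_methylome <- function(path, min_coverage = 5) {
  # parse problems surface as a line-numbered error below, not as warnings
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "beta", "coverage"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      beta = readr::col_double(),
      coverage = readr::col_double()
    ),
    progress = FALSE, lazy = FALSE
  ))
  pb <- readr::problems(x)
  if (nrow(pb) > 0) {
    stop("malformed methylome line ", pb$row[1], " in ", path, ": expected ",
         pb$expected[1], ", got ", pb$actual[1])
  }
  bad <- which(is.na(x$beta) | x$beta < 0 | x$beta > 1)
  if (length(bad) > 0) {
    stop("beta value outside [0,1] at line ", bad[1], " of ", path)
  }
  x |>
    filter(.data$coverage >= min_coverage) |>
    arrange(.data$chrom, .data$pos)
}

#' Write a methylome table
#' @param m Methylome tibble (`chrom`, `pos`, `beta`, `coverage`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  readr::write_tsv(m[, c("chrom", "pos", "beta", "coverage")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file into an interval tibble
#'
#' Accepts BED3 to BED6; extra columns beyond the sixth are ignored. The
#' optional columns map to `name`, `score`, `strand`.
#'
#' @param path BED file, optionally gzipped.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6L))] <- nm[seq_len(min(ncol(x), 6L))]
  validate_intervals(as_tibble(x[, seq_len(min(ncol(x), 6L)), drop = FALSE]),
                     arg = path)
}

#' Write an interval tibble as BED
#'
#' Writes BED3 plus whichever of `name`, `score`, `strand` are present.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED is positional: name/score placeholders are required once strand is kept
  if ("strand" %in% cols && !"score" %in% cols) x$score <- 0
  if (("score" %in% names(x)) && !"name" %in% cols) x$name <- "."
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#' @param path bedGraph file, optionally gzipped.
#' @return Tibble with `chrom`, `start`, `end`, `value`, sorted.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "value"),
    col_types = "cddd", progress = FALSE, lazy = FALSE
  )
  if (any(!is.finite(x$value))) stop("non-finite signal value in ", path)
  sort_intervals(validate_intervals(x, arg = path))
}

#' Write a 4-column bedGraph signal track
#' @param x Signal tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a binary single-cell accessibility matrix
#'
#' Reads the triplet representation written by [write_accessibility()]:
#' a cell table (`cell`, `count`), a locus BED with `role` (promoter or
#' enhancer) and `gene` columns, and a sparse triplet TSV (`cell_idx`,
#' `locus_idx`) listing open entries.
#'
#' @param dir Directory containing `cells.tsv`, `loci.bed`, `triplets.tsv`.
#' @return An `acc_matrix` object (see [acc_matrix()]).
#' @export
read_accessibility <- function(dir) {
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           col_types = "cd", progress = FALSE)
  loci <- readr::read_tsv(file.path(dir, "loci.bed"),
                          col_names = c("chrom", "start", "end", "role", "gene"),
                          col_types = "cddcc", progress = FALSE)
  trip <- readr::read_tsv(file.path(dir, "triplets.tsv"),
                          col_types = "dd", progress = FALSE)
  mat <- Matrix::sparseMatrix(
    i = trip$cell_idx, j = trip$locus_idx, x = 1,
    dims = c(nrow(cells), nrow(loci))
  )
  acc_matrix(mat, loci = loci, cells = cells)
}

#' Write a binary single-cell accessibility matrix
#' @param m An `acc_matrix` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_accessibility <- function(m, dir) {
  stopifnot(inherits(m, "acc_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(m$cells, file.path(dir, "cells.tsv"), progress = FALSE)
  readr::write_tsv(m$loci[, c("chrom", "start", "end", "role", "gene")],
                   file.path(dir, "loci.bed"), col_names = FALSE,
                   progress = FALSE)
  idx <- Matrix::which(m$matrix != 0, arr.ind = TRUE)
  trip <- tibble(cell_idx = idx[, 1], locus_idx = idx[, 2]) |>
    arrange(.data$cell_idx, .data$locus_idx)
  readr::write_tsv(trip, file.path(dir, "triplets.tsv"), progress = FALSE)
  invisible(dir)
}
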