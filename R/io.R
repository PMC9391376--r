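#' Read and write one-gene-per-line lists
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write a single-cell simulation in 10x-style triplet layout
#'
#' Writes `matrix.mtx` (Matrix Market), `genes.tsv`, `barcodes.tsv` and a
#' `cells.tsv` metadata table into `dir`.
#'
#' @param sim an `sc_sim` (or a list with `counts` and `cell_meta`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sc_mtx <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(sim$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sim$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style triplet layout written by [write_sc_mtx()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and optionally `cells.tsv`.
#' @return list with `counts` (sparse genes x cells) and `cell_meta`.
#' @export
read_sc_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cells.tsv")
  cell_meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  else data.frame(cell_id = colnames(counts))
  list(counts = counts, cell_meta = cell_meta)
}

#' Write a probe count table as TSV files
#'
#' Writes `probe_counts.tsv` (AOI x probe), `probe_map.tsv` and
#' `aoi_metadata.tsv` into `dir`.
#'
#' @param t a [probe_count_table()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dsp_tables <- function(t, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(aoi_id = rownames(t$counts), t$counts,
                                check.names = FALSE),
                     file.path(dir, "probe_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(t$probe_map, file.path(dir, "probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(t$aoi_meta, file.path(dir, "aoi_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read probe-level DSP tables written by [write_dsp_tables()]
#'
#' @param dir directory with `probe_counts.tsv`, `probe_map.tsv`,
#'   `aoi_metadata.tsv`.
#' @return a [probe_count_table()].
#' @export
read_dsp_tables <- function(dir) {
  cnt <- utils::read.delim(file.path(dir, "probe_counts.tsv"),
                           check.names = FALSE)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt$aoi_id
  probe_count_table(m,
                    utils::read.delim(file.path(dir, "probe_map.tsv"),
                                      stringsAsFactors = FALSE),
                    utils::read.delim(file.path(dir, "aoi_metadata.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Read a gene genomic-position table
#'
#' TSV with columns `gene`, `chrom`, `start` (1-based starts).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_gene_positions <- function(path) {
  pos <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom", "start") %in% names(pos)))
    .fail("read_gene_positions: needs columns gene, chrom, start")
  pos
}
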