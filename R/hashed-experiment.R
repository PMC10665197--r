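#' Container for a hashed single-cell experiment
#'
#' Raw input to demultiplexing: sparse cell-by-gene and cell-by-hash-oligo
#' count matrices over the same cells, plus per-cell QC fields.
#'
#' @param gene_counts sparse (or dense) nonnegative integer matrix, cells in
#'   rows, genes in columns.
#' @param hash_counts nonnegative integer matrix, cells in rows, hash oligos
#'   in columns; row names must match `gene_counts`.
#' @param oligo_to_embryo named character vector mapping oligo column names to
#'   embryo ids.
#' @param mito_fraction numeric in \[0,1\], one value per cell.
#' @return object of class `hashed_experiment` with fields `gene_counts`,
#'   `hash_counts`, `oligo_to_embryo`, `umi` (row sums of `gene_counts`) and
#'   `mito_fraction`.
#' @export
hashed_experiment <- function(gene_counts, hash_counts, oligo_to_embryo,
                              mito_fraction) {
  gene_counts <- as(as(gene_counts, "CsparseMatrix"), "generalMatrix")
  hash_counts <- as(as(hash_counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(gene_counts) == 0) stop("experiment has no cells")
  if (!identical(rownames(gene_counts), rownames(hash_counts))) {
    stop("gene and hash matrices must cover identical, identically ordered cells")
  }
  if (any(gene_counts@x < 0) || any(hash_counts@x < 0)) {
    stop("counts must be nonnegative")
  }
  if (length(mito_fraction) != nrow(gene_counts) ||
      any(mito_fraction < 0 | mito_fraction > 1)) {
    stop("mito_fraction must be one value in [0,1] per cell")
  }
  structure(list(
    gene_counts = gene_counts,
    hash_counts = hash_counts,
    oligo_to_embryo = oligo_to_embryo,
    umi = Matrix::rowSums(gene_counts),
    mito_fraction = as.numeric(mito_fraction)
  ), class = "hashed_experiment")
}

#' @export
print.hashed_experiment <- function(x, ...) {
  cat("hashed_experiment:", nrow(x$gene_counts), "cells x",
      ncol(x$gene_counts), "genes;", ncol(x$hash_counts), "hash oligos\n")
  cat("  median UMI:", median(x$umi), " median mito:",
      signif(median(x$mito_fraction), 3), "\n")
  invisible(x)
}

#' Read a hashed experiment from Matrix Market + TSV files
#'
#' Expects the on-disk layout written by [write_simulation()]: `counts.mtx`,
#' `hashes.mtx`, `cells.tsv` (columns `cell`, `mito_fraction`) and
#' `embryos.tsv` (columns `oligo`, `embryo`).
#'
#' @param dir directory containing the files.
#' @return a `hashed_experiment`.
#' @export
read_hashed_experiment <- function(dir) {
  genes <- Matrix::readMM(file.path(dir, "counts.mtx"))
  hashes <- Matrix::readMM(file.path(dir, "hashes.mtx"))
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  embryos <- read.delim(file.path(dir, "embryos.tsv"), stringsAsFactors = FALSE)
  rownames(genes) <- cells$cell
  rownames(hashes) <- cells$cell
  colnames(genes) <- sprintf("g%04d", seq_len(ncol(genes)))
  colnames(hashes) <- embryos$oligo
  hashed_experiment(genes, hashes,
                    setNames(embryos$embryo, embryos$oligo),
                    cells$mito_fraction)
}
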