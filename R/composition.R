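#' Embryo-by-cell-type composition matrix
#'
#' The pivot of all abundance statistics: integer counts of each cell type
#' recovered from each embryo, together with embryo metadata and per-timepoint
#' size factors. Size factors are an embryo's total recovered cells divided by
#' the geometric mean of totals across embryos of the same timepoint, so that
#' within every timepoint they multiply to one.
#'
#' @param counts integer matrix, embryos in rows, cell types in columns.
#' @param metadata data.frame with one row per embryo; must contain columns
#'   `embryo`, `genotype` and `timepoint` (a `batch` column is carried along if
#'   present).
#' @return an object of class `embryo_composition`: a list with elements
#'   `counts`, `metadata` (including a `size_factor` column) and `normalized`
#'   (counts divided by the embryo's size factor).
#' @export
embryo_composition <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("composition counts must be nonnegative integers")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("type%02d", seq_len(ncol(counts)))
  }
  metadata <- as.data.frame(metadata)
  need <- c("embryo", "genotype", "timepoint")
  if (!all(need %in% names(metadata))) {
    stop("embryo metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(metadata) != nrow(counts)) {
    stop("metadata rows must match count matrix rows")
  }
  rownames(counts) <- metadata$embryo
  obj <- structure(list(counts = counts, metadata = metadata),
                   class = "embryo_composition")
  size_factors(obj)
}

#' Per-timepoint size factors for an embryo composition matrix
#'
#' Computes, for every embryo, its total recovered cells divided by the
#' geometric mean of totals across all embryos of the same timepoint, and
#' stores size-factor-normalized counts. Correcting recovery depth within a
#' stage (not across stages) matters because absolute embryo size grows over
#' development.
#'
#' @param m an `embryo_composition`.
#' @return `m` with `metadata$size_factor` and `normalized` refreshed.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "embryo_composition"))
  totals <- rowSums(m$counts)
  if (any(totals == 0)) {
    stop("embryos with zero assigned cells: ",
         paste(m$metadata$embryo[totals == 0], collapse = ", "))
  }
  sf <- numeric(length(totals))
  for (tp in unique(m$metadata$timepoint)) {
    i <- m$metadata$timepoint == tp
    sf[i] <- totals[i] / geo_mean(totals[i])
  }
  m$metadata$size_factor <- sf
  m$normalized <- m$counts / sf
  m
}

#' Tally annotated cells into an embryo-by-cell-type matrix
#'
#' @param cells data.frame with one row per assigned cell; needs columns
#'   `embryo` and `cell_type`.
#' @param embryo_metadata data.frame of embryo records (`embryo`, `genotype`,
#'   `timepoint`, ...); every cell's embryo must appear here.
#' @param cell_types optional character vector fixing the column set (types
#'   never seen still get an explicit zero column); defaults to the types
#'   observed.
#' @return an `embryo_composition` whose row sums equal the number of cells
#'   per embryo.
#' @export
tally <- function(cells, embryo_metadata, cell_types = NULL) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("embryo", "cell_type") %in% names(cells)))
  embryo_metadata <- as.data.frame(embryo_metadata)
  unknown <- setdiff(unique(cells$embryo), embryo_metadata$embryo)
  if (length(unknown)) {
    stop("cells reference unknown embryo id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  if (is.null(cell_types)) cell_types <- sort(unique(cells$cell_type))
  tab <- table(factor(cells$embryo, levels = embryo_metadata$embryo),
               factor(cells$cell_type, levels = cell_types))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  embryo_composition(counts, embryo_metadata)
}

#' Principal components of embryo compositions
#'
#' Centers `log1p` of size-factor-normalized counts across embryos and returns
#' the leading principal-component loadings, the linear preprocessing step
#' ahead of any nonlinear embedding (which is deliberately pluggable and out
#' of scope here).
#'
#' @param m an `embryo_composition`.
#' @param n_components number of components to keep.
#' @param log whether to `log1p`-transform normalized counts first (default
#'   TRUE; variance stabilization for counts).
#' @return list with `loadings` (embryos x components), `sdev`, and `rotation`.
#' @export
composition_pca <- function(m, n_components = 10, log = TRUE) {
  stopifnot(inherits(m, "embryo_composition"))
  if (nrow(m$counts) < 2) stop("need at least 2 embryos for PCA")
  x <- m$normalized
  if (log) x <- log1p(x)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(n_embryos, n_cell_types)")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  list(loadings = pc$x[, k, drop = FALSE],
       sdev = pc$sdev[k],
       rotation = pc$rotation[, k, drop = FALSE])
}

#' @export
print.embryo_composition <- function(x, ...) {
  cat("embryo_composition:", nrow(x$counts), "embryos x", ncol(x$counts),
      "cell types;", length(unique(x$metadata$timepoint)), "timepoint(s)\n")
  invisible(x)
}

#' Write a composition matrix and its size factors to TSV files
#'
#' @param m an `embryo_composition`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_composition <- function(m, dir) {
  stopifnot(inherits(m, "embryo_composition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(data.frame(embryo = rownames(m$counts), m$counts,
                         check.names = FALSE),
              file.path(dir, "composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$metadata[, c("embryo", "timepoint", "size_factor")],
              file.path(dir, "size_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
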