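#' Aggregate cells into per-embryo, per-cell-type pseudo-cells
#'
#' Sums raw counts of all cells sharing an (embryo, cell type) pair into one
#' pseudo-cell profile, the unit of downstream differential-expression
#' testing (the DE model itself lives outside this package). Sums, not
#' means, preserve the count nature of the data for count GLMs. Groups with
#' fewer than `min_cells` member cells are dropped and reported.
#'
#' @param expr cell-by-gene count matrix (sparse or dense) with cell row
#'   names.
#' @param annotations data.frame with one row per cell: columns `cell`,
#'   `embryo`, `cell_type` (extra columns such as genotype/timepoint are
#'   carried through per group).
#' @param min_cells minimal group size (default 5).
#' @return list with `counts` (sparse pseudo-cell x gene matrix), `meta`
#'   (per pseudo-cell: embryo, cell_type, n_cells and carried metadata) and
#'   `dropped` (groups below `min_cells`).
#' @export
aggregate_pseudocells <- function(expr, annotations, min_cells = 5) {
  stopifnot(min_cells >= 1)
  expr <- as(expr, "CsparseMatrix")
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("cell", "embryo", "cell_type") %in% names(annotations)))
  common <- intersect(rownames(expr), annotations$cell)
  if (!length(common)) stop("no annotated cells found in the matrix")
  ann <- annotations[match(common, annotations$cell), , drop = FALSE]
  x <- expr[common, , drop = FALSE]
  grp <- factor(paste(ann$embryo, ann$cell_type, sep = "\r"))
  ind <- Matrix::fac2sparse(grp)           # groups x cells indicator
  sums <- ind %*% x
  n_cells <- as.integer(table(grp)[rownames(sums)])
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  meta <- data.frame(embryo = parts[, 1], cell_type = parts[, 2],
                     n_cells = n_cells, stringsAsFactors = FALSE)
  ## carry per-embryo metadata if present
  extra <- setdiff(names(ann), c("cell", "cell_type"))
  if (length(extra) > 1) {
    per_emb <- unique(ann[, extra, drop = FALSE])
    if (!anyDuplicated(per_emb$embryo)) {
      for (col in setdiff(extra, "embryo")) {
        meta[[col]] <- per_emb[[col]][match(meta$embryo, per_emb$embryo)]
      }
    }
  }
  keep <- meta$n_cells >= min_cells
  dropped <- meta[!keep, c("embryo", "cell_type", "n_cells")]
  rownames(sums) <- paste(meta$embryo, meta$cell_type, sep = ":")
  list(counts = sums[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE],
       dropped = dropped)
}
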