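#' Freeze a reference transform for query projection
#'
#' Computes and stores everything needed to place new cells into a reference
#' principal-component space without refitting: per-gene centering/scaling
#' constants on `log1p` size-factor-normalized expression, the PCA rotation
#' matrix, per-component linear depth-correction coefficients on log10 UMI,
#' and the residualized, labelled reference loadings. Size factors use the
#' reference geometric-mean UMI, so queries are normalized on the reference
#' scale.
#'
#' @param expr cell-by-gene count matrix (sparse or dense) of the reference.
#' @param labels data.frame, one row per reference cell, each column one
#'   annotation level (e.g. major group, tissue, cell type).
#' @param n_components number of principal components to keep (capped at the
#'   matrix rank; atlas-scale practice is 100 for a whole-embryo space and
#'   50 for subspaces).
#' @param scale whether to unit-scale genes after centering (default TRUE);
#'   constant genes are kept with zero loading and reported.
#' @return object of class `projection_model`.
#' @export
fit_reference <- function(expr, labels, n_components = 50, scale = TRUE) {
  expr <- as(expr, "CsparseMatrix")
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  stopifnot(nrow(labels) == nrow(expr))
  umi <- Matrix::rowSums(expr)
  if (any(umi == 0)) stop("reference cells with zero counts")
  geo_umi <- geo_mean(umi)
  x <- log1p(as.matrix(expr) / (umi / geo_umi))
  centers <- colMeans(x)
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  scales <- if (scale) ifelse(constant, 1, sds) else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  n_components <- min(as.integer(n_components), nrow(x) - 1L, ncol(x))
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  load <- pc$x[, seq_len(n_components), drop = FALSE]
  ## frozen depth correction: per-component slope on centered log10 UMI
  lu <- log10(umi)
  lu_c <- lu - mean(lu)
  slopes <- drop(crossprod(load, lu_c)) / sum(lu_c^2)
  resid <- load - outer(lu_c, slopes)
  structure(list(
    genes = colnames(expr),
    centers = centers,
    scales = scales,
    constant_genes = colnames(expr)[constant],
    rotation = rot,
    sdev = pc$sdev[seq_len(n_components)],
    geo_umi = geo_umi,
    depth_slopes = slopes,
    mean_log10_umi = mean(lu),
    ref_loadings = resid,
    ref_labels = labels
  ), class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("projection_model:", length(x$genes), "genes,",
      ncol(x$rotation), "components,", nrow(x$ref_loadings),
      "reference cells\n")
  invisible(x)
}

#' Project query cells into a frozen reference space
#'
#' Queries are normalized exactly as the reference was (size factor against
#' the stored reference geometric-mean UMI, `log1p`, stored centering and
#' scaling), rotated by the stored matrix, and depth-corrected by
#' subtracting each component's stored linear log10-UMI effect. Genes absent
#' from the query are treated as zero counts before centering (reported via
#' attribute `missing_genes`); an overlap below 50% errors, guarding against
#' a mismatched annotation or species.
#'
#' @param model a [fit_reference()] model.
#' @param expr query cell-by-gene counts; column names are matched to the
#'   model's gene list.
#' @return matrix of residualized component loadings (cells x components).
#' @export
project_cells <- function(model, expr) {
  stopifnot(inherits(model, "projection_model"))
  expr <- as(expr, "CsparseMatrix")
  overlap <- intersect(colnames(expr), model$genes)
  if (length(overlap) < 0.5 * length(model$genes)) {
    stop("query shares only ", length(overlap), "/", length(model$genes),
         " genes with the reference; refusing to project")
  }
  full <- Matrix::Matrix(0, nrow(expr), length(model$genes), sparse = TRUE,
                         dimnames = list(rownames(expr), model$genes))
  full[, overlap] <- expr[, overlap, drop = FALSE]
  umi <- Matrix::rowSums(full)
  if (any(umi == 0)) stop("query cells with zero counts on model genes")
  x <- log1p(as.matrix(full) / (umi / model$geo_umi))
  xs <- sweep(sweep(x, 2, model$centers), 2, model$scales, "/")
  load <- xs %*% model$rotation
  lu_c <- log10(umi) - model$mean_log10_umi
  out <- load - outer(lu_c, model$depth_slopes)
  attr(out, "missing_genes") <- setdiff(model$genes, overlap)
  out
}

#' Transfer labels to projected cells by k-NN majority vote
#'
#' Each query cell takes the majority label among its `k` nearest reference
#' cells in residualized component space. Ties are broken by
#' inverse-distance-weighted vote, then by the smaller mean neighbour
#' distance, deterministically.
#'
#' @param model a [fit_reference()] model.
#' @param loadings query loadings from [project_cells()].
#' @param k number of neighbours (default 10).
#' @param level which label column of the model's reference labels to
#'   transfer (default the first).
#' @param method k-NN backend, `"exact"` or `"ivf"`.
#' @return data.frame with `label`, `vote_frac`, `mean_dist` and
#'   `low_confidence` (vote fraction <= 0.5), one row per query cell.
#' @export
transfer_labels <- function(model, loadings, k = 10, level = NULL,
                            method = c("exact", "ivf")) {
  stopifnot(inherits(model, "projection_model"))
  method <- match.arg(method)
  if (is.null(level)) level <- names(model$ref_labels)[1]
  lab <- as.character(model$ref_labels[[level]])
  nn <- knn_search(model$ref_loadings, loadings, k, method)
  n <- nrow(loadings)
  out_label <- character(n)
  vote_frac <- numeric(n)
  mean_dist <- rowMeans(nn$dist)
  for (i in seq_len(n)) {
    li <- lab[nn$index[i, ]]
    tv <- table(li)
    top <- max(tv)
    winners <- names(tv)[tv == top]
    if (length(winners) > 1L) {
      ## inverse-distance-weighted vote among tied labels, then mean distance
      w <- 1 / pmax(nn$dist[i, ], 1e-12)
      wv <- vapply(winners, function(l) sum(w[li == l]), numeric(1))
      winners <- winners[wv == max(wv)]
      if (length(winners) > 1L) {
        md <- vapply(winners, function(l) mean(nn$dist[i, li == l]),
                     numeric(1))
        winners <- winners[order(md, winners)][1]
      }
    }
    out_label[i] <- winners[1]
    vote_frac[i] <- top / k
  }
  data.frame(label = out_label, vote_frac = vote_frac,
             mean_dist = mean_dist,
             low_confidence = vote_frac <= 0.5,
             stringsAsFactors = FALSE)
}

#' Hierarchical projection and label transfer
#'
#' Mirrors atlas practice: queries are first projected into the global
#' reference space and given a major-group label by k-NN majority vote; each
#' group's cells are then re-projected into that group's sub-model and the
#' finer level is transferred there.
#'
#' @param global a [fit_reference()] model whose first label column is the
#'   major group.
#' @param sub_models named list of [fit_reference()] models, one per major
#'   group, whose first label column is the finer level.
#' @param expr query cell-by-gene counts.
#' @param k neighbours per vote (default 10).
#' @param method k-NN backend.
#' @return data.frame per query cell with `major_group`, `label` (finer
#'   level), vote fractions and distances for both passes.
#' @export
transfer_hierarchy <- function(global, sub_models, expr, k = 10,
                               method = c("exact", "ivf")) {
  method <- match.arg(method)
  gl <- project_cells(global, expr)
  pass1 <- transfer_labels(global, gl, k = k, method = method)
  out <- data.frame(major_group = pass1$label,
                    major_vote = pass1$vote_frac,
                    label = NA_character_,
                    vote_frac = NA_real_,
                    mean_dist = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(expr)
  for (grp in unique(pass1$label)) {
    if (!grp %in% names(sub_models)) next
    i <- which(pass1$label == grp)
    sub <- sub_models[[grp]]
    sl <- project_cells(sub, expr[i, , drop = FALSE])
    p2 <- transfer_labels(sub, sl, k = min(k, nrow(sub$ref_loadings)),
                          method = method)
    out$label[i] <- p2$label
    out$vote_frac[i] <- p2$vote_frac
    out$mean_dist[i] <- p2$mean_dist
  }
  out
}

#' Serialize a projection model to JSON
#'
#' Everything in the model (gene constants, rotation, depth coefficients,
#' labelled reference loadings) is written to a single JSON file at full
#' numeric precision, so a saved model reproduces identical transfers.
#'
#' @param model a `projection_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_projection_model <- function(model, path) {
  stopifnot(inherits(model, "projection_model"))
  x <- unclass(model)
  x$rotation_dim <- dim(x$rotation)
  x$ref_dim <- dim(x$ref_loadings)
  x$rotation_rownames <- rownames(x$rotation)
  x$rotation <- as.numeric(x$rotation)
  x$ref_loadings <- as.numeric(x$ref_loadings)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Load a projection model saved by [save_projection_model()]
#' @param path file path.
#' @return a `projection_model`.
#' @export
load_projection_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- matrix(x$rotation, x$rotation_dim[1], x$rotation_dim[2])
  rownames(rot) <- x$rotation_rownames
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  ref <- matrix(x$ref_loadings, x$ref_dim[1], x$ref_dim[2])
  colnames(ref) <- paste0("PC", seq_len(ncol(ref)))
  structure(list(
    genes = x$genes,
    centers = setNames(x$centers, x$genes),
    scales = setNames(x$scales, x$genes),
    constant_genes = x$constant_genes,
    rotation = rot,
    sdev = x$sdev,
    geo_umi = x$geo_umi,
    depth_slopes = x$depth_slopes,
    mean_log10_umi = x$mean_log10_umi,
    ref_loadings = ref,
    ref_labels = as.data.frame(x$ref_labels, stringsAsFactors = FALSE)
  ), class = "projection_model")
}
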