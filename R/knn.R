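## k-nearest-neighbour search in component space.
##
## The exact backend computes Euclidean distances blockwise via the
## ||a-b||^2 = ||a||^2 + ||b||^2 - 2a.b identity; the approximate backend is
## an inverted-file scheme (coarse k-means partition, probing the closest
## few cells' clusters), standing in for the approximate indexes used at
## atlas scale while staying dependency-free. Exact search is the default
## and the test oracle for the approximate one.

knn_exact <- function(ref, query, k, block = 2048L) {
  ref <- as.matrix(ref)
  query <- as.matrix(query)
  n_ref <- nrow(ref)
  if (k > n_ref) stop("k exceeds the reference size")
  rn2 <- rowSums(ref^2)
  idx <- matrix(0L, nrow(query), k)
  dst <- matrix(0, nrow(query), k)
  starts <- seq(1L, nrow(query), by = block)
  for (s in starts) {
    e <- min(s + block - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(q))) {
      ## order() gives a deterministic index-order tie-break
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, dist = dst)
}

knn_ivf <- function(ref, query, k, n_clusters = NULL, n_probe = 3L) {
  ref <- as.matrix(ref)
  query <- as.matrix(query)
  n_ref <- nrow(ref)
  if (k > n_ref) stop("k exceeds the reference size")
  if (is.null(n_clusters)) {
    n_clusters <- max(2L, min(64L, as.integer(sqrt(n_ref))))
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(20260102L)
  km <- suppressWarnings(kmeans(ref, centers = n_clusters, nstart = 3,
                                iter.max = 50))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  members <- split(seq_len(n_ref), km$cluster)
  idx <- matrix(0L, nrow(query), k)
  dst <- matrix(0, nrow(query), k)
  cd2 <- outer(rowSums(query^2), rowSums(km$centers^2), "+") -
    2 * tcrossprod(query, km$centers)
  for (i in seq_len(nrow(query))) {
    probe <- order(cd2[i, ])[seq_len(min(n_probe, n_clusters))]
    cand <- unlist(members[as.character(probe)], use.names = FALSE)
    while (length(cand) < k && length(probe) < n_clusters) {
      nxt <- order(cd2[i, ])[length(probe) + 1L]
      probe <- c(probe, nxt)
      cand <- unlist(members[as.character(probe)], use.names = FALSE)
    }
    d2 <- colSums((t(ref[cand, , drop = FALSE]) - query[i, ])^2)
    o <- order(d2)[seq_len(k)]
    idx[i, ] <- cand[o]
    dst[i, ] <- sqrt(pmax(d2[o], 0))
  }
  list(index = idx, dist = dst)
}

#' k-nearest neighbours in Euclidean space
#'
#' @param ref reference matrix (rows = points).
#' @param query query matrix with the same number of columns.
#' @param k number of neighbours.
#' @param method `"exact"` (default) or `"ivf"` (approximate inverted-file
#'   search over a coarse k-means partition).
#' @return list with integer `index` (query x k, rows of `ref`) and `dist`.
#' @export
knn_search <- function(ref, query, k, method = c("exact", "ivf")) {
  method <- match.arg(method)
  switch(method,
         exact = knn_exact(ref, query, k),
         ivf = knn_ivf(ref, query, k))
}
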