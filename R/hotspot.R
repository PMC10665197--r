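#' Local Getis-Ord statistic over a k-NN graph of an embedding
#'
#' For each cell, tests whether its `k` nearest neighbours (self excluded;
#' binary weights) carry more or fewer perturbed cells than expected if
#' labels were randomly placed. With \eqn{W_i = k} and binary weights the
#' z-form of the local \eqn{G_i} statistic is
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar x_{(i)} W_i}
#'   {s_{(i)} \sqrt{[(n-1)k - k^2]/(n-2)}}}
#' where \eqn{\bar x_{(i)}} and \eqn{s_{(i)}} are the mean and standard
#' deviation of the indicator over all cells except \eqn{i}. Cells where
#' \eqn{s_{(i)} = 0} (constant label field) are reported as undefined.
#'
#' @param coords numeric matrix of embedding coordinates (2-3 columns).
#' @param x binary perturbation indicator (0/1) per cell.
#' @param k neighbourhood size (default 15).
#' @param include_self if `TRUE`, computes the \eqn{G_i^*} variant in which
#'   the cell's own value joins its neighbourhood.
#' @return a `hotspot_table` data.frame: per cell `g_sum` (perturbed
#'   neighbours), `z`, `p` (two-sided normal), plus the neighbour index
#'   matrix as attribute `"neighbors"`.
#' @export
local_g <- function(coords, x, k = 15, include_self = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(x) == n, all(x %in% c(0, 1)))
  if (k < 1 || k >= n - 1) stop("k must satisfy 1 <= k < n - 1")
  if (anyDuplicated(coords)) {
    warning("duplicate coordinates: k-NN ties broken by index order")
  }
  nn <- knn_exact(coords, coords, k + 1L)
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn$index[i, ]
    self <- match(i, row)
    row <- if (is.na(self)) row[seq_len(k)] else row[-self]
    nbr[i, ] <- row[seq_len(k)]
  }
  xs <- sum(x)
  xq <- sum(x^2)
  g_sum <- rowSums(matrix(x[nbr], n, k))
  if (include_self) {
    g_sum <- g_sum + x
    W <- k + 1
    xbar <- rep(xs / n, n)
    s2 <- rep(xq / n - (xs / n)^2, n)
    denom_n <- sqrt(pmax((n * W - W^2) / (n - 1), 0))
  } else {
    W <- k
    xbar <- (xs - x) / (n - 1)
    s2 <- (xq - x^2) / (n - 1) - xbar^2
    denom_n <- sqrt(pmax(((n - 1) * W - W^2) / (n - 2), 0))
  }
  s <- sqrt(pmax(s2, 0))
  z <- rep(NA_real_, n)
  ok <- s > 0
  z[ok] <- (g_sum[ok] - xbar[ok] * W) / (s[ok] * denom_n)
  out <- data.frame(
    cell = if (is.null(rownames(coords))) seq_len(n) else rownames(coords),
    x = x,
    g_sum = g_sum,
    z = z,
    p = 2 * pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  attr(out, "neighbors") <- nbr
  attr(out, "k") <- k
  class(out) <- c("hotspot_table", class(out))
  out
}

#' Call hot and cold spots with Bonferroni correction
#'
#' Adjusts the two-sided p-values of every defined cell by Bonferroni and
#' calls a cell `hot` (perturbation-enriched neighbourhood) when z > 0 and
#' the adjusted p falls below `alpha`, `cold` when z < 0, `neither`
#' otherwise; cells with undefined z stay `undefined`.
#'
#' @param tab a [local_g()] table.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `tab` with added `p_adj` and `call` columns.
#' @export
call_spots <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "hotspot_table"))
  m <- sum(!is.na(tab$z))
  tab$p_adj <- pmin(1, tab$p * m)
  call <- rep("neither", nrow(tab))
  call[is.na(tab$z)] <- "undefined"
  sig <- !is.na(tab$z) & tab$p_adj < alpha
  call[sig & tab$z > 0] <- "hot"
  call[sig & tab$z < 0] <- "cold"
  tab$call <- call
  tab
}

#' Conditional-permutation p-values for the local G statistic
#'
#' Test oracle for the analytic z: for each cell, holds its own label fixed
#' and redraws its `k` neighbours' labels from the remaining cells,
#' recomputing the neighbourhood sum. The two-sided p is
#' (1 + #{at least as extreme}) / (1 + n_perm), extremity measured as
#' distance of the neighbourhood sum from its conditional expectation.
#'
#' @param coords,x,k as in [local_g()].
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed making the draw reproducible.
#' @return numeric vector of per-cell permutation p-values.
#' @export
permutation_p <- function(coords, x, k = 15, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 99)
  tab <- local_g(coords, x, k)
  nbr <- attr(tab, "neighbors")
  n <- length(x)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  p <- numeric(n)
  for (i in seq_len(n)) {
    others <- x[-i]
    expected <- k * mean(others)
    obs_dev <- abs(tab$g_sum[i] - expected)
    perm <- vapply(seq_len(n_perm), function(b) {
      sum(others[sample.int(n - 1L, k)])
    }, numeric(1))
    p[i] <- (1 + sum(abs(perm - expected) >= obs_dev - 1e-12)) / (1 + n_perm)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  p
}
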