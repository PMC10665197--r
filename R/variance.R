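#' Per-type mean, standard deviation and coefficient of variation
#'
#' Summarizes size-factor-normalized counts across embryos of one timepoint.
#' The coefficient of variation CoV = sd/mean captures how reproducible a
#' cell type's abundance is between genetically identical embryos. Types with
#' zero mean are excluded (reported in the `dropped` attribute).
#'
#' @param m an [embryo_composition()].
#' @param timepoint which timepoint to summarize.
#' @param genotype which genotype (default 0, the control group; variance is
#'   a wild-type baseline property).
#' @return data.frame with columns `cell_type`, `mean`, `sd`, `cov` and
#'   `n_embryos`; sample (n-1) standard deviation.
#' @export
cov_table <- function(m, timepoint, genotype = 0) {
  stopifnot(inherits(m, "embryo_composition"))
  sel <- m$metadata$timepoint == timepoint & m$metadata$genotype == genotype
  if (sum(sel) < 3) stop("need >= 3 embryos at the requested timepoint")
  x <- m$normalized[sel, , drop = FALSE]
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  keep <- mu > 0
  out <- data.frame(
    cell_type = colnames(x)[keep],
    mean = mu[keep],
    sd = s[keep],
    cov = s[keep] / mu[keep],
    n_embryos = sum(sel),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped") <- colnames(x)[!keep]
  out
}

#' Fit the mean-CoV trend with a gamma GLM
#'
#' Regresses each cell type's CoV on its mean normalized count using a
#' gamma-family GLM with identity link and the two-parameter dispersion-style
#' mean function \eqn{E[CoV] = a_0 + a_1 / mean}: an asymptotic CoV floor
#' `a0` that abundant types approach, plus a count-driven `a1/mean` term that
#' dominates for rare types (counting noise). The gamma shape is estimated
#' from Pearson residuals and a 95% confidence band of the fitted curve is
#' returned.
#'
#' @param tab output of [cov_table()].
#' @param response `"cov"` (default) or `"variance"` (alternative response
#'   for the same functional form).
#' @return object of class `variance_fit`: list with `coef` (a0, a1),
#'   `shape`, `table` (the input plus `fitted`), `curve` (grid with `fit`,
#'   `lower`, `upper`) and the underlying `glm` fit.
#' @export
fit_mean_cov <- function(tab, response = c("cov", "variance")) {
  response <- match.arg(response)
  y <- if (response == "cov") tab$cov else tab$sd^2
  ok <- y > 0 & tab$mean > 0
  if (sum(ok) < 5) stop("need >= 5 cell types with positive mean and CoV ",
                        "(did all embryos have identical counts?)")
  d <- data.frame(y = y[ok], inv_mean = 1 / tab$mean[ok])
  ## suppressWarnings: the gamma AIC term emits NaN warnings on exact fits
  fit <- tryCatch(
    suppressWarnings(
      glm(y ~ inv_mean, data = d, family = Gamma(link = "identity"),
          start = pmax(coef(lm(y ~ inv_mean, data = d)), 1e-6))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- glm(y ~ inv_mean, data = d, family = Gamma(link = "identity"),
               start = c(1e-6, 1e-6),
               control = list(maxit = 200))
  }
  a <- coef(fit)
  ## guard: the curve must stay positive over the observed range
  rng <- range(tab$mean[ok])
  if (any(a[1] + a[2] / rng <= 0)) {
    warning("fitted mean-CoV curve non-positive over the data range; ",
            "flooring the asymptote")
    a[1] <- max(a[1], 1e-6)
  }
  ## gamma shape (1/dispersion) from Pearson residuals
  pr <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  shape <- min(1 / max(pr, 1e-12), 1e8)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 100))
  pred <- predict(fit, newdata = data.frame(inv_mean = 1 / grid),
                  se.fit = TRUE)
  tab$fitted <- a[1] + a[2] / tab$mean
  structure(list(
    coef = c(a0 = unname(a[1]), a1 = unname(a[2])),
    shape = shape,
    response = response,
    table = tab,
    curve = data.frame(mean = grid, fit = pred$fit,
                       lower = pred$fit - 1.96 * pred$se.fit,
                       upper = pred$fit + 1.96 * pred$se.fit),
    glm = fit
  ), class = "variance_fit")
}

#' @importFrom stats residuals
#' @export
print.variance_fit <- function(x, ...) {
  cat("variance_fit:", nrow(x$table), "cell types;",
      sprintf("E[%s] = %.3g + %.3g/mean (gamma shape %.1f)\n",
              x$response, x$coef[1], x$coef[2], x$shape))
  invisible(x)
}

#' Flag cell types more variable than the mean-CoV trend predicts
#'
#' For each type, computes the upper-tail probability of its observed CoV
#' under the fitted gamma law (mean given by the fitted curve, shape from the
#' trend fit). One-sided and uncorrected by default, flagging only excess
#' variance; an optional BH correction is available.
#'
#' @param fit a [fit_mean_cov()] result.
#' @param p_threshold flag types with p below this (default 0.05).
#' @param fdr if `TRUE`, BH-adjust the upper-tail p-values first.
#' @return the fit's `table` with added `p_excess` and `flagged` columns.
#' @export
flag_excess <- function(fit, p_threshold = 0.05, fdr = FALSE) {
  stopifnot(inherits(fit, "variance_fit"))
  tab <- fit$table
  y <- if (fit$response == "cov") tab$cov else tab$sd^2
  p <- pgamma(y, shape = fit$shape, rate = fit$shape / tab$fitted,
              lower.tail = FALSE)
  if (fdr) p <- p.adjust(p, "BH")
  tab$p_excess <- p
  tab$flagged <- p < p_threshold
  tab
}
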