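#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats coef dbinom glm Gamma kmeans lm median optim p.adjust
#'   pgamma pnorm prcomp pt predict quantile rbeta rbinom rgamma rlnorm rmultinom
#'   rnorm rpois runif sd setNames var
#' @importFrom utils read.delim write.table head
NULL

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Geometric mean of positive values
#' @param x positive numeric vector
#' @return the geometric mean, exp(mean(log(x)))
#' @keywords internal
geo_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

## Dirichlet sampler via normalized gammas; shape may contain zeros
## (zero-probability categories stay exactly zero).
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha, rate = 1), 0)
  s <- sum(g)
  if (s == 0) stop("degenerate Dirichlet draw: all concentrations zero")
  g / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw from a lognormal parameterized by arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
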