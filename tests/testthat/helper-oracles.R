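## Independent numeric-quadrature oracle for the beta-binomial log-pmf:
## integrates the binomial pmf against the beta mixing density on the logit
## scale (removes endpoint singularities; log1p forms avoid saturation of
## plogis in the tails). Gauss-Kronrod via pracma, split at the integrand
## mode, with tail bounds widened for small shape parameters.
bebin_quad_loglik <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lmax <- lchoose(n, k) - lbeta(a, b)
  lf <- function(t) lmax - (k + a) * log1p(exp(-t)) - (n - k + b) * log1p(exp(t))
  tstar <- qlogis((k + a) / (n + a + b))
  peak <- lf(tstar)
  f <- function(t) exp(lf(t) - peak)
  lo <- tstar - 60 / min(1, k + a)
  hi <- tstar + 60 / min(1, n - k + b)
  v <- pracma::quadgk(f, lo, tstar, tol = 1e-14) +
    pracma::quadgk(f, tstar, hi, tol = 1e-14)
  peak + log(v)
}

## Independent intercept-only beta-binomial MLE: coarse grid over
## (logit mu, logit rho) followed by gradient-free Nelder-Mead polish.
bebin_grid_mle <- function(k, n) {
  ll <- function(par) sum(bebin_loglik(k, n, plogis(par[1]), plogis(par[2])))
  grid_mu <- qlogis(seq(0.01, 0.99, length.out = 40))
  grid_rho <- qlogis(exp(seq(log(1e-4), log(0.5), length.out = 40)))
  best <- c(0, qlogis(0.01))
  best_ll <- -Inf
  for (gm in grid_mu) for (gr in grid_rho) {
    v <- ll(c(gm, gr))
    if (v > best_ll) { best_ll <- v; best <- c(gm, gr) }
  }
  fit <- optim(best, function(p) -ll(p), method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  list(mu = plogis(fit$par[1]), rho = plogis(fit$par[2]),
       loglik = -fit$value)
}
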