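#' Beta-binomial log-likelihood in mean / litter-effect form
#'
#' Log-probability of observing `k` cells of a focal type among `n` total,
#' when the per-embryo proportion is beta-distributed around mean `mu` with
#' intra-class correlation `rho` (the "litter effect": overdispersion with
#' respect to the binomial). The classical shape parameters are
#' \eqn{\alpha = \mu(1-\rho)/\rho} and \eqn{\beta = (1-\mu)(1-\rho)/\rho}, so
#' \eqn{E[k] = n\mu} and \eqn{Var[k] = n\mu(1-\mu)(1 + (n-1)\rho)}.
#' Computed entirely through log-gamma functions; as \eqn{\rho \to 0} it
#' converges to the binomial log-pmf.
#'
#' @param k successes (cells of the focal type), 0 <= k <= n.
#' @param n trials (total cells in the embryo).
#' @param mu mean proportion, in (0,1).
#' @param rho litter effect, in (0,1).
#' @return vector of log-likelihood contributions, one per observation.
#' @export
bebin_loglik <- function(k, n, mu, rho) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly inside (0,1)")
  if (any(rho <= 0 | rho >= 1)) stop("rho must lie strictly inside (0,1)")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

## negative log-likelihood and analytic gradient for the regression
## parameterization: logit(mu) = X_mu theta_mu, logit(rho) = X_rho theta_rho.
bebin_nll <- function(theta, k, n, X_mu, X_rho, fix_rho = NULL) {
  p <- ncol(X_mu)
  mu <- inv_logit(drop(X_mu %*% theta[seq_len(p)]))
  rho <- if (is.null(fix_rho)) {
    inv_logit(drop(X_rho %*% theta[-seq_len(p)]))
  } else rep(fix_rho, length(k))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  rho <- pmin(pmax(rho, 1e-12), 1 - 1e-12)
  -sum(bebin_loglik(k, n, mu, rho))
}

bebin_nll_grad <- function(theta, k, n, X_mu, X_rho, fix_rho = NULL) {
  p <- ncol(X_mu)
  mu <- inv_logit(drop(X_mu %*% theta[seq_len(p)]))
  rho <- if (is.null(fix_rho)) {
    inv_logit(drop(X_rho %*% theta[-seq_len(p)]))
  } else rep(fix_rho, length(k))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  rho <- pmin(pmax(rho, 1e-12), 1 - 1e-12)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  dga <- digamma(k + a) - digamma(n + a + b) - digamma(a) + digamma(a + b)
  dgb <- digamma(n - k + b) - digamma(n + a + b) - digamma(b) + digamma(a + b)
  ## chain rule through (a, b) to the linear predictors
  dmu <- (dga - dgb) * (1 - rho) / rho * mu * (1 - mu)
  g_mu <- -drop(crossprod(X_mu, dmu))
  if (is.null(fix_rho)) {
    drho <- -(dga * mu + dgb * (1 - mu)) / rho^2 * rho * (1 - rho)
    g_rho <- -drop(crossprod(X_rho, drho))
    c(g_mu, g_rho)
  } else {
    g_mu
  }
}

#' Fit a beta-binomial regression for one cell type
#'
#' Maximum-likelihood fit of the abundance model: the focal type's count
#' `k` out of `n` total cells per embryo is beta-binomial with
#' \eqn{logit(\mu) = \beta_0 + \beta_g x + } (optional nuisance terms) and
#' \eqn{logit(\rho) = \chi_0 + \chi_g x}, so both the mean proportion and the
#' between-embryo overdispersion may shift with genotype. Optimization is
#' quasi-Newton (BFGS) with an analytic gradient, started from the null model
#' (pooled proportion, `rho` near 0.01) plus deterministically jittered
#' restarts; standard errors come from the inverse observed information at
#' the optimum and the genotype effect is tested by a two-sided Wald test.
#'
#' @param k,n per-embryo focal-type counts and totals.
#' @param x binary genotype indicator per embryo (`NULL` for an
#'   intercept-only model).
#' @param nuisance optional numeric matrix of extra mean-model covariates
#'   (already transformed/standardized), e.g. a periderm-count proxy for
#'   animal size.
#' @param fix_rho if non-`NULL`, the litter effect is held at this value and
#'   only the mean model is estimated (mainly for the binomial-limit check).
#' @param augment if `TRUE`, adds a Jeffreys-style half pseudo-success and
#'   half pseudo-failure to every embryo, rescuing complete-separation fits.
#' @param n_restarts number of jittered restarts beyond the null start.
#' @param reduce_boundary_dispersion if `TRUE` (default), a fit whose
#'   genotype-specific litter effect collapses to the rho = 0 boundary (the
#'   group dispersion is not identifiable from a handful of replicate
#'   embryos, and the resulting Wald standard error is spuriously small) is
#'   refit with a shared dispersion intercept; the refit is returned with
#'   `dispersion_boundary = TRUE`.
#' @return list with elements `coef_mu`, `coef_rho`, `se_mu`, `se_rho`,
#'   `beta` / `se` / `z` / `p` for the genotype coefficient (NA for
#'   intercept-only fits), `mu_hat` (fitted control-group mean), `rho_hat`,
#'   `loglik`, `converged` and `separation`.
#' @export
fit_bebin <- function(k, n, x = NULL, nuisance = NULL, fix_rho = NULL,
                      augment = FALSE, n_restarts = 2,
                      reduce_boundary_dispersion = TRUE,
                      rho_by_genotype = TRUE) {
  stopifnot(length(k) == length(n), all(k >= 0), all(k <= n))
  has_x <- !is.null(x)
  if (has_x) {
    stopifnot(length(x) == length(k), all(x %in% c(0, 1)))
    if (length(unique(x)) < 2) stop("genotype indicator is constant")
    if (min(table(x)) < 2) stop("need >= 2 embryos per genotype group")
  }
  separation <- FALSE
  if (has_x) {
    for (g in c(0, 1)) {
      kg <- k[x == g]
      ng <- n[x == g]
      if (all(kg == 0) || all(kg == ng)) separation <- TRUE
    }
  }
  if (separation && augment) {
    k <- k + 0.5
    n <- n + 1
  }
  X_mu <- cbind(intercept = rep(1, length(k)))
  if (has_x) X_mu <- cbind(X_mu, genotype = x)
  if (!is.null(nuisance)) X_mu <- cbind(X_mu, as.matrix(nuisance))
  X_rho <- cbind(intercept = rep(1, length(k)))
  if (has_x && rho_by_genotype) X_rho <- cbind(X_rho, genotype = x)

  p <- ncol(X_mu)
  q <- if (is.null(fix_rho)) ncol(X_rho) else 0L
  pooled <- sum(k) / sum(n)
  pooled <- min(max(pooled, 1e-6), 1 - 1e-6)
  start0 <- c(logit(pooled), rep(0, p - 1))
  if (q > 0) start0 <- c(start0, logit(0.01), rep(0, q - 1))

  run <- function(par0) {
    suppressWarnings(
      optim(par0, bebin_nll, bebin_nll_grad, k = k, n = n, X_mu = X_mu,
            X_rho = X_rho, fix_rho = fix_rho, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)))
  }
  best <- run(start0)
  ## deterministic jittered restarts guard against bad local optima
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(20260101L)
  for (r in seq_len(n_restarts)) {
    cand <- tryCatch(run(start0 + rnorm(length(start0), 0, 0.5)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value - 1e-10) best <- cand
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  ## a genotype-specific litter effect that collapses to the rho = 0
  ## boundary is not identifiable from few replicates and yields spuriously
  ## small Wald SEs; refit with a shared dispersion intercept for inference
  if (has_x && rho_by_genotype && is.null(fix_rho) &&
      reduce_boundary_dispersion) {
    group_rho <- inv_logit(c(best$par[p + 1L],
                             best$par[p + 1L] + best$par[p + 2L]))
    if (min(group_rho) < 1e-6 && max(group_rho) >= 1e-6) {
      out <- fit_bebin(k, n, x = x, nuisance = nuisance, fix_rho = fix_rho,
                       augment = FALSE, n_restarts = n_restarts,
                       rho_by_genotype = FALSE)
      out$dispersion_boundary <- TRUE
      out$separation <- separation
      if (separation && !augment) out$p <- out$z <- out$se <- NA_real_
      return(out)
    }
  }

  gnorm <- suppressWarnings(
    sqrt(sum(bebin_nll_grad(best$par, k, n, X_mu, X_rho, fix_rho)^2)))
  converged <- best$convergence == 0 && is.finite(best$value) &&
    gnorm < 1e-3 * max(1, abs(best$value))

  vcov <- matrix(NA_real_, length(best$par), length(best$par))
  if (converged) {
    H <- suppressWarnings(
      optim(best$par, bebin_nll, bebin_nll_grad, k = k, n = n,
            X_mu = X_mu, X_rho = X_rho, fix_rho = fix_rho,
            method = "BFGS", hessian = TRUE,
            control = list(maxit = 0))$hessian)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      vcov <- vc
    } else {
      ## dispersion at its boundary (rho -> 0) makes the chi block of the
      ## observed information degenerate; fall back to the mean-model block
      ## (cross-terms vanish at the boundary), leaving chi SEs missing
      vc_mu <- tryCatch(solve(H[seq_len(p), seq_len(p), drop = FALSE]),
                        error = function(e) NULL)
      if (!is.null(vc_mu) && all(is.finite(diag(vc_mu))) &&
          all(diag(vc_mu) > 0)) {
        vcov[seq_len(p), seq_len(p)] <- vc_mu
      } else {
        converged <- FALSE
      }
    }
  }

  coef_mu <- setNames(best$par[seq_len(p)], colnames(X_mu))
  coef_rho <- if (q > 0) {
    setNames(best$par[p + seq_len(q)], colnames(X_rho))
  } else setNames(numeric(0), character(0))
  se_all <- suppressWarnings(sqrt(diag(vcov)))
  suppress <- separation && !augment
  beta <- se <- z <- pval <- NA_real_
  ## Wald p against a Student-t reference with residual df: with tens of
  ## embryos and an estimated dispersion, the normal reference is visibly
  ## anticonservative in the far tail
  df_resid <- max(1, length(k) - (p + q))
  if (has_x && !suppress && converged) {
    beta <- coef_mu[["genotype"]]
    se <- se_all[2]
    z <- beta / se
    pval <- 2 * pt(-abs(z), df = df_resid)
  } else if (has_x) {
    beta <- coef_mu[["genotype"]]
  }
  list(
    coef_mu = coef_mu,
    coef_rho = coef_rho,
    se_mu = se_all[seq_len(p)],
    se_rho = if (q > 0) se_all[p + seq_len(q)] else numeric(0),
    beta = unname(beta), se = unname(se), z = unname(z), p = unname(pval),
    mu_hat = inv_logit(coef_mu[[1]]),
    rho_hat = if (q > 0) inv_logit(coef_rho[[1]]) else fix_rho,
    loglik = -best$value,
    converged = converged,
    separation = separation,
    dispersion_boundary = FALSE
  )
}

#' Differential cell-type abundance testing across genotypes
#'
#' Fits one beta-binomial regression per (cell type, genotype, timepoint)
#' against stage-matched control embryos (genotype 0), tests the genotype
#' coefficient on the mean by Wald test, and corrects p-values by
#' Benjamini-Hochberg across cell types within each genotype-by-timepoint
#' contrast. A cell type is called differentially abundant (DACT) when its
#' q-value falls below `alpha`.
#'
#' The response is the raw per-embryo count of the focal type with the
#' embryo's total recovered cells as the trials, so recovery-depth
#' differences are absorbed by the binomial denominator; size factors serve
#' visualization and the variance module. A compatibility mode that rounds
#' size-factor-normalized counts instead is available but not recommended.
#'
#' @param m an [embryo_composition()].
#' @param alpha q-value threshold for DACT calls (default 0.01).
#' @param nuisance_type optional cell-type column name (e.g. a periderm
#'   count) entered into the mean model as a standardized `log1p` covariate
#'   and excluded from testing.
#' @param global_fdr if `TRUE`, BH is applied once across all contrasts
#'   instead of within each genotype-by-timepoint contrast.
#' @param rounded_normalized if `TRUE`, uses rounded size-factor-normalized
#'   counts as the response (compatibility mode).
#' @param augment_separation if `TRUE`, separated fits are rescued by
#'   Jeffreys-style augmentation instead of being flagged and skipped.
#' @return data.frame of class `dact_table`: one row per tested (cell type,
#'   genotype, timepoint) with `beta`, `se`, `z`, `p`, `q`, `direction`,
#'   `dact`, `converged`, `separation`, `note`; untestable types are carried
#'   with `note` set and no inference.
#' @export
test_dact <- function(m, alpha = 0.01, nuisance_type = NULL,
                      global_fdr = FALSE, rounded_normalized = FALSE,
                      augment_separation = FALSE) {
  stopifnot(inherits(m, "embryo_composition"))
  md <- m$metadata
  genos <- sort(setdiff(unique(md$genotype), 0))
  if (!length(genos)) stop("no non-control genotypes present")
  counts <- if (rounded_normalized) round(m$normalized) else m$counts
  rows <- list()
  for (tp in sort(unique(md$timepoint))) {
    ctrl <- md$genotype == 0 & md$timepoint == tp
    for (g in genos) {
      pert <- md$genotype == g & md$timepoint == tp
      if (!any(pert)) next
      if (!any(ctrl)) {
        stop("no control embryos at timepoint ", tp,
             " for genotype ", g)
      }
      sel <- ctrl | pert
      kmat <- counts[sel, , drop = FALSE]
      ntot <- rowSums(kmat)
      x <- as.numeric(md$genotype[sel] == g)
      nuis <- NULL
      if (!is.null(nuisance_type)) {
        if (!nuisance_type %in% colnames(kmat)) {
          stop("nuisance_type not found among cell types: ", nuisance_type)
        }
        v <- log1p(kmat[, nuisance_type])
        nuis <- cbind(nuisance = if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
      }
      test_types <- setdiff(colnames(kmat), nuisance_type)
      for (ct in test_types) {
        kk <- kmat[, ct]
        if (sum(kk) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell_type = ct, genotype = g, timepoint = tp,
            beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
            converged = NA, separation = NA, note = "absent",
            stringsAsFactors = FALSE)
          next
        }
        fit <- tryCatch(
          fit_bebin(kk, ntot, x, nuisance = nuis,
                    augment = augment_separation),
          error = function(e) NULL)
        if (is.null(fit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell_type = ct, genotype = g, timepoint = tp,
            beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
            converged = FALSE, separation = NA, note = "fit_error",
            stringsAsFactors = FALSE)
          next
        }
        note <- if (fit$separation && !augment_separation) {
          "separation"
        } else if (!fit$converged) "no_convergence" else ""
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, genotype = g, timepoint = tp,
          beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
          converged = fit$converged, separation = fit$separation,
          note = note, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  testable <- !is.na(out$p)
  if (global_fdr) {
    out$q[testable] <- p.adjust(out$p[testable], "BH")
  } else {
    for (tp in unique(out$timepoint)) {
      for (g in unique(out$genotype)) {
        i <- testable & out$timepoint == tp & out$genotype == g
        if (any(i)) out$q[i] <- p.adjust(out$p[i], "BH")
      }
    }
  }
  out$direction <- ifelse(is.na(out$beta), NA_character_,
                          ifelse(out$beta > 0, "up", "down"))
  out$dact <- !is.na(out$q) & out$q < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("dact_table", class(out))
  out
}
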