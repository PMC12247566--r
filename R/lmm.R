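#' Maximum-likelihood fit of a Gaussian one-random-intercept mixed model
#'
#' Fits `y ~ X + (1 | group)` by maximum likelihood (not REML, so AICs are
#' comparable across fixed-effect structures). The likelihood is profiled
#' down to the single variance ratio `lambda = var_group / var_resid`: for
#' block-diagonal `V = I + lambda * Z Z'` the GLS normal equations reduce to
#' per-group sufficient statistics via the Woodbury identity, which makes a
#' fit cost a handful of group-level cross products per likelihood
#' evaluation. This is what lets the permutation calibration refit hundreds
#' of thousands of models in seconds.
#'
#' AIC counts `k = p + 2` parameters (fixed effects plus the two variances),
#' matching the convention of `lme4::lmer(..., REML = FALSE)`.
#'
#' @param X n x p fixed-effects design matrix (include the intercept).
#' @param y response vector.
#' @param group grouping factor (participant).
#' @return list with `beta`, `se`, `logLik`, `aic`, `sigma2` (residual
#'   variance), `tau2` (group variance), `lambda`, `n`, `k`.
#' @export
lmm_ml <- function(X, y, group) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(group) == n)
  g <- as.integer(factor(group))
  G <- max(g)
  p <- ncol(X)

  stats <- lmm_group_stats(X, y, g, G)
  lambda <- lmm_opt_lambda(stats, n, p)
  fit <- lmm_profile(stats, lambda, n, p, want_cov = TRUE)

  k <- p + 2
  list(beta = drop(fit$beta), se = sqrt(diag(fit$cov_beta)),
       cov_beta = fit$cov_beta,
       logLik = -fit$nll, aic = 2 * k + 2 * fit$nll,
       sigma2 = fit$sigma2, tau2 = lambda * fit$sigma2,
       lambda = lambda, n = n, k = k,
       coef_names = colnames(X))
}

# per-group cross products; everything the profile likelihood needs
lmm_group_stats <- function(X, y, g, G) {
  p <- ncol(X)
  ni <- tabulate(g, G)
  sx <- rowsum(X, g)                 # G x p, per-group column sums
  sy <- drop(rowsum(y, g))           # per-group response sums
  Sxy <- crossprod(X, y)             # pooled
  Syy <- sum(y * y)
  Sxx <- crossprod(X)
  list(ni = ni, sx = sx, sy = sy, Sxx = Sxx, Sxy = Sxy, Syy = Syy, G = G, p = p)
}

# maximize the profile likelihood over the variance ratio; the profile
# deviance is smooth in lambda, so golden-section search on [0, 1e4] with a
# boundary check (lambda = 0, no group variance) suffices
lmm_opt_lambda <- function(st, n, p) {
  prof <- function(lambda) lmm_profile(st, lambda, n, p)$nll
  opt <- stats::optimize(prof, interval = c(0, 1e4), tol = 1e-9)
  if (prof(0) <= opt$objective) 0 else opt$minimum
}

# ML AIC of y ~ X + (1|g) straight from sufficient statistics
lmm_aic_from_stats <- function(st, n, p) {
  lambda <- lmm_opt_lambda(st, n, p)
  2 * (p + 2) + 2 * lmm_profile(st, lambda, n, p)$nll
}

# negative profile log-likelihood and GLS quantities at a given lambda
lmm_profile <- function(st, lambda, n, p, want_cov = FALSE) {
  ci <- lambda / (1 + st$ni * lambda)       # per-group shrinkage weights
  A <- st$Sxx - crossprod(st$sx * sqrt(ci)) # X' V^-1 X
  b <- st$Sxy - crossprod(st$sx, ci * st$sy)
  q <- st$Syy - sum(ci * st$sy^2)
  # aliased (rank-deficient) designs, e.g. duplicated predictors, get a
  # minimal ridge so the fit degenerates gracefully instead of failing
  R <- tryCatch(chol(A), error = function(e)
    chol(A + diag(1e-10 * max(diag(A)) + 1e-300, nrow(A))))
  beta <- backsolve(R, forwardsolve(t(R), b))
  rss <- max(q - sum(b * beta), 1e-300)
  sigma2 <- rss / n
  logdetV <- sum(log1p(st$ni * lambda))
  nll <- 0.5 * (n * (log(2 * pi * sigma2) + 1) + logdetV)
  cov_beta <- if (want_cov) sigma2 * chol2inv(R) else NULL
  list(nll = nll, beta = beta, cov_beta = cov_beta, sigma2 = sigma2)
}

#' Wald confidence intervals for an `lmm_ml` fit
#'
#' Large-sample normal intervals and two-sided p-values for the fixed
#' effects.
#'
#' @param fit result of [lmm_ml()].
#' @param level confidence level.
#' @return data.frame (term, estimate, se, lower, upper, z, p).
#' @export
lmm_confint <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- fit$beta / fit$se
  data.frame(term = fit$coef_names %||% paste0("b", seq_along(fit$beta)),
             estimate = fit$beta, se = fit$se,
             lower = fit$beta - zq * fit$se,
             upper = fit$beta + zq * fit$se,
             z = z, p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}
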