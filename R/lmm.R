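# Per-subject sufficient statistics for the random-intercept/slope LMM on
# the internal time scale (days / 100, for conditioning).
lmm_suffstats <- function(long, tscale = 100) {
  t2 <- long$day / tscale
  ids <- unique(long$id)
  f <- factor(long$id, levels = ids)
  list(
    ids = ids,
    n  = as.numeric(tapply(long$value, f, length)),
    S1 = as.numeric(tapply(t2, f, sum)),
    S2 = as.numeric(tapply(t2^2, f, sum)),
    Zy1 = as.numeric(tapply(long$value, f, sum)),
    Zy2 = as.numeric(tapply(t2 * long$value, f, sum)),
    yy  = as.numeric(tapply(long$value^2, f, sum)),
    tscale = tscale)
}

# Profiled marginal -2-fold machinery: given internal-scale (D, sigma2),
# return GLS fixed effects, the quadratic form and the log-determinant sum.
lmm_profile <- function(ss, D, s2) {
  Di <- solve(D)
  P11 <- s2 * Di[1, 1] + ss$n
  P12 <- s2 * Di[1, 2] + ss$S1
  P22 <- s2 * Di[2, 2] + ss$S2
  detP <- P11 * P22 - P12^2
  logdet_term <- sum(log(detP)) - 2 * length(ss$n) * log(s2) +
    length(ss$n) * determinant(D)$modulus[1]
  # M = P^{-1}
  M11 <- P22 / detP; M12 <- -P12 / detP; M22 <- P11 / detP
  # GLS normal equations (X = Z here). The naive Woodbury form
  # Z'Z - Z'Z M Z'Z cancels catastrophically as s2 -> 0; use the exact
  # identity X'V^{-1}X = Dinv - s2 Dinv M Dinv and X'V^{-1}y = Dinv M Z'y,
  # stable in the noiseless limit.
  Di11 <- Di[1, 1]; Di12 <- Di[1, 2]; Di22 <- Di[2, 2]
  DM11 <- Di11^2 * M11 + 2 * Di11 * Di12 * M12 + Di12^2 * M22
  DM12 <- Di11 * Di12 * M11 + (Di11 * Di22 + Di12^2) * M12 +
    Di12 * Di22 * M22
  DM22 <- Di12^2 * M11 + 2 * Di12 * Di22 * M12 + Di22^2 * M22
  A11 <- sum(Di11 - s2 * DM11)
  A12 <- sum(Di12 - s2 * DM12)
  A22 <- sum(Di22 - s2 * DM22)
  c1 <- sum(Di11 * (M11 * ss$Zy1 + M12 * ss$Zy2) +
              Di12 * (M12 * ss$Zy1 + M22 * ss$Zy2))
  c2 <- sum(Di12 * (M11 * ss$Zy1 + M12 * ss$Zy2) +
              Di22 * (M12 * ss$Zy1 + M22 * ss$Zy2))
  A <- matrix(c(A11, A12, A12, A22), 2, 2)
  # slope may be unidentifiable (e.g. every visit at day 0): fix it at 0
  beta <- if (rcond(A) < 1e-12) c(c1 / A11, 0) else solve(A, c(c1, c2))
  Zr1 <- ss$Zy1 - ss$n * beta[1] - ss$S1 * beta[2]
  Zr2 <- ss$Zy2 - ss$S1 * beta[1] - ss$S2 * beta[2]
  rr <- ss$yy - 2 * (beta[1] * ss$Zy1 + beta[2] * ss$Zy2) +
    beta[1]^2 * ss$n + 2 * beta[1] * beta[2] * ss$S1 + beta[2]^2 * ss$S2
  quad <- sum(rr - (Zr1^2 * M11 + 2 * Zr1 * Zr2 * M12 + Zr2^2 * M22)) / s2
  N <- sum(ss$n)
  loglik <- -0.5 * (N * log(2 * pi * s2) + logdet_term + quad)
  list(beta = beta, loglik = loglik)
}

# theta = (l11, l21, l22, log sigma2); D = L L' with L lower triangular,
# diagonal on the log scale (log-Cholesky, PSD by construction).
theta_to_D <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  tcrossprod(L)
}

#' Fit the random-intercept/slope linear mixed model by maximum likelihood
#'
#' Fits `value ~ day` with correlated subject-level random intercept and
#' slope and i.i.d. Gaussian measurement error, by direct maximization of
#' the marginal Gaussian likelihood (ML, not REML). The fixed effects are
#' profiled out by generalized least squares; the covariance parameters are
#' optimized on a log-Cholesky scale, with time internally rescaled to
#' days/100 for conditioning. All reported values are on the day scale.
#'
#' @param long Long-format data frame with columns `id`, `day`, `value`.
#' @return An object of class `lmm_fit`: `beta` (intercept, slope per day),
#'   `D` (2x2 random-effects covariance, day scale), `sigma2`, `loglik`,
#'   `converged`, and internal pieces reused by the joint model.
#' @export
fit_lmm <- function(long) {
  stopifnot(all(c("id", "day", "value") %in% names(long)))
  ss <- lmm_suffstats(long)
  if (max(ss$n) < 2) {
    warning("no subject has two or more visits; ",
            "falling back to a random-intercept-only model")
    return(fit_lmm_intercept_only(long, ss))
  }
  v0 <- stats::var(long$value)
  # relative floor on the residual variance: keeps the profile algebra
  # well-conditioned on (near-)noiseless data
  s2_floor <- 1e-8 * max(v0, 1e-12)
  init <- c(0.5 * log(max(v0 / 2, 1e-2)), 0,
            0.5 * log(max(v0 / 50, 1e-4)), log(max(v0 / 2, 1e-2)))
  negll <- function(theta) {
    D <- theta_to_D(theta)
    s2 <- max(exp(theta[4]), s2_floor)
    out <- tryCatch(-lmm_profile(ss, D, s2)$loglik, error = function(e) NA)
    if (!is.finite(out)) 1e10 else out
  }
  opt <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  D_int <- theta_to_D(opt$par)
  s2 <- max(exp(opt$par[4]), s2_floor)
  prof <- lmm_profile(ss, D_int, s2)
  tsc <- ss$tscale
  D_day <- D_int * matrix(c(1, 1 / tsc, 1 / tsc, 1 / tsc^2), 2, 2)
  beta_day <- c(intercept = prof$beta[1], slope = prof$beta[2] / tsc)
  structure(
    list(beta = beta_day,
         D = D_day, sigma2 = s2, loglik = prof$loglik,
         converged = opt$convergence == 0,
         internal = list(theta = opt$par, beta_int = prof$beta,
                         D_int = D_int, tscale = tsc, suffstats = ss)),
    class = "lmm_fit")
}

fit_lmm_intercept_only <- function(long, ss) {
  negll <- function(par) {  # par = (log var_b0, log s2)
    D <- matrix(c(exp(par[1]), 0, 0, 1e-12), 2, 2)
    out <- tryCatch(-lmm_profile(ss, D, exp(par[2]))$loglik,
                    error = function(e) NA)
    if (!is.finite(out)) 1e10 else out
  }
  v0 <- stats::var(long$value)
  opt <- stats::optim(log(c(v0 / 2, v0 / 2)), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  D_int <- matrix(c(exp(opt$par[1]), 0, 0, 1e-12), 2, 2)
  s2 <- exp(opt$par[2])
  prof <- lmm_profile(ss, D_int, s2)
  tsc <- ss$tscale
  D_day <- D_int * matrix(c(1, 1 / tsc, 1 / tsc, 1 / tsc^2), 2, 2)
  structure(
    list(beta = c(intercept = prof$beta[1], slope = prof$beta[2] / tsc),
         D = D_day, sigma2 = s2, loglik = prof$loglik,
         converged = opt$convergence == 0,
         internal = list(theta = NULL, beta_int = prof$beta, D_int = D_int,
                         tscale = tsc, suffstats = ss)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM (ML): intercept %.4f, slope %.6f /day, sigma2 %.4f\n",
              x$beta[1], x$beta[2], x$sigma2))
  cat(sprintf("  D: Var(b0) %.4f, Var(b1) %.3g, Cov %.3g;  loglik %.3f\n",
              x$D[1, 1], x$D[2, 2], x$D[1, 2], x$loglik))
  invisible(x)
}

#' Empirical Bayes modes of the random effects
#'
#' Closed-form Gaussian posterior mode and conditional covariance of each
#' subject's `(b0, b1)` given that subject's longitudinal data under the
#' fitted LMM: precision `D^{-1} + Z'Z/sigma2`, mode
#' `Q^{-1} Z'(y - X beta)/sigma2`. Used to center and scale the
#' pseudo-adaptive quadrature of the joint model.
#'
#' @param fit An [fit_lmm()] result.
#' @param long The longitudinal data frame the modes are wanted for
#'   (defaults to the data the model was fitted to, via its sufficient
#'   statistics).
#' @return A list with `ids`, `modes` (n x 2, day scale) and `cov` (list of
#'   2x2 conditional covariances, day scale).
#' @export
eb_modes <- function(fit, long = NULL) {
  ss <- if (is.null(long)) fit$internal$suffstats else lmm_suffstats(long)
  tsc <- ss$tscale
  D <- fit$internal$D_int
  if (min(eigen(D, only.values = TRUE)$values) < 1e-10)
    D <- D + diag(1e-10, 2)
  Di <- solve(D)
  s2 <- fit$sigma2
  beta <- fit$internal$beta_int
  n <- length(ss$ids)
  modes <- matrix(0, n, 2)
  covs <- vector("list", n)
  scl <- matrix(c(1, 1 / tsc, 1 / tsc, 1 / tsc^2), 2, 2)
  for (i in seq_len(n)) {
    ZtZ <- matrix(c(ss$n[i], ss$S1[i], ss$S1[i], ss$S2[i]), 2, 2)
    Zr <- c(ss$Zy1[i] - ss$n[i] * beta[1] - ss$S1[i] * beta[2],
            ss$Zy2[i] - ss$S1[i] * beta[1] - ss$S2[i] * beta[2])
    Q <- Di + ZtZ / s2
    V <- solve(Q)
    m <- drop(V %*% Zr) / s2
    modes[i, ] <- m * c(1, 1 / tsc)
    covs[[i]] <- V * scl
  }
  list(ids = ss$ids, modes = modes, cov = covs)
}
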