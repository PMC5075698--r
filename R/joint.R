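#' Joint-model fitting specification
#'
#' Controls the baseline hazard family, quadrature and optimizer settings
#' for [fit_joint()].
#'
#' @param baseline `"weibull"` or `"piecewise"` (piecewise-constant with
#'   knots at equally spaced quantiles of the observed event times).
#' @param n_intervals Number of piecewise-constant intervals.
#' @param gh_points Gauss--Hermite nodes per random-effect dimension.
#' @param pseudo_adaptive Center and scale the quadrature grid at each
#'   subject's empirical Bayes mode/curvature from the separate LMM fit
#'   (recommended; fewer nodes suffice).
#' @param max_iter Optimizer iteration cap.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An object of class `joint_spec`.
#' @export
joint_spec <- function(baseline = c("weibull", "piecewise"),
                       n_intervals = 6L, gh_points = 9L,
                       pseudo_adaptive = TRUE, max_iter = 200L,
                       tol = 1e-8) {
  baseline <- match.arg(baseline)
  stopifnot(gh_points >= 3, n_intervals >= 1)
  structure(list(baseline = baseline, n_intervals = as.integer(n_intervals),
                 gh_points = as.integer(gh_points),
                 pseudo_adaptive = isTRUE(pseudo_adaptive),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "joint_spec")
}

# 15-panel fixed-order Gauss-Legendre rule on [0, 1]; scaled to [0, T] per
# subject when integrating the Weibull-baseline cumulative hazard. Panel
# boundaries are quadratically graded towards 0, where t^(shape-1) has a
# kink for non-integer shapes.
gl_unit_rule <- function(panels = 15L, order = 3L) {
  s <- numeric(0); w <- numeric(0)
  bounds <- (seq_len(panels + 1L) / (panels + 1L))^2
  bounds <- c(0, bounds[-1] / max(bounds))
  for (p in seq_len(panels)) {
    r <- pracma::gaussLegendre(order, bounds[p], bounds[p + 1])
    s <- c(s, r$x); w <- c(w, r$w)
  }
  list(s = s, w = w)
}

# Keep a quadrature-centering covariance usable as a grid scale: floor the
# variances at a small fraction of the marginal outcome variance (slope
# floor deflated by the squared day range) and cap |correlation| at 0.95.
# A rank-degenerate conditional covariance (possible when the initializing
# LMM hits the boundary on a small dataset) would otherwise collapse the
# two-dimensional grid onto a line.
center_regularize <- function(V, v0_floor, v1_floor) {
  v0 <- max(V[1, 1], v0_floor)
  v1 <- max(V[2, 2], v1_floor)
  r <- V[1, 2] / sqrt(V[1, 1] * V[2, 2])
  if (!is.finite(r)) r <- 0
  r <- max(min(r, 0.95), -0.95)
  matrix(c(v0, r * sqrt(v0 * v1), r * sqrt(v0 * v1), v1), 2, 2)
}

# Assemble everything the likelihood engine needs for one dataset: ordered
# survival rows, per-subject longitudinal sufficient statistics (day
# scale), the fixed pseudo-adaptive Gauss-Hermite grid and the
# Gauss-Legendre rule. The grid is centered/scaled once, from the separate
# LMM fit, and stays fixed during optimization.
prepare_joint_data <- function(survival, longitudinal, spec, lmm) {
  surv <- survival[order(survival$id), , drop = FALSE]
  long <- longitudinal
  ids <- surv$id
  n <- length(ids)
  f <- factor(long$id, levels = ids)
  ss <- list(
    n  = as.numeric(tapply(long$value, f, length)),
    S1 = as.numeric(tapply(long$day, f, sum)),
    S2 = as.numeric(tapply(long$day^2, f, sum)),
    Zy1 = as.numeric(tapply(long$value, f, sum)),
    Zy2 = as.numeric(tapply(long$day * long$value, f, sum)),
    yy  = as.numeric(tapply(long$value^2, f, sum)))
  for (k in seq_along(ss)) ss[[k]][is.na(ss[[k]])] <- 0

  gh <- pracma::gaussHermite(spec$gh_points)
  grid <- expand.grid(q1 = seq_len(spec$gh_points),
                      q2 = seq_len(spec$gh_points))
  z <- cbind(gh$x[grid$q1], gh$x[grid$q2])
  logw_node <- log(gh$w[grid$q1]) + log(gh$w[grid$q2]) + rowSums(z^2)
  G <- nrow(z)

  eb <- eb_modes(lmm)
  eb_idx <- match(ids, eb$ids)
  vy <- stats::var(long$value)
  drange <- max(diff(range(long$day)), 30)
  v0_floor <- 0.01 * vy
  v1_floor <- 0.01 * vy / drange^2
  b0g <- matrix(0, n, G); b1g <- matrix(0, n, G); logw <- matrix(0, n, G)
  for (i in seq_len(n)) {
    j <- eb_idx[i]
    if (spec$pseudo_adaptive && !is.na(j)) {
      mode <- eb$modes[j, ]; V <- eb$cov[[j]]
    } else {
      mode <- c(0, 0); V <- lmm$D
    }
    L <- t(chol(center_regularize(V, v0_floor, v1_floor)))
    b <- sweep(sqrt(2) * z %*% t(L), 2, mode, `+`)
    b0g[i, ] <- b[, 1]; b1g[i, ] <- b[, 2]
    logw[i, ] <- log(2) + sum(log(diag(L))) + logw_node
  }

  gl <- gl_unit_rule()
  sgl <- outer(surv$time, gl$s)
  wgl <- outer(surv$time, gl$w)

  knots <- numeric(0)
  if (spec$baseline == "piecewise") {
    et <- surv$time[surv$status == 1]
    if (length(et) < spec$n_intervals)
      stop("too few events for the requested piecewise intervals")
    knots <- as.numeric(stats::quantile(
      et, probs = seq_len(spec$n_intervals - 1) / spec$n_intervals))
  }
  list(surv = surv, ss = ss, b0g = b0g, b1g = b1g, logw = logw,
       sgl = sgl, wgl = wgl, knots = knots, n = n)
}

# Optimizer parameter vector <-> concrete day-scale parameters. Internally
# the slope-type components run on a days/100 scale for conditioning:
# par = (beta0, 100*beta1, log sigma2, log-Cholesky of the internal-scale D,
#        alpha, gamma, baseline parameters).
par_to_params <- function(par, spec, knots) {
  D_int <- theta_to_D(par[4:6])
  tsc <- 100
  D <- D_int * matrix(c(1, 1 / tsc, 1 / tsc, 1 / tsc^2), 2, 2)
  bl <- par[-(1:8)]
  baseline <- if (spec$baseline == "weibull") {
    list(type = "weibull", log_scale = bl[1], log_shape = bl[2])
  } else {
    list(type = "piecewise", log_hazard = bl, knots = knots)
  }
  list(beta = c(par[1], par[2] / tsc), sigma2 = exp(par[3]), D = D,
       alpha = par[7], gamma = par[8], baseline = baseline)
}

params_baseline_vec <- function(params) {
  if (params$baseline$type == "weibull")
    c(params$baseline$log_scale, params$baseline$log_shape)
  else params$baseline$log_hazard
}

# Per-subject marginal log-likelihoods through the compiled engine.
joint_logliks <- function(params, jd) {
  bl_type <- if (params$baseline$type == "weibull") 0L else 1L
  joint_subject_logliks_cpp(
    params$beta[1], params$beta[2], params$sigma2, params$D,
    params$alpha, params$gamma, bl_type, params_baseline_vec(params),
    if (bl_type == 1L) params$baseline$knots else numeric(0),
    jd$surv$time, as.integer(jd$surv$status), jd$surv$group,
    jd$ss$n, jd$ss$S1, jd$ss$S2, jd$ss$Zy1, jd$ss$Zy2, jd$ss$yy,
    jd$b0g, jd$b1g, jd$logw, jd$sgl, jd$wgl)
}

#' Conditional survival log-likelihood given the random effects
#'
#' `delta * log h(T | b) - integral_0^T h(s | b) ds` for one subject, with
#' `h(t | b) = h0(t) exp(gamma u + alpha m(t | b))` and
#' `m(t | b) = beta0 + beta1 t + b0 + b1 t`. Under the piecewise-constant
#' baseline the cumulative hazard is evaluated in closed form on each
#' interval (the integral of `c e^{d s}`, with the `d -> 0` limit handled
#' analytically); under the Weibull baseline by fixed-order Gauss--Legendre
#' on 15 subintervals of `[0, T]`.
#'
#' @param params Joint-model parameter list: `beta` (length 2), `alpha`,
#'   `gamma`, and `baseline` (either `type = "weibull"` with `log_scale`,
#'   `log_shape`, or `type = "piecewise"` with `log_hazard`, `knots`).
#' @param time,status Recorded time and event indicator.
#' @param group Group indicator (0/1).
#' @param b Numeric length-2 vector `(b0, b1)`.
#' @return The conditional survival log-likelihood (scalar).
#' @export
conditional_survival_loglik <- function(params, time, status, group, b) {
  if (time <= 0) return(0)
  m0 <- params$beta[1] + b[1]
  m1 <- params$beta[2] + b[2]
  am1 <- params$alpha * m1
  lin <- params$gamma * group + params$alpha * m0
  bl <- params$baseline
  if (bl$type == "weibull") {
    shape <- exp(bl$log_shape)
    gl <- gl_unit_rule()
    s <- time * gl$s; w <- time * gl$w
    cumh <- exp(lin) * sum(w * exp(bl$log_scale) * shape * s^(shape - 1) *
                             exp(am1 * s))
    lh <- bl$log_scale + log(shape) + (shape - 1) * log(time) +
      lin + am1 * time
  } else {
    cuts <- c(0, bl$knots, Inf)
    cumh <- 0
    for (j in seq_along(bl$log_hazard)) {
      s1 <- min(cuts[j], time); s2 <- min(cuts[j + 1], time)
      if (s2 > s1) {
        seg <- if (abs(am1) < 1e-12) s2 - s1 else
          (exp(am1 * s2) - exp(am1 * s1)) / am1
        cumh <- cumh + exp(bl$log_hazard[j]) * seg
      }
    }
    cumh <- exp(lin) * cumh
    jT <- findInterval(time, c(0, bl$knots), rightmost.closed = FALSE)
    lh <- bl$log_hazard[jT] + lin + am1 * time
  }
  if (!is.finite(cumh)) cumh <- 1e300
  status * lh - cumh
}

# Conditional longitudinal log-likelihood for one subject given b.
conditional_long_loglik <- function(params, day, value, b) {
  if (length(day) == 0) return(0)
  mu <- params$beta[1] + b[1] + (params$beta[2] + b[2]) * day
  sum(stats::dnorm(value, mu, sqrt(params$sigma2), log = TRUE))
}

#' Marginal log-likelihood of one subject
#'
#' Integrates `exp(loglik_surv(b) + loglik_long(b))` against the N(0, D)
#' random-effects density on a two-dimensional Gauss--Hermite grid,
#' optionally shifted/scaled to a supplied posterior mode and covariance
#' (pseudo-adaptive rule). Log-sum-exp is used throughout.
#'
#' @inheritParams conditional_survival_loglik
#' @param day,value The subject's longitudinal record (possibly empty).
#' @param gh_points Nodes per dimension.
#' @param center Optional list with `mode` (length 2) and `cov` (2x2) for
#'   pseudo-adaptive centering; defaults to standard quadrature scaled by
#'   the prior covariance `params$D`.
#' @return The marginal log-likelihood (scalar).
#' @export
subject_marginal_loglik <- function(params, time, status, group, day, value,
                                    gh_points = 9L, center = NULL) {
  gh <- pracma::gaussHermite(gh_points)
  grid <- expand.grid(q1 = seq_len(gh_points), q2 = seq_len(gh_points))
  z <- cbind(gh$x[grid$q1], gh$x[grid$q2])
  logw <- log(gh$w[grid$q1]) + log(gh$w[grid$q2]) + rowSums(z^2)
  if (is.null(center)) center <- list(mode = c(0, 0), cov = params$D)
  L <- t(chol(center$cov))
  b <- sweep(sqrt(2) * z %*% t(L), 2, center$mode, `+`)
  Di <- solve(params$D)
  ldetD <- determinant(params$D)$modulus[1]
  ll <- vapply(seq_len(nrow(b)), function(q) {
    bq <- b[q, ]
    conditional_survival_loglik(params, time, status, group, bq) +
      conditional_long_loglik(params, day, value, bq) -
      log(2 * pi) - 0.5 * ldetD - 0.5 * drop(bq %*% Di %*% bq)
  }, numeric(1))
  tot <- ll + logw + log(2) + sum(log(diag(L)))
  m <- max(tot)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(tot - m)))
}

#' Fit the shared random-effects joint model by maximum likelihood
#'
#' Direct quasi-Newton maximization of the Gauss--Hermite-approximated
#' marginal likelihood of the joint model: a linear mixed-effects
#' trajectory submodel (random intercept and slope) linked to a
#' proportional-hazards survival submodel through the current latent value
#' `m_i(t)`, with a Weibull or piecewise-constant baseline hazard.
#' Initialization comes from the separate LMM fit (trajectory parameters,
#' and the empirical Bayes modes that center the pseudo-adaptive
#' quadrature) and a LOCF Cox fit (group coefficient), with the
#' association started at zero. Standard errors for the association and
#' group coefficients come from the inverse of a central-difference
#' observed-information matrix at the optimum.
#'
#' @param dataset A [simulate_dataset()] result, or any list with
#'   `survival` (`id`, `group`, `time`, `status`) and `longitudinal`
#'   (`id`, `day`, `value`) components.
#' @param spec A [joint_spec()].
#' @return An object of class `joint_fit`: `alpha`, `gamma`, `se`
#'   (for alpha and gamma), `ci` (Wald 95%), `beta`, `D`, `sigma2`,
#'   `baseline`, `loglik`, `converged`, `n_events`, `spec`.
#' @export
fit_joint <- function(dataset, spec = joint_spec()) {
  surv <- dataset$survival
  long <- dataset$longitudinal
  if (sum(surv$status) < 1) stop("at least one event is required")
  lmm <- fit_lmm(long)
  jd <- prepare_joint_data(surv, long, spec, lmm)

  gamma0 <- tryCatch({
    cf <- fit_cox(build_locf_table(dataset))
    g <- unname(cf$coef["group"])
    if (is.finite(g)) g else 0
  }, error = function(e) 0)

  D_int <- lmm$internal$D_int + diag(1e-8, 2)
  C <- t(chol(D_int))
  exposure <- sum(surv$time)
  nev <- sum(surv$status)
  lw0 <- log(nev / exposure) - gamma0 * mean(surv$group)
  bl0 <- if (spec$baseline == "weibull") c(lw0, 0) else
    rep(lw0, spec$n_intervals)
  par <- unname(c(lmm$beta[1], lmm$beta[2] * 100, log(lmm$sigma2),
                  log(C[1, 1]), C[2, 1], log(C[2, 2]), 0, gamma0, bl0))

  negll <- function(p) {
    params <- par_to_params(p, spec, jd$knots)
    v <- tryCatch(-sum(joint_logliks(params, jd)), error = function(e) NA)
    if (!is.finite(v)) 1e10 else v
  }
  ps <- c(1, 1, 0.5, 0.5, 0.5, 0.5, 0.02, 0.5, rep(0.5, length(bl0)))
  opt <- stats::optim(par, negll, method = "BFGS",
                      control = list(maxit = spec$max_iter,
                                     reltol = spec$tol, parscale = ps))
  params <- par_to_params(opt$par, spec, jd$knots)
  H <- central_diff_hessian(negll, opt$par, h = 1e-4 * pmax(1, abs(opt$par)))
  vc <- tryCatch(solve(H), error = function(e) matrix(NA, length(par),
                                                      length(par)))
  se_ag <- suppressWarnings(sqrt(c(alpha = vc[7, 7], gamma = vc[8, 8])))
  converged <- opt$convergence == 0 && all(is.finite(se_ag)) &&
    all(se_ag > 0)
  est <- c(alpha = params$alpha, gamma = params$gamma)
  ci <- cbind(lower = est - 1.96 * se_ag, upper = est + 1.96 * se_ag)
  structure(
    list(alpha = params$alpha, gamma = params$gamma, se = se_ag, ci = ci,
         beta = c(intercept = params$beta[1], slope = params$beta[2]),
         D = params$D, sigma2 = params$sigma2, baseline = params$baseline,
         loglik = -opt$value, converged = converged, n_events = nev,
         spec = spec, lmm = lmm, par = opt$par, knots = jd$knots),
    class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint model (%s baseline, %s)\n", x$baseline$type,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  alpha %.5f (se %.5f), gamma %.4f (se %.4f)\n",
              x$alpha, x$se["alpha"], x$gamma, x$se["gamma"]))
  cat(sprintf("  beta (%.3f, %.5f), sigma2 %.3f, loglik %.3f\n",
              x$beta[1], x$beta[2], x$sigma2, x$loglik))
  invisible(x)
}

# Central-difference observed-information matrix of a scalar function.
central_diff_hessian <- function(f, x, h) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (j in seq_len(p)) {
    ej <- rep(0, p); ej[j] <- h[j]
    H[j, j] <- (f(x + ej) - 2 * f0 + f(x - ej)) / h[j]^2
    if (j < p) for (k in (j + 1):p) {
      ek <- rep(0, p); ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) +
           f(x - ej - ek)) / (4 * h[j] * h[k])
    }
  }
  H
}
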