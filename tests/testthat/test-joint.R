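# Shared small fixture: monotone set-1 conditions at reduced n, plus its
# LMM fit and a parameter list consistent with that fit.
joint_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- fixture_scenario("set1", n_per_group = 75)
      ds <- simulate_dataset(sc, 1)
      lmm <- fit_lmm(ds$longitudinal)
      C <- t(chol(lmm$internal$D_int))
      base_par <- c(lmm$beta[1], lmm$beta[2] * 100, log(lmm$sigma2),
                    log(C[1, 1]), C[2, 1], log(C[2, 2]))
      cache <<- list(sc = sc, ds = ds, lmm = lmm, base_par = base_par)
    }
    cache
  }
})

test_that("conditional survival loglik collapses to the exponential", {
  params <- list(beta = c(40, 0.02), alpha = 0, gamma = 0.3,
                 baseline = list(type = "weibull", log_scale = log(0.01),
                                 log_shape = 0))
  for (st in 0:1) {
    ll <- conditional_survival_loglik(params, 120, st, 1, c(1.5, -0.01))
    rate <- 0.01 * exp(0.3)
    expect_equal(ll, st * log(rate) - rate * 120, tolerance = 1e-10)
  }
})

test_that("piecewise cumulative hazard matches adaptive integration", {
  params <- list(beta = c(40, 0.02), alpha = -0.03, gamma = -0.2,
                 baseline = list(type = "piecewise",
                                 log_hazard = -4.5, knots = numeric(0)))
  b <- c(2, 0.015)
  hfun <- function(s)
    exp(-4.5) * exp(params$gamma * 1 + params$alpha *
                      (40 + 2 + (0.02 + 0.015) * s))
  H <- integrate(hfun, 0, 200, rel.tol = 1e-12)$value
  ll <- conditional_survival_loglik(params, 200, 1, 1, b)
  expect_equal(ll, log(hfun(200)) - H, tolerance = 1e-8)

  # multi-interval baseline, zero-slope (d -> 0) branch included
  params$baseline <- list(type = "piecewise",
                          log_hazard = c(-5, -4.2, -4.8),
                          knots = c(60, 150))
  params$alpha <- 0.02
  b0 <- c(-1, -0.02)  # alpha * m1 == 0 exactly
  hfun2 <- function(s) {
    lev <- ifelse(s <= 60, -5, ifelse(s <= 150, -4.2, -4.8))
    exp(lev) * exp(params$alpha * (40 - 1 + (0.02 - 0.02) * s))
  }
  H2 <- sum(sapply(list(c(0, 60), c(60, 150), c(150, 210)), function(iv)
    integrate(hfun2, iv[1], iv[2], rel.tol = 1e-12)$value))
  ll2 <- conditional_survival_loglik(params, 210, 0, 0, b0)
  expect_equal(ll2, -H2, tolerance = 1e-8)
})

test_that("weibull cumulative hazard matches adaptive integration", {
  params <- list(beta = c(40, 0.02), alpha = -0.03, gamma = 0,
                 baseline = list(type = "weibull", log_scale = -5,
                                 log_shape = log(1.4)))
  b <- c(3, 0.01)
  hfun <- function(s) exp(-5) * 1.4 * s^0.4 *
    exp(params$alpha * (43 + 0.03 * s))
  H <- integrate(hfun, 0, 180, rel.tol = 1e-12)$value
  ll <- conditional_survival_loglik(params, 180, 1, 0, b)
  # fixed-order panel rule: ~1e-5 relative against adaptive integration
  expect_equal(ll, log(hfun(180)) - H, tolerance = 1e-4)
})

test_that("the survival integrand is consistent with the simulator", {
  # flat baseline equal to the generator's exp(lambda0): the continuous
  # cumulative hazard matches the daily sum within discretization error
  sc <- sim_scenario()  # a0 = 40, a1 = 0.02, lambda1 = -0.03
  params <- list(beta = c(40, 0.02), alpha = -0.03, gamma = 0,
                 baseline = list(type = "piecewise", log_hazard = -4.8,
                                 knots = numeric(0)))
  ll <- conditional_survival_loglik(params, 120, 0, 0, c(0, 0))
  daily <- -sum(daily_hazard(sc, 0, 0, 0, 0:119))
  expect_equal(ll, daily, tolerance = 0.01)
})

test_that("the compiled engine agrees with the reference marginal", {
  fx <- joint_fixture()
  spec <- joint_spec("weibull", gh_points = 9)
  jd <- jmbench:::prepare_joint_data(fx$ds$survival, fx$ds$longitudinal,
                                     spec, fx$lmm)
  params <- jmbench:::par_to_params(c(fx$base_par, -0.03, 0.1, -6, 0.02),
                                    spec, jd$knots)
  ll_cpp <- jmbench:::joint_logliks(params, jd)
  eb <- eb_modes(fx$lmm)
  set.seed(14)
  idx <- sample(seq_len(nrow(fx$ds$survival)), 12)
  for (i in idx) {
    s <- fx$ds$survival[i, ]
    l <- fx$ds$longitudinal[fx$ds$longitudinal$id == s$id, ]
    V <- jmbench:::center_regularize(
      eb$cov[[i]], 0.01 * var(fx$ds$longitudinal$value),
      0.01 * var(fx$ds$longitudinal$value) /
        max(diff(range(fx$ds$longitudinal$day)), 30)^2)
    ll_r <- subject_marginal_loglik(
      params, s$time, s$status, s$group, l$day, l$value, gh_points = 9,
      center = list(mode = eb$modes[i, ], cov = V))
    expect_equal(ll_cpp[i], ll_r, tolerance = 1e-8)
  }
})

test_that("the likelihood factorizes exactly at alpha = 0", {
  fx <- joint_fixture()
  spec <- joint_spec("piecewise")
  jd <- jmbench:::prepare_joint_data(fx$ds$survival, fx$ds$longitudinal,
                                     spec, fx$lmm)
  ph <- c(-6.2, -6, -5.9, -6.1, -5.8, -6)
  params <- jmbench:::par_to_params(c(fx$base_par, 0, 0.1, ph), spec,
                                    jd$knots)
  tot <- sum(jmbench:::joint_logliks(params, jd))
  s <- jd$surv
  cuts <- c(0, jd$knots, Inf)
  H0 <- vapply(s$time, function(Ti) {
    h <- 0
    for (j in seq_along(ph)) {
      s1 <- min(cuts[j], Ti); s2 <- min(cuts[j + 1], Ti)
      if (s2 > s1) h <- h + exp(ph[j]) * (s2 - s1)
    }
    h
  }, numeric(1))
  jT <- findInterval(s$time, c(0, jd$knots))
  surv_ll <- sum(s$status * (ph[jT] + params$gamma * s$group) -
                   exp(params$gamma * s$group) * H0)
  expect_equal(tot, fx$lmm$loglik + surv_ll, tolerance = 1e-6)
})

test_that("the quadrature is converged at the default node count", {
  fx <- joint_fixture()
  for (bl in c("weibull", "piecewise")) {
    extra <- if (bl == "weibull") c(-6, 0.02) else
      c(-6.1, -6, -5.9, -6, -5.8, -6)
    ll <- vapply(c(9, 15), function(g) {
      spec <- joint_spec(bl, gh_points = g)
      jd <- jmbench:::prepare_joint_data(fx$ds$survival,
                                         fx$ds$longitudinal, spec, fx$lmm)
      params <- jmbench:::par_to_params(c(fx$base_par, -0.03, 0.1, extra),
                                        spec, jd$knots)
      sum(jmbench:::joint_logliks(params, jd))
    }, numeric(1))
    expect_lt(abs(ll[1] - ll[2]), 1e-3)
  }
})

test_that("the marginal loglik is invariant to subject relabeling", {
  fx <- joint_fixture()
  spec <- joint_spec("weibull")
  jd <- jmbench:::prepare_joint_data(fx$ds$survival, fx$ds$longitudinal,
                                     spec, fx$lmm)
  params <- jmbench:::par_to_params(c(fx$base_par, -0.03, 0.1, -6, 0.02),
                                    spec, jd$knots)
  tot1 <- sum(jmbench:::joint_logliks(params, jd))
  set.seed(8)
  n <- nrow(fx$ds$survival)
  relab <- sample(n)
  surv2 <- fx$ds$survival
  surv2$id <- relab[surv2$id]
  long2 <- fx$ds$longitudinal
  long2$id <- relab[long2$id]
  long2 <- long2[sample(nrow(long2)), ]
  lmm2 <- fit_lmm(long2)
  jd2 <- jmbench:::prepare_joint_data(surv2, long2, spec, lmm2)
  tot2 <- sum(jmbench:::joint_logliks(params, jd2))
  expect_equal(tot1, tot2, tolerance = 1e-8)
})

test_that("a prior-integrated subject matches Monte-Carlo integration", {
  params <- list(beta = c(40, 0.02), sigma2 = 16,
                 D = matrix(c(32, 0.06, 0.06, 0.002), 2, 2),
                 alpha = -0.03, gamma = 0.2,
                 baseline = list(type = "piecewise", log_hazard = -5.5,
                                 knots = numeric(0)))
  ll <- subject_marginal_loglik(params, 150, 1, 1, numeric(0), numeric(0),
                                gh_points = 15)
  set.seed(55)
  N <- 4e5
  B <- matrix(rnorm(2 * N), ncol = 2) %*% chol(params$D)
  m0 <- 40 + B[, 1]; m1 <- 0.02 + B[, 2]
  am1 <- params$alpha * m1
  lin <- params$gamma + params$alpha * m0
  H <- exp(-5.5) * exp(lin) * (exp(am1 * 150) - 1) / am1
  lw <- (-5.5 + lin + am1 * 150) - H
  mm <- max(lw)
  mc <- mm + log(mean(exp(lw - mm)))
  expect_equal(ll, mc, tolerance = 0.01)
})

test_that("data generated without association give a null alpha", {
  sc <- sim_scenario(lambda1 = 0, lambda0 = -5.9, cov = "a",
                     n_per_group = 150, seed = 17, set_id = 99L)
  ds <- simulate_dataset(sc, 1)
  fit <- fit_joint(ds, joint_spec("piecewise"))
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha) / fit$se["alpha"], 3)
  # trajectory side decouples to the LMM-only estimates
  lmm <- fit_lmm(ds$longitudinal)
  expect_equal(unname(fit$beta), unname(lmm$beta), tolerance = 0.01)
  expect_equal(fit$sigma2, lmm$sigma2, tolerance = 0.05)
})
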