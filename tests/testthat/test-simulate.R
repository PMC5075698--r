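test_that("latent trajectory evaluates the linear mixed form", {
  sc <- sim_scenario(a0 = 40, a1 = 0.02)
  expect_equal(true_trajectory(sc, 0, 0, 0), 40)
  sc2 <- sim_scenario(a0 = 40, a1 = 0.1)
  expect_equal(true_trajectory(sc2, 0, 0, 100), 50)
  expect_equal(true_trajectory(sc, -2, 0.01, 50), 39.5)
  expect_error(true_trajectory(sc, 0, 0, 400), "horizon")
  expect_error(true_trajectory(sc, 0, 0, -1), "horizon")
})

test_that("random effects reproduce the target covariance structure", {
  # 1e5 draws: correlation MC SE ~ 0.003, allow ~4 SEs (absolute)
  set.seed(101)
  b <- draw_random_effects(re_cov_form("a"), 1e5)
  expect_lt(abs(cor(b[, 1], b[, 2]) - 0.237), 0.013)
  expect_lt(abs(mean(b[, 1])), 0.1)
  expect_lt(abs(var(b[, 1]) - 32), 0.7)
  expect_lt(abs(var(b[, 2]) - 0.002), 5e-5)
  b <- draw_random_effects(re_cov_form("d"), 1e5)
  expect_lt(abs(cor(b[, 1], b[, 2]) - 0.032), 0.013)
  b <- draw_random_effects(re_cov(4, 0.001, 0), 1e5)
  expect_lt(abs(cor(b[, 1], b[, 2])), 0.013)
})

test_that("daily hazard is log-linear in the latent value and group", {
  sc <- sim_scenario(a0 = 40, a1 = 0, lambda0 = -4.8, lambda1 = -0.03,
                     tau = 0)
  expect_equal(daily_hazard(sc, 0, 0, 0, 10), exp(-6))
  sc$tau <- -0.5
  expect_equal(daily_hazard(sc, 0, 0, 1, 10), exp(-6.5))
  # lambda1 = 0: constant over time and subjects
  sc0 <- sim_scenario(lambda1 = 0, tau = 0, a1 = 0.1)
  h <- daily_hazard(sc0, 1.3, -0.02, 0, c(0, 100, 300))
  expect_equal(h, rep(exp(-4.8), 3))
  expect_true(all(h > 0))
})

test_that("degenerate event times collapse to the exponential law", {
  # no random effects, flat trajectory: rate = exp(lambda0 + lambda1 a0)
  rate <- 0.02
  sc <- sim_scenario(a0 = 40, a1 = 0, cov = re_cov(1e-12, 1e-12, 0),
                     lambda0 = log(rate) + 0.03 * 40, lambda1 = -0.03)
  set.seed(7)
  tt <- sim_event_times_fixture(sc, 1e4)
  expect_lt(mean(is.na(tt)), 0.002)
  obs <- tt[!is.na(tt)]
  expect_equal(mean(obs), 1 / rate, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(obs, stats::pexp, rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("marginal survival matches the cumulative-hazard oracle", {
  sc <- fixture_scenario("set1")
  set.seed(21)
  n <- 2e4
  b <- draw_random_effects(sc$cov, n)
  tt <- draw_event_time(sc, b[, 1], b[, 2], rep(0, n))
  # independent oracle: S(k) = E over fresh (b0, b1) of exp(-sum_{t<k} h)
  b2 <- draw_random_effects(sc$cov, n)
  for (k in c(30, 120, 364)) {
    S_emp <- mean(is.na(tt) | tt >= k)
    h <- vapply(seq_len(n), function(i)
      sum(daily_hazard(sc, b2[i, 1], b2[i, 2], 0, 0:(k - 1))), numeric(1))
    S_or <- mean(exp(-h))
    se <- sqrt(S_or * (1 - S_or) / n + var(exp(-h)) / n)
    expect_lt(abs(S_emp - S_or), 3 * se + 1e-12)
  }
})

test_that("monotone censoring is continuous Uniform(1, 364)", {
  set.seed(5)
  cc <- draw_censoring_monotone(1e5)
  expect_true(all(cc >= 1 & cc <= 364))
  expect_equal(mean(cc), 182.5, tolerance = 1.5)
  expect_equal(mean(cc <= 182.5), 0.5, tolerance = 0.01)
})

test_that("monotone observation keeps the 30-day grid below the time", {
  sc <- fixture_scenario("set1")
  set.seed(2)
  v <- observe_monotone(sc, 1, 0.01, 95)
  expect_equal(v$day, c(0, 30, 60, 90))
  v <- observe_monotone(sc, 1, 0.01, 15)
  expect_equal(v$day, 0)
  sc0 <- sc; sc0$error_var <- 0
  v <- observe_monotone(sc0, -2, 0.01, 100)
  expect_equal(v$value, true_trajectory(sc0, -2, 0.01, v$day))
})

test_that("non-monotone observation respects windows and missingness", {
  sc <- fixture_scenario("set23")
  set.seed(31)
  saw_empty <- FALSE
  for (r in 1:300) {
    ev <- if (r %% 3 == 0) NA else runif(1, 5, 400)
    obs <- observe_nonmonotone(sc, 0.5, 0.001, ev)
    d <- obs$visits$day
    expect_equal(d[1], 0)
    expect_true(all(diff(d) > 0))
    post <- d[-1]
    if (length(post)) {
      # each jittered day sits within +/-7 of its nominal 30-day occasion
      nearest <- 30 * round(post / 30)
      expect_true(all(abs(post - nearest) <= 7))
    }
    if (obs$status == 1) {
      expect_true(all(d < obs$time))
      expect_equal(obs$time, ev)
    } else {
      expect_equal(obs$time, max(d))
      if (obs$time == 0) saw_empty <- TRUE
    }
  }
  expect_true(saw_empty)  # the all-missing pattern occurs and censors at 0
})

test_that("dataset simulation is reproducible and balanced", {
  sc <- fixture_scenario("set1", n_per_group = 60)
  d1 <- simulate_dataset(sc, 4)
  d2 <- simulate_dataset(sc, 4)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(sc, 5)
  expect_false(identical(d1$survival$time, d3$survival$time))
  expect_equal(table(d1$survival$group), table(c(rep(0, 60), rep(1, 60))),
               ignore_attr = TRUE)
  expect_true(all(d1$survival$status %in% 0:1))
  # every subject has a day-0 visit; visits stop before events
  base <- d1$longitudinal[d1$longitudinal$day == 0, ]
  expect_setequal(base$id, d1$survival$id)
  ev <- d1$survival[d1$survival$status == 1, ]
  for (i in seq_len(nrow(ev))) {
    vd <- d1$longitudinal$day[d1$longitudinal$id == ev$id[i]]
    expect_true(all(vd < ev$time[i]))
  }
})

test_that("a negative group effect lowers the group-2 event fraction", {
  sc <- fixture_scenario("set33", n_per_group = 3000)
  ds <- simulate_dataset(sc, 1)
  f <- tapply(ds$survival$status, ds$survival$group, mean)
  expect_gt(f[["0"]], f[["1"]])
})

test_that("event counts are stable and non-degenerate across replicates", {
  sc <- fixture_scenario("set1", n_per_group = 50)
  ev <- vapply(1:20, function(r)
    sum(simulate_dataset(sc, r)$survival$status), numeric(1))
  expect_true(all(ev > 0 & ev < 100))
  expect_gt(var(ev), 0)
})
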