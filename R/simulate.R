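#' Latent trajectory value
#'
#' Evaluates the subject's true (error-free) predictor value
#' `a0 + a1 t + b0 + b1 t` at day `t`.
#'
#' @param scenario A [sim_scenario()].
#' @param b0,b1 Realized random intercept and slope.
#' @param t Day, in `[0, horizon_days - 1]`; vectorized.
#' @return Numeric vector of trajectory values.
#' @export
true_trajectory <- function(scenario, b0, b1, t) {
  if (any(t < 0 | t > scenario$horizon_days - 1))
    stop("t outside the follow-up horizon")
  traj_value(scenario, b0, b1, t)
}

# Unchecked linear evaluation; jittered assessment windows may fall a few
# days past the hazard horizon (nominal day 360 + 7) and still carry an
# observation of the linear trajectory.
traj_value <- function(scenario, b0, b1, t) {
  scenario$a0 + scenario$a1 * t + b0 + b1 * t
}

#' Draw random effects
#'
#' Samples `n` (b0, b1) pairs from the bivariate normal with mean zero and
#' the scenario's covariance matrix, using the current RNG stream.
#'
#' @param cov A [re_cov()] object.
#' @param n Number of subjects.
#' @return An `n x 2` matrix with columns `b0`, `b1`.
#' @export
draw_random_effects <- function(cov, n) {
  stopifnot(inherits(cov, "re_cov"), n >= 1)
  L <- chol(as.matrix(cov))  # upper triangular, D = L'L
  z <- matrix(stats::rnorm(2 * n), n, 2)
  b <- z %*% L
  colnames(b) <- c("b0", "b1")
  b
}

#' Daily hazard
#'
#' The hazard for day `t` is `exp(lambda0 + lambda1 m(t) + tau u)` where
#' `m(t)` is the latent trajectory value; it is held constant over the day.
#'
#' @inheritParams true_trajectory
#' @param group Group indicator, 0 or 1.
#' @return Hazard rate per day (strictly positive); vectorized over `t`.
#' @export
daily_hazard <- function(scenario, b0, b1, group, t) {
  stopifnot(all(group %in% c(0, 1)))
  exp(scenario$lambda0 +
        scenario$lambda1 * true_trajectory(scenario, b0, b1, t) +
        scenario$tau * group)
}

# Vectorized piecewise-exponential event times for n subjects. The hazard is
# constant within each day t in {0,...,364} at exp(c_i + d_i t) with
# c_i = lambda0 + tau u_i + lambda1 (a0 + b0i), d_i = lambda1 (a1 + b1i).
# A unit-rate exponential E is inverted against the cumulative daily hazard:
# the event falls in the first day whose cumulative hazard reaches E, with a
# linear residual inside the day. Survival to day k is exactly
# exp(-sum_{t<k} h(t)); NA means no event within the horizon.
sim_event_times <- function(scenario, b0, b1, group) {
  n <- length(b0)
  ndays <- scenario$horizon_days
  cc <- scenario$lambda0 + scenario$tau * group +
    scenario$lambda1 * (scenario$a0 + b0)
  dd <- scenario$lambda1 * (scenario$a1 + b1)
  h <- exp(matrix(cc, n, ndays) + tcrossprod(dd, 0:(ndays - 1)))
  cumh <- h
  for (j in 2:ndays) cumh[, j] <- cumh[, j - 1] + h[, j]
  E <- stats::rexp(n)
  k <- rowSums(cumh < E)          # full days survived
  out <- rep(NA_real_, n)
  hit <- k < ndays
  if (any(hit)) {
    prior <- ifelse(k[hit] > 0, cumh[cbind(which(hit), pmax(k[hit], 1))], 0)
    out[hit] <- k[hit] + (E[hit] - prior) / h[cbind(which(hit), k[hit] + 1)]
  }
  out
}

#' Draw one event time
#'
#' Piecewise-exponential draw with the hazard held constant within each day:
#' marginally, survival to day `k` equals `exp(-sum_{t<k} h(t))`, and the
#' event time is continuous within the triggering day.
#'
#' @inheritParams daily_hazard
#' @return Event time in days, or `NA` if no event occurs by the end of the
#'   horizon.
#' @export
draw_event_time <- function(scenario, b0, b1, group) {
  sim_event_times(scenario, b0, b1, group)
}

#' Draw monotone-regime censoring times
#'
#' @param n Number of draws.
#' @return `n` draws from the continuous Uniform(1, 364).
#' @export
draw_censoring_monotone <- function(n = 1) {
  stats::runif(n, 1, 364)
}

#' Observe a subject under the monotone visit schedule
#'
#' Visits fall on days 0, 30, 60, ... strictly before the recorded
#' event/censoring time; each observed value is the true trajectory plus
#' Gaussian measurement error. Post-event and post-censoring occasions are
#' discarded.
#'
#' @inheritParams true_trajectory
#' @param time Recorded event or censoring time (days).
#' @return A data frame with columns `day`, `value`.
#' @export
observe_monotone <- function(scenario, b0, b1, time) {
  days <- seq(0L, scenario$horizon_days - 1L, by = scenario$visit_interval)
  days <- days[days < time]
  value <- true_trajectory(scenario, b0, b1, days) +
    stats::rnorm(length(days), 0, sqrt(scenario$error_var))
  data.frame(day = days, value = value)
}

#' Observe a subject under the non-monotone visit schedule
#'
#' Baseline is always assessed at day 0. The 12 nominal post-baseline
#' occasions (days 30, 60, ..., 360) are each jittered by an integer drawn
#' uniformly from -7..7 (a +/-7-day assessment window), and a uniformly
#' random subset of the 12 occasions, of uniformly random size 0--12, is
#' set missing. The censoring time is the day of the last non-missing
#' assessment unless the generated event time is earlier; visits on or
#' after an event are dropped.
#'
#' @inheritParams true_trajectory
#' @param event_time Generated event time, or `NA` if none in the horizon.
#' @return A list with `time` (recorded time), `status` (1 event /
#'   0 censored) and `visits` (data frame `day`, `value`).
#' @export
observe_nonmonotone <- function(scenario, b0, b1, event_time) {
  nocc <- 12L
  nominal <- scenario$visit_interval * seq_len(nocc)
  jitter <- sample.int(2L * scenario$window_days + 1L, nocc,
                       replace = TRUE) - scenario$window_days - 1L
  actual <- nominal + jitter
  n_miss <- sample.int(nocc + 1L, 1L) - 1L      # Uniform{0,...,12}
  miss <- if (n_miss > 0) sample.int(nocc, n_miss) else integer(0)
  kept <- if (length(miss)) actual[-miss] else actual
  cens <- if (length(kept)) max(kept) else 0
  if (!is.na(event_time) && event_time <= cens) {
    time <- event_time
    status <- 1L
  } else {
    time <- cens
    status <- 0L
  }
  days <- c(0L, kept)
  days <- if (status == 1L) days[days < time] else days[days <= time]
  value <- traj_value(scenario, b0, b1, days) +
    stats::rnorm(length(days), 0, sqrt(scenario$error_var))
  list(time = time, status = status,
       visits = data.frame(day = days, value = value))
}

# Replicate seed stream: a documented counter scheme mixing the scenario's
# root seed, its set id and the replicate index, kept below 2^31 - 1.
replicate_seed <- function(scenario, replicate_index) {
  sid <- if (is.na(scenario$set_id)) 0L else scenario$set_id
  as.integer((abs(as.numeric(scenario$seed)) * 100003 +
                sid * 10007 +
                as.numeric(replicate_index) * 101) %% 2147483647)
}

#' Simulate one complete dataset
#'
#' Generates random effects, event and censoring times and observed
#' longitudinal records for `n_per_group` subjects in each of two groups,
#' under the scenario's missingness regime. Fully reproducible: the RNG is
#' seeded from the scenario's root seed, its set id and `replicate_index`.
#'
#' @param scenario A [sim_scenario()].
#' @param replicate_index Replicate counter (1-based).
#' @return An object of class `sim_dataset`: a list with the `scenario`,
#'   the `replicate_index`, a `survival` data frame
#'   (`id`, `group`, `time`, `status`, `b0`, `b1`) and a long-format
#'   `longitudinal` data frame (`id`, `day`, `value`).
#' @export
simulate_dataset <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(replicate_seed(scenario, replicate_index))
  n <- scenario$n_per_group * scenario$n_groups
  group <- rep(0:1, each = scenario$n_per_group)
  b <- draw_random_effects(scenario$cov, n)
  Tev <- sim_event_times(scenario, b[, 1], b[, 2], group)

  if (scenario$missingness == "monotone") {
    C <- draw_censoring_monotone(n)
    status <- as.integer(!is.na(Tev) & Tev <= C)
    time <- ifelse(status == 1L, Tev, C)
    # visit counts on the 30-day grid strictly below the recorded time
    on_grid <- time %% scenario$visit_interval == 0 & time > 0
    nv <- pmin(13, floor(time / scenario$visit_interval) + 1)
    nv[on_grid] <- pmin(13, time[on_grid] / scenario$visit_interval)
    nv <- as.integer(nv)
    id_long <- rep(seq_len(n), nv)
    day <- scenario$visit_interval * (sequence(nv) - 1L)
    value <- true_trajectory(scenario, b[id_long, 1], b[id_long, 2], day) +
      stats::rnorm(length(day), 0, sqrt(scenario$error_var))
    longitudinal <- data.frame(id = id_long, day = day, value = value)
  } else {
    time <- numeric(n)
    status <- integer(n)
    vis <- vector("list", n)
    for (i in seq_len(n)) {
      obs <- observe_nonmonotone(scenario, b[i, 1], b[i, 2], Tev[i])
      time[i] <- obs$time
      status[i] <- obs$status
      vis[[i]] <- obs$visits
    }
    nv <- vapply(vis, nrow, integer(1))
    longitudinal <- data.frame(
      id = rep(seq_len(n), nv),
      day = unlist(lapply(vis, `[[`, "day"), use.names = FALSE),
      value = unlist(lapply(vis, `[[`, "value"), use.names = FALSE))
  }

  structure(
    list(scenario = scenario, replicate_index = as.integer(replicate_index),
         survival = data.frame(id = seq_len(n), group = group, time = time,
                               status = status, b0 = b[, 1], b1 = b[, 2]),
         longitudinal = longitudinal),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset (replicate %d): %d subjects, %d events, %d visits\n",
    x$replicate_index, nrow(x$survival), sum(x$survival$status),
    nrow(x$longitudinal)))
  invisible(x)
}
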