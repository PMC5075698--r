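#' Random-effects covariance specification
#'
#' Describes the 2x2 covariance matrix of the subject-level random intercept
#' and random slope of the latent trajectory. Four named forms (`"a"`--`"d"`)
#' span large/small variances crossed with large/small correlation.
#'
#' @param var_b0 Variance of the random intercept (predictor units squared).
#' @param var_b1 Variance of the random slope ((units/day)^2).
#' @param cov_b0b1 Covariance between intercept and slope.
#' @return An object of class `re_cov` with fields `var_b0`, `var_b1`,
#'   `cov_b0b1` and the implied `correlation`.
#' @export
re_cov <- function(var_b0, var_b1, cov_b0b1) {
  stopifnot(is.numeric(var_b0), is.numeric(var_b1), is.numeric(cov_b0b1))
  if (var_b0 <= 0 || var_b1 <= 0)
    stop("random-effect variances must be positive")
  if (cov_b0b1^2 > var_b0 * var_b1)
    stop("covariance exceeds the positive semi-definite bound")
  structure(
    list(var_b0 = var_b0, var_b1 = var_b1, cov_b0b1 = cov_b0b1,
         correlation = cov_b0b1 / sqrt(var_b0 * var_b1)),
    class = "re_cov")
}

#' @export
as.matrix.re_cov <- function(x, ...) {
  matrix(c(x$var_b0, x$cov_b0b1, x$cov_b0b1, x$var_b1), 2, 2)
}

#' The four named covariance forms
#'
#' @param form One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return A [re_cov()] object.
#' @export
re_cov_form <- function(form = c("a", "b", "c", "d")) {
  form <- match.arg(form)
  switch(form,
    a = re_cov(32, 0.002,  0.06),
    b = re_cov(32, 0.002,  0.02),
    c = re_cov(8,  0.0005, 0.02),
    d = re_cov(8,  0.0005, 0.002))
}

#' Define one simulation scenario
#'
#' A scenario fixes every ingredient of the generator: the latent linear
#' mixed-effects trajectory (fixed intercept/slope, random-effects
#' covariance, residual variance), the log-linear daily hazard (baseline
#' log-hazard, trajectory effect, group effect), the follow-up horizon and
#' visit schedule, the missingness regime and the sample size.
#'
#' @param a0,a1 Fixed-effect intercept (predictor units) and slope
#'   (units/day) of the trajectory.
#' @param cov A [re_cov()] object (or form letter) for the random effects.
#' @param error_var Variance of the Gaussian measurement error.
#' @param lambda0 Log baseline hazard (per day).
#' @param lambda1 Effect of the latent trajectory value on the log hazard.
#' @param tau Group effect on the log hazard (group indicator 0/1).
#' @param missingness `"monotone"` (visits every 30 days until the event or
#'   censoring) or `"nonmonotone"` (jittered visit days, haphazardly skipped
#'   occasions).
#' @param n_per_group Subjects per group (two groups).
#' @param seed Root seed for the scenario; replicate streams are derived
#'   from it (see [simulate_dataset()]).
#' @param set_id Optional integer label used in study tables.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(a0 = 40, a1 = 0.02, cov = "a", error_var = 16,
                         lambda0 = -4.8, lambda1 = -0.03, tau = 0,
                         missingness = c("monotone", "nonmonotone"),
                         n_per_group = 150, seed = 1L, set_id = NA_integer_) {
  if (is.character(cov)) cov <- re_cov_form(cov)
  stopifnot(inherits(cov, "re_cov"))
  missingness <- match.arg(missingness)
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  structure(
    list(a0 = a0, a1 = a1, cov = cov, error_var = error_var,
         lambda0 = lambda0, lambda1 = lambda1, tau = tau,
         missingness = missingness, n_per_group = as.integer(n_per_group),
         n_groups = 2L, horizon_days = 365L, visit_interval = 30L,
         window_days = 7L, seed = as.integer(seed),
         set_id = as.integer(set_id)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario%s: %s missingness\n",
    if (is.na(x$set_id)) "" else paste0(" set ", x$set_id), x$missingness))
  cat(sprintf("  trajectory: %g + %g t,  D = (%g, %g, cov %g),  Var(eps) = %g\n",
              x$a0, x$a1, x$cov$var_b0, x$cov$var_b1, x$cov$cov_b0b1,
              x$error_var))
  cat(sprintf("  hazard: exp(%g %+g m(t) %+g u),  n = %d x 2\n",
              x$lambda0, x$lambda1, x$tau, x$n_per_group))
  invisible(x)
}

#' The 36-scenario study grid
#'
#' Sets 1--16 use the monotone visit pattern, 17--32 the non-monotone
#' pattern. Within each block of 16 the order is: error variance 16 then 4;
#' within that, fixed slope 0.02 then 0.1; within that, covariance forms
#' a, b, c, d. Sets 33--36 duplicate sets 3, 7, 19 and 23 with a non-zero
#' group effect (tau = -0.5).
#'
#' @param n_per_group Subjects per group for every scenario.
#' @param seed Root seed assigned to every scenario (replicate streams also
#'   mix in the set id, so scenarios are mutually independent).
#' @return A list of 36 [sim_scenario()] objects, named `set1` ... `set36`.
#' @export
scenario_grid <- function(n_per_group = 150, seed = 1L) {
  grid <- list()
  set <- 0L
  for (miss in c("monotone", "nonmonotone")) {
    for (ev in c(16, 4)) {
      for (a1 in c(0.02, 0.1)) {
        for (form in c("a", "b", "c", "d")) {
          set <- set + 1L
          grid[[set]] <- sim_scenario(
            a1 = a1, cov = form, error_var = ev, missingness = miss,
            n_per_group = n_per_group, seed = seed, set_id = set)
        }
      }
    }
  }
  for (base in c(3L, 7L, 19L, 23L)) {
    set <- set + 1L
    sc <- grid[[base]]
    sc$tau <- -0.5
    sc$set_id <- set
    grid[[set]] <- sc
  }
  names(grid) <- paste0("set", seq_along(grid))
  grid
}
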