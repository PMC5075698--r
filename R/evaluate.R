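#' Confidence-interval coverage over replicates
#'
#' Percentage of converged replicates whose 95% interval contains the true
#' value; intervals are treated as closed, so a truth landing exactly on an
#' endpoint counts as covered.
#'
#' @param results Data frame of replicate results with columns `ci_low`,
#'   `ci_high`, `converged`.
#' @param true_value The true parameter value.
#' @return Percentage in `[0, 100]`, or `NA` if no replicate converged.
#' @export
coverage <- function(results, true_value) {
  ok <- results$converged & is.finite(results$ci_low) &
    is.finite(results$ci_high)
  if (!any(ok)) return(NA_real_)
  100 * mean(results$ci_low[ok] <= true_value &
               true_value <= results$ci_high[ok])
}

#' Percentage of estimates below the true value
#'
#' The study's bias diagnostic: the percentage of converged estimates
#' strictly less than the truth. Around 50 indicates an unbiased,
#' symmetric estimator.
#'
#' @param results Data frame with columns `estimate`, `converged`.
#' @param true_value The true parameter value.
#' @return Percentage in `[0, 100]`, or `NA` if no replicate converged.
#' @export
pct_below <- function(results, true_value) {
  ok <- results$converged & is.finite(results$estimate)
  if (!any(ok)) return(NA_real_)
  100 * mean(results$estimate[ok] < true_value)
}

#' Flag poorly performing cells
#'
#' A method/parameter cell is flagged when its 95% interval coverage is
#' strictly below 90% or its percentage of estimates below the truth falls
#' outside the closed interval `[40, 60]`. `NA` inputs propagate to `NA`
#' flags.
#'
#' @param coverage_pct,pct_below_truth Numeric vectors (percent).
#' @return Logical vector (with `NA` where the inputs are `NA`).
#' @export
flag_cell <- function(coverage_pct, pct_below_truth) {
  cov_bad <- ifelse(is.na(coverage_pct), NA, coverage_pct < 90)
  bias_bad <- ifelse(is.na(pct_below_truth), NA,
                     pct_below_truth < 40 | pct_below_truth > 60)
  cov_bad | bias_bad
}

# Fit one method on one simulated dataset; returns a one-row data frame of
# estimates/intervals for the predictor (lambda1-type) and group
# (tau-type) coefficients.
fit_method <- function(dataset, method, spec_joint = NULL) {
  res <- data.frame(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, tau_estimate = NA_real_,
                    tau_se = NA_real_, tau_ci_low = NA_real_,
                    tau_ci_high = NA_real_, converged = FALSE)
  out <- tryCatch({
    if (method %in% c("cox_baseline", "cox_locf")) {
      tab <- if (method == "cox_baseline") build_baseline_table(dataset)
             else build_locf_table(dataset)
      fit <- fit_cox(tab)
      list(est = fit$coef["value"], se = fit$se["value"],
           ci = fit$ci["value", ], tau = fit$coef["group"],
           tau_se = fit$se["group"], tau_ci = fit$ci["group", ],
           conv = fit$converged)
    } else {
      spec <- if (!is.null(spec_joint)) spec_joint else
        joint_spec(baseline = if (method == "joint_pc") "piecewise"
                   else "weibull")
      fit <- fit_joint(dataset, spec)
      list(est = fit$alpha, se = fit$se["alpha"], ci = fit$ci["alpha", ],
           tau = fit$gamma, tau_se = fit$se["gamma"],
           tau_ci = fit$ci["gamma", ], conv = fit$converged)
    }
  }, error = function(e) NULL)
  if (!is.null(out)) {
    res$estimate <- unname(out$est); res$se <- unname(out$se)
    res$ci_low <- unname(out$ci[1]); res$ci_high <- unname(out$ci[2])
    res$tau_estimate <- unname(out$tau); res$tau_se <- unname(out$tau_se)
    res$tau_ci_low <- unname(out$tau_ci[1])
    res$tau_ci_high <- unname(out$tau_ci[2])
    res$converged <- isTRUE(out$conv)
  }
  res
}

#' Run a replicate simulation study
#'
#' Simulates `replicates` datasets for each requested scenario, fits each
#' requested method, and summarizes interval coverage and the
#' percentage-below-truth diagnostic for the predictor and group
#' coefficients. Replicate seed streams are derived from the scenario's
#' root seed and the replicate index, so results are deterministic and
#' independent of execution order.
#'
#' @param scenarios A list of [sim_scenario()] objects (e.g. a subset of
#'   [scenario_grid()]).
#' @param methods Character vector from `"cox_baseline"`, `"cox_locf"`,
#'   `"joint_weibull"`, `"joint_pc"`.
#' @param replicates Number of replicates per scenario (default 100).
#' @param spec_joint Optional [joint_spec()] overriding joint-model
#'   settings for the `joint_*` methods.
#' @return A list with `replicates` (long data frame of per-replicate
#'   results) and `summary` (one row per scenario x method with
#'   `coverage_lambda1`, `pct_below_lambda1`, `coverage_tau`,
#'   `pct_below_tau`, `n_converged`, and the corresponding flags).
#' @export
run_study <- function(scenarios, methods = c("cox_baseline", "cox_locf"),
                      replicates = 100L, spec_joint = NULL) {
  stopifnot(replicates >= 1)
  methods <- match.arg(methods,
                       c("cox_baseline", "cox_locf", "joint_weibull",
                         "joint_pc"), several.ok = TRUE)
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- vector("list", length(scenarios) * length(methods) * replicates)
  k <- 0L
  for (sc in scenarios) {
    for (r in seq_len(replicates)) {
      ds <- simulate_dataset(sc, r)
      for (m in methods) {
        k <- k + 1L
        res <- fit_method(ds, m, spec_joint)
        res$set_id <- sc$set_id; res$replicate <- r; res$method <- m
        rows[[k]] <- res
      }
    }
  }
  rep_df <- do.call(rbind, rows[seq_len(k)])
  summ <- do.call(rbind, lapply(scenarios, function(sc) {
    do.call(rbind, lapply(methods, function(m) {
      d <- rep_df[rep_df$set_id == sc$set_id & rep_df$method == m, ]
      tau_d <- data.frame(estimate = d$tau_estimate,
                          ci_low = d$tau_ci_low, ci_high = d$tau_ci_high,
                          converged = d$converged)
      cl <- coverage(d, sc$lambda1)
      pl <- pct_below(d, sc$lambda1)
      ct <- coverage(tau_d, sc$tau)
      pt <- pct_below(tau_d, sc$tau)
      data.frame(set_id = sc$set_id, method = m,
                 coverage_lambda1 = cl, pct_below_lambda1 = pl,
                 coverage_tau = ct, pct_below_tau = pt,
                 n_converged = sum(d$converged),
                 flag_lambda1 = flag_cell(cl, pl),
                 flag_tau = flag_cell(ct, pt))
    }))
  }))
  rownames(summ) <- NULL
  list(replicates = rep_df, summary = summ)
}
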