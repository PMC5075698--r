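#' Counting-process table from the baseline predictor value only
#'
#' One at-risk interval `(0, time]` per subject, carrying the day-0
#' observed predictor value throughout follow-up. Subjects whose recorded
#' time is 0 (possible under the non-monotone regime when every
#' post-baseline occasion is missing) have no at-risk exposure and are
#' omitted.
#'
#' @param dataset A [simulate_dataset()] result, or any list with
#'   `survival` (`id`, `group`, `time`, `status`) and `longitudinal`
#'   (`id`, `day`, `value`) components.
#' @return A data frame with columns `id`, `start`, `stop`, `status`,
#'   `group`, `value`.
#' @export
build_baseline_table <- function(dataset) {
  surv <- dataset$survival
  long <- dataset$longitudinal
  base <- long[long$day == 0, c("id", "value")]
  if (!all(surv$id %in% base$id))
    stop("every subject needs a day-0 predictor value")
  tab <- data.frame(id = surv$id, start = 0, stop = surv$time,
                    status = surv$status,
                    group = surv$group,
                    value = base$value[match(surv$id, base$id)])
  tab[tab$stop > tab$start, , drop = FALSE]
}

#' Counting-process table with last observation carried forward
#'
#' A subject with visits at days `v1 = 0 < v2 < ... < vk` and recorded time
#' `t` contributes intervals `(v_j, v_{j+1}]` carrying the value observed at
#' `v_j`, with a final interval `(v_k, t]` carrying the last observed value
#' and the subject's event status. Zero-length intervals (a censoring time
#' equal to the last visit day) are dropped, with the status moved to the
#' last remaining interval.
#'
#' @inheritParams build_baseline_table
#' @return A data frame with columns `id`, `start`, `stop`, `status`,
#'   `group`, `value`.
#' @export
build_locf_table <- function(dataset) {
  surv <- dataset$survival
  long <- dataset$longitudinal
  long <- long[order(long$id, long$day), , drop = FALSE]
  n <- nrow(long)
  is_last <- long$id != c(long$id[-1], -1L)
  sidx <- match(long$id, surv$id)
  stop_day <- ifelse(is_last, surv$time[sidx], c(long$day[-1], NA))
  status <- ifelse(is_last, surv$status[sidx], 0L)
  tab <- data.frame(id = long$id, start = long$day, stop = stop_day,
                    status = as.integer(status),
                    group = surv$group[sidx], value = long$value)
  keep <- tab$stop > tab$start
  # a dropped terminal row (stop == start) passes its status backwards
  dropped <- which(!keep & tab$status == 1L)
  for (j in dropped) {
    prior <- which(keep & tab$id == tab$id[j])
    if (length(prior)) tab$status[max(prior)] <- 1L
  }
  tab[keep, , drop = FALSE]
}

# Breslow partial log-likelihood, score and information for a
# counting-process table; X is the (value, group) design matrix.
cox_pl_parts <- function(start, stop, status, X, beta) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  evt <- status == 1L
  ut <- sort(unique(stop[evt]))
  m <- length(ut)
  p <- ncol(X)
  R <- outer(start, ut, `<`) & outer(stop, ut, `>=`)
  S0 <- drop(crossprod(R, w))                         # m
  S1 <- crossprod(R, w * X)                           # m x p
  d <- vapply(ut, function(t) sum(evt & stop == t), numeric(1))
  sx <- rowsum(X[evt, , drop = FALSE], group = stop[evt])  # ordered by time
  loglik <- sum(eta[evt]) - sum(d * log(S0))
  Ebar <- S1 / S0
  grad <- colSums(sx) - colSums(d * Ebar)
  info <- matrix(0, p, p)
  for (k in seq_len(p)) {
    for (l in k:p) {
      S2kl <- drop(crossprod(R, w * X[, k] * X[, l]))
      v <- sum(d * (S2kl / S0 - Ebar[, k] * Ebar[, l]))
      info[k, l] <- info[l, k] <- v
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Cox partial log-likelihood and score
#'
#' Evaluates the Breslow-ties partial log-likelihood of a counting-process
#' table at a given coefficient vector, together with its score vector.
#' The at-risk convention is `(start, stop]`: a row is at risk at event
#' time `t` when `start < t <= stop`.
#'
#' @param table A counting-process data frame with columns `start`, `stop`,
#'   `status`, `value`, `group`.
#' @param beta Coefficient vector `(value, group)`.
#' @return A list with `loglik` and `grad`.
#' @export
cox_partial_loglik <- function(table, beta) {
  X <- cbind(value = table$value, group = table$group)
  parts <- cox_pl_parts(table$start, table$stop, table$status, X, beta)
  parts[c("loglik", "grad")]
}

#' Fit a Cox proportional-hazards model on a counting-process table
#'
#' Newton--Raphson maximization of the Breslow partial likelihood in two
#' coefficients (predictor value and group). Standard errors come from the
#' inverse observed information at the optimum; 95% confidence intervals
#' are Wald intervals on the coefficient scale.
#'
#' @param table A counting-process data frame (`start`, `stop`, `status`,
#'   `value`, `group`).
#' @param max_iter,tol Newton iteration cap and score-norm tolerance.
#' @return An object of class `cox_fit`: `coef`, `se`, `vcov`, `ci`
#'   (2 x 2 matrix of Wald limits), `loglik`, `n_events`, `converged`.
#' @export
fit_cox <- function(table, max_iter = 30L, tol = 1e-9) {
  if (sum(table$status) < 1) stop("at least one event is required")
  X <- cbind(value = table$value, group = table$group)
  if (length(unique(table$group)) == 1L) {
    # degenerate single-group table: drop the group column, report NA
    X <- X[, "value", drop = FALSE]
  }
  start <- table$start; stop_ <- table$stop; status <- table$status
  p <- ncol(X)
  beta <- rep(0, p)
  parts <- cox_pl_parts(start, stop_, status, X, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- solve(parts$info, parts$grad)
    stepsize <- 1
    repeat {
      cand <- beta + stepsize * step
      cand_parts <- cox_pl_parts(start, stop_, status, X, cand)
      if (cand_parts$loglik >= parts$loglik - 1e-12 || stepsize < 1e-4) break
      stepsize <- stepsize / 2
    }
    beta <- cand
    parts <- cand_parts
    if (sqrt(sum(parts$grad^2)) < tol) { converged <- TRUE; break }
  }
  if (any(abs(beta) > 15)) converged <- FALSE  # monotone-likelihood guard
  vc <- tryCatch(solve(parts$info), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  coef <- drop(beta); names(coef) <- colnames(X); names(se) <- colnames(X)
  if (p == 1L) {
    coef <- c(coef, group = NA_real_)
    se <- c(se, group = NA_real_)
  }
  ci <- cbind(lower = coef - 1.96 * se, upper = coef + 1.96 * se)
  structure(
    list(coef = coef, se = se, vcov = vc, ci = ci, loglik = parts$loglik,
         n_events = sum(status), converged = converged),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%d events, %s)\n", x$n_events,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(coef = x$coef, se = x$se,
                   lower95 = x$ci[, 1], upper95 = x$ci[, 2]))
  invisible(x)
}
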