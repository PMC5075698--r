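# Shared fixture builders; everything is generated in code under fixed
# seeds, no stored data.

fixture_scenario <- function(set = "set1", n_per_group = 150, seed = 3) {
  sc <- scenario_grid(seed = seed)[[set]]
  sc$n_per_group <- as.integer(n_per_group)
  sc
}

sim_event_times_fixture <- function(sc, n) {
  draw_event_time(sc, rep(0, n), rep(0, n), rep(0, n))
}

# direct multivariate-normal log-density via Cholesky (test oracle)
dmvnorm_log <- function(y, mu, V) {
  L <- chol(V)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# brute-force Breslow partial log-likelihood by risk-set enumeration
brute_partial_loglik <- function(tab, beta) {
  eta <- beta[1] * tab$value + beta[2] * tab$group
  ll <- 0
  for (j in which(tab$status == 1)) {
    t_e <- tab$stop[j]
    risk <- tab$start < t_e & t_e <= tab$stop
    ll <- ll + eta[j] - log(sum(exp(eta[risk])))
  }
  ll
}
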