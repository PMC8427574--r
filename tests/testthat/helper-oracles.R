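# Independent oracles, deliberately naive: used only to check the package's
# survival-backed implementations on small inputs.

# Breslow partial log-likelihood for a single binary covariate.
# Exact partial likelihood when there are no tied event times.
breslow_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    dead <- event & time == t
    at_risk <- time >= t
    ll <- ll + beta * sum(x[dead]) -
      sum(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Maximize the partial likelihood by 1-d search over beta in [-5, 5].
brute_force_loghr <- function(time, event, x) {
  stats::optimize(function(b) breslow_partial_loglik(b, time, event, x),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
}

# Day-by-day product-limit estimator.
naive_km <- function(time, event) {
  days <- sort(unique(time))
  s <- 1
  out <- data.frame(day = days, survival = NA_real_)
  for (i in seq_along(days)) {
    at_risk <- sum(time >= days[i])
    d <- sum(event & time == days[i])
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# Clopper-Pearson bounds by direct numeric inversion of binomial tails.
tail_inversion_ci <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p) - (1 - alpha / 2),
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Random draws of valid model parameters for property tests.
random_model_draws <- function(n, seed) {
  set.seed(seed)
  data.frame(
    delta = stats::runif(n, 0.05, 2),
    J = stats::runif(n, 0.01, 0.5),
    z = stats::runif(n, 0, 1),
    q = stats::runif(n, 0.05, 0.5),
    s_u = stats::runif(n, 0.005, 0.05)
  )
}
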