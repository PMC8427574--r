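#' Configuration for the stochastic cohort simulator
#'
#' Discrete-time (yearly) stochastic counterpart of the deterministic model.
#' Rates are interpreted as per-year probabilities, so all of `s_u`, `s_i`,
#' `q` must lie in \[0, 1\] alongside `z` and `J`.
#'
#' @param params A [transmission_params()] with `s_u`, `s_i`, `q` all <= 1.
#' @param annual_foundresses Number of new foundresses each year (>= 1).
#' @param J Foundress infection prevalence in \[0, 1\].
#' @param years Total simulated years (> `burn_in`).
#' @param burn_in Initial years discarded before summarising (>= 0).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   full configuration.
#' @param replicates Number of independent replicate runs (>= 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, annual_foundresses = 10000, J = 0.07,
                       years = 250, burn_in = 50, seed = 1L,
                       replicates = 1L) {
  stopifnot(inherits(params, "transmission_params"))
  for (nm in c("s_u", "s_i", "q")) {
    if (params[[nm]] > 1) {
      stop(sprintf("'%s' = %g is not interpretable as a yearly probability",
                   nm, params[[nm]]), call. = FALSE)
    }
  }
  chk_num(J, "J")
  if (J < 0 || J > 1) stop("'J' must be in [0, 1]", call. = FALSE)
  if (annual_foundresses < 1) {
    stop("'annual_foundresses' must be >= 1", call. = FALSE)
  }
  if (!(years > burn_in && burn_in >= 0)) {
    stop("require years > burn_in >= 0", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  structure(list(params = params,
                 annual_foundresses = as.integer(annual_foundresses),
                 J = J, years = as.integer(years),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

#' Simulate yearly cohorts of founding colonies
#'
#' Each year, `annual_foundresses` new foundresses arrive; a
#' binomial(`annual_foundresses`, `J`) draw of them carries the symbiont.
#' Infected foundresses mature with probability `s_i` and, conditional on
#' maturing, retain the symbiont with probability `z` (otherwise they join
#' the uninfected mature class); uninfected foundresses mature with
#' probability `s_u`. Every mature colony existing at the start of the year
#' dies with probability `q`; the year's new maturations join the census
#' afterwards, so each class fluctuates around `F * s / q`. The long-run
#' mean prevalence of
#' the infected mature class is an independent Monte-Carlo check on the
#' closed-form [equilibrium_prevalence()].
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with `counts` (data frame
#'   `replicate`, `year`, `M_i`, `M_u`), `V_hat` (post-burn-in mean
#'   prevalence), `se` (Monte-Carlo standard error of `V_hat`: across
#'   replicate means when `replicates >= 2`, otherwise batch means over the
#'   post-burn-in years), and the `config`.
#' @examples
#' p <- transmission_params(s_u = 0.01, s_i = 0.003, z = 1, q = 0.1)
#' r <- simulate_cohorts(sim_config(p, annual_foundresses = 2000,
#'                                  years = 80, burn_in = 30, seed = 7))
#' r$V_hat
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  n <- config$annual_foundresses
  set.seed(config$seed)
  rows <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    M_i <- 0L; M_u <- 0L
    yi <- integer(config$years); yu <- integer(config$years)
    for (t in seq_len(config$years)) {
      f_i <- stats::rbinom(1L, n, config$J)
      f_u <- n - f_i
      mat_i <- stats::rbinom(1L, f_i, p$s_i)
      keep <- stats::rbinom(1L, mat_i, p$z)
      mat_u <- stats::rbinom(1L, f_u, p$s_u) + (mat_i - keep)
      # mortality strikes colonies existing at the start of the year;
      # this year's maturations enter the census afterwards, so the
      # stationary mean of each class is F * s / q
      M_i <- M_i - stats::rbinom(1L, M_i, p$q) + keep
      M_u <- M_u - stats::rbinom(1L, M_u, p$q) + mat_u
      yi[t] <- M_i; yu[t] <- M_u
    }
    rows[[r]] <- data.frame(replicate = r, year = seq_len(config$years),
                            M_i = yi, M_u = yu)
  }
  counts <- do.call(rbind, rows)
  post <- counts[counts$year > config$burn_in, ]
  tot <- post$M_i + post$M_u
  prev <- ifelse(tot > 0, post$M_i / tot, NA_real_)
  V_hat <- mean(prev, na.rm = TRUE)
  if (config$replicates >= 2L) {
    rep_means <- tapply(prev, post$replicate,
                        function(v) mean(v, na.rm = TRUE))
    se <- stats::sd(rep_means) / sqrt(length(rep_means))
  } else {
    # batch means over the (autocorrelated) yearly series
    nb <- 10L
    b <- cut(seq_along(prev), nb, labels = FALSE)
    bm <- tapply(prev, b, function(v) mean(v, na.rm = TRUE))
    se <- stats::sd(bm) / sqrt(nb)
  }
  structure(list(counts = counts, V_hat = V_hat, se = se, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Stochastic cohort simulation: %d replicate(s), %d years (burn-in %d)\n",
    x$config$replicates, x$config$years, x$config$burn_in))
  cat(sprintf("  post-burn-in mean prevalence V_hat = %.5f (MC SE %.5f)\n",
              x$V_hat, x$se))
  invisible(x)
}

#' Summarise the simulated prevalence distribution
#'
#' Pools post-burn-in replicate-by-year prevalence values and reports their
#' mean, standard deviation, and central 95% interval (empirical quantiles).
#'
#' @param result A `sim_result` from [simulate_cohorts()].
#' @return List with `mean`, `sd`, `lower`, `upper` (2.5% and 97.5%
#'   quantiles, necessarily within \[0, 1\]).
#' @export
prevalence_distribution <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  cfg <- result$config
  post <- result$counts[result$counts$year > cfg$burn_in, ]
  tot <- post$M_i + post$M_u
  prev <- post$M_i[tot > 0] / tot[tot > 0]
  if (length(prev) < 2L) {
    stop("undefined prevalence: fewer than 2 post-burn-in years with ",
         "mature colonies", call. = FALSE)
  }
  qs <- unname(stats::quantile(prev, c(0.025, 0.975)))
  list(mean = mean(prev), sd = stats::sd(prev),
       lower = qs[1], upper = qs[2])
}
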