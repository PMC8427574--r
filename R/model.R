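#' Right-hand side of the mature-colony dynamics
#'
#' Instantaneous rates of change of the infected and uninfected mature-colony
#' classes under strict vertical transmission. Infected mature colonies are
#' produced by infected foundresses that mature (rate `s_i`) and retain the
#' symbiont (probability `z`); infected foundresses that mature but lose the
#' symbiont (`s_i * (1 - z)`) feed the uninfected class, alongside uninfected
#' foundresses maturing at `s_u`. Both mature classes die at the shared rate
#' `q`:
#'
#' \deqn{dM_i/dt = F_i s_i z - M_i q}
#' \deqn{dM_u/dt = F_u s_u + F_i s_i (1 - z) - M_u q}
#'
#' @param state A [population_state()].
#' @param params A [transmission_params()].
#' @return Named numeric vector `c(dM_i_dt, dM_u_dt)` (year^-1).
#' @examples
#' p <- transmission_params(s_u = 0.04, s_i = 0.02, z = 0.25, q = 0.1)
#' ode_rhs(population_state(F_u = 50, F_i = 100), p)
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "transmission_params"))
  dMi <- state$F_i * params$s_i * params$z - state$M_i * params$q
  dMu <- state$F_u * params$s_u + state$F_i * params$s_i * (1 - params$z) -
    state$M_u * params$q
  c(dM_i_dt = dMi, dM_u_dt = dMu)
}

#' Equilibrium of the mature-colony classes
#'
#' Closed-form fixed point of the mature-colony dynamics with foundress
#' counts held constant: `M_i* = F_i s_i z / q` and
#' `M_u* = (F_u s_u + F_i s_i (1 - z)) / q`.
#'
#' @param params A [transmission_params()].
#' @param F_i,F_u Constant foundress counts.
#' @return A [population_state()] at which [ode_rhs()] vanishes.
#' @examples
#' p <- transmission_params(s_u = 0.01, s_i = 0.01, z = 1, q = 0.1)
#' equilibrium_state(p, F_i = 70, F_u = 930)
#' @export
equilibrium_state <- function(params, F_i, F_u) {
  stopifnot(inherits(params, "transmission_params"))
  chk_num(F_i, "F_i"); chk_num(F_u, "F_u")
  if (F_i < 0 || F_u < 0) stop("foundress counts must be >= 0", call. = FALSE)
  if (params$q <= 0) stop("no equilibrium exists when q <= 0", call. = FALSE)
  M_i <- F_i * params$s_i * params$z / params$q
  M_u <- (F_u * params$s_u + F_i * params$s_i * (1 - params$z)) / params$q
  population_state(F_u = F_u, F_i = F_i, M_u = M_u, M_i = M_i)
}

#' Equilibrium mature-colony infection prevalence
#'
#' The model's central closed form: at equilibrium the fraction of mature
#' colonies carrying the symbiont is
#' \deqn{V = \frac{\delta z}{1/J - 1 + \delta}}
#' where `delta = s_i/s_u` is the symbiont's effect on the chance a foundress
#' reaches maturity, `J` the foundress infection prevalence, and `z` the
#' persistence probability of the inherited infection. `V` is bounded by `z`,
#' so even a neutral symbiont (`delta = 1`) with perfect persistence
#' (`z = 1`) can at most mirror the foundress prevalence (`V = J`).
#'
#' `J = 0` or `delta = 0` return 0 by continuity; the single indeterminate
#' point `J = 1, delta = 0` is an error.
#'
#' @param delta Unitless virulence ratio, >= 0.
#' @param J Foundress infection prevalence in \[0, 1\].
#' @param z Persistence probability in \[0, 1\].
#' @return Prevalence `V` in \[0, z\].
#' @examples
#' equilibrium_prevalence(0.3, 0.07, 1) # ~0.022
#' equilibrium_prevalence(1, 0.07, 1)   # 0.07
#' @export
equilibrium_prevalence <- function(delta, J, z) {
  chk_num(delta, "delta"); chk_num(J, "J"); chk_num(z, "z")
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  if (J < 0 || J > 1) stop("'J' must be in [0, 1]", call. = FALSE)
  if (z < 0 || z > 1) stop("'z' must be in [0, 1]", call. = FALSE)
  if (J == 1 && delta == 0) {
    stop("degenerate input: J = 1 with delta = 0 leaves V indeterminate",
         call. = FALSE)
  }
  if (J == 0 || delta == 0) return(0)
  delta * z / (1 / J - 1 + delta)
}

#' Integrate the mature-colony dynamics
#'
#' Numerical companion to the closed-form equilibrium: integrates the
#' two mature-colony equations forward with foundress counts fixed, using a
#' fixed-step 4th-order Runge-Kutta scheme. If the step is too coarse for
#' the decay rate (`step >= 1/q`) the integrator warns and switches to an
#' adaptive solver.
#'
#' @param params A [transmission_params()].
#' @param F_i,F_u Constant foundress counts.
#' @param initial A [population_state()] giving the starting mature-colony
#'   counts; its foundress fields are ignored in favour of `F_i`, `F_u`.
#'   Defaults to empty mature classes.
#' @param horizon Length of the run in years; default `20 / q`, ample for
#'   convergence of the prevalence to its limit.
#' @param step Output/integration step in years; default `0.1 / q`.
#' @return An object of class `trajectory`: a data frame with columns
#'   `time`, `M_i`, `M_u`, `V` (instantaneous prevalence, `NA` when both
#'   classes are empty).
#' @examples
#' p <- transmission_params(delta = 0.3, z = 1, q = 0.1)
#' tr <- integrate_dynamics(p, F_i = 70, F_u = 930)
#' tail(tr, 1)$V # ~ equilibrium_prevalence(0.3, 70/1000, 1)
#' @export
integrate_dynamics <- function(params, F_i, F_u,
                               initial = population_state(F_u, F_i),
                               horizon = 20 / params$q,
                               step = 0.1 / params$q) {
  stopifnot(inherits(params, "transmission_params"),
            inherits(initial, "population_state"))
  chk_num(F_i, "F_i"); chk_num(F_u, "F_u")
  if (horizon <= 0) stop("'horizon' must be > 0", call. = FALSE)
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  method <- "rk4"
  if (step >= 1 / params$q) {
    warning("step >= 1/q: fixed-step integration would be inaccurate; ",
            "using adaptive solver (lsoda)")
    method <- "lsoda"
  }
  times <- seq(0, horizon, by = step)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  rhs <- function(t, y, parms) {
    st <- population_state(F_u = F_u, F_i = F_i,
                           M_u = max(y[["M_u"]], 0), M_i = max(y[["M_i"]], 0))
    d <- ode_rhs(st, params)
    list(c(M_i = d[["dM_i_dt"]], M_u = d[["dM_u_dt"]]))
  }
  sol <- deSolve::ode(y = c(M_i = initial$M_i, M_u = initial$M_u),
                      times = times, func = rhs, parms = NULL,
                      method = method)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  tot <- out$M_i + out$M_u
  out$V <- ifelse(tot > 0, out$M_i / tot, NA_real_)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Ceiling on the vertical-transmission share of field prevalence
#'
#' Ratio of the model's equilibrium prevalence (what strict vertical
#' transmission could at most sustain) to the prevalence observed in the
#' field; the reporting layer rounds it to the nearest percent.
#'
#' @param V_model Model equilibrium prevalence in \[0, 1\].
#' @param V_field Field-observed mature-colony prevalence in (0, 1\].
#' @return The fraction `V_model / V_field` (unrounded).
#' @examples
#' vertical_contribution_ratio(0.02, 0.73) # ~0.027, "3%"
#' @export
vertical_contribution_ratio <- function(V_model, V_field) {
  chk_num(V_model, "V_model"); chk_num(V_field, "V_field")
  if (V_model < 0 || V_model > 1) {
    stop("'V_model' must be in [0, 1]", call. = FALSE)
  }
  if (V_field <= 0 || V_field > 1) {
    stop("'V_field' must be in (0, 1]; the ratio is undefined at 0",
         call. = FALSE)
  }
  V_model / V_field
}

#' Equilibrium prevalence over a parameter grid
#'
#' Evaluates [equilibrium_prevalence()] on the full factorial grid of the
#' supplied `delta`, `J` and `z` values, for sensitivity analysis. `V` is
#' nondecreasing along each axis with the others held fixed.
#'
#' @param delta_values,J_values,z_values Nonempty numeric vectors within the
#'   respective parameter domains.
#' @return A data frame with columns `delta`, `J`, `z`, `V`, one row per
#'   combination.
#' @examples
#' sensitivity_grid(c(0.3, 1), 0.07, 1)
#' @export
sensitivity_grid <- function(delta_values, J_values, z_values) {
  if (length(delta_values) == 0 || length(J_values) == 0 ||
      length(z_values) == 0) {
    stop("all three value lists must be nonempty", call. = FALSE)
  }
  g <- expand.grid(delta = delta_values, J = J_values, z = z_values,
                   KEEP.OUT.ATTRS = FALSE)
  g$V <- mapply(equilibrium_prevalence, g$delta, g$J, g$z)
  g
}
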