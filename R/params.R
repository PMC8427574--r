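#' Transmission model parameters
#'
#' Constructs the rate set for the two-class colony transmission model:
#' maturation rates of uninfected (`s_u`) and infected (`s_i`) foundresses,
#' the persistence probability `z` of an inherited symbiont through colony
#' development, and the mature-colony mortality rate `q` (shared by infected
#' and uninfected colonies). The virulence ratio `delta = s_i / s_u` is
#' derived and stored.
#'
#' Either both absolute rates (`s_u`, `s_i`) or the ratio `delta` may be
#' supplied, never both. Absolute rates are not identifiable from the
#' equilibrium prevalence (only `delta` is), so when `delta` alone is given
#' a placeholder `s_u` is used and the result is flagged with
#' `rates_placeholder = TRUE`; reporting layers should surface this flag.
#'
#' @param s_u Maturation rate of uninfected foundresses
#'   (colony individual^-1 year^-1). Must be > 0.
#' @param s_i Maturation rate of infected foundresses (same units). Must be
#'   >= 0. Supply together with `s_u`, or omit and give `delta`.
#' @param delta Unitless ratio `s_i / s_u`; alternative to `s_i`.
#' @param z Probability in \[0, 1\] that an inherited symbiont persists from
#'   founding to colony maturity.
#' @param q Mature-colony mortality rate (year^-1). Must be > 0.
#' @return An object of class `transmission_params`: a list with elements
#'   `s_u`, `s_i`, `delta`, `z`, `q`, `rates_placeholder`.
#' @examples
#' transmission_params(s_u = 0.01, s_i = 0.003, z = 1, q = 0.1)
#' transmission_params(delta = 0.3) # placeholder absolute rates
#' @export
transmission_params <- function(s_u = NULL, s_i = NULL, delta = NULL,
                                z = 1, q = 0.1) {
  if (!is.null(delta) && !is.null(s_i)) {
    stop("supply either 's_i' (with 's_u') or 'delta', not both",
         call. = FALSE)
  }
  placeholder <- FALSE
  if (!is.null(delta)) {
    stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
    if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
    if (is.null(s_u)) {
      s_u <- 0.01 # arbitrary placeholder; only the ratio is identified
      placeholder <- TRUE
    }
    s_i <- delta * s_u
  }
  if (is.null(s_u) || is.null(s_i)) {
    stop("supply both 's_u' and 's_i', or 'delta'", call. = FALSE)
  }
  chk_num(s_u, "s_u"); chk_num(s_i, "s_i")
  chk_num(z, "z"); chk_num(q, "q")
  if (s_u <= 0) stop("'s_u' must be > 0", call. = FALSE)
  if (s_i < 0) stop("'s_i' must be >= 0", call. = FALSE)
  if (z < 0 || z > 1) stop("'z' must be in [0, 1]", call. = FALSE)
  if (q <= 0) stop("'q' must be > 0", call. = FALSE)
  structure(
    list(s_u = s_u, s_i = s_i, delta = s_i / s_u, z = z, q = q,
         rates_placeholder = placeholder),
    class = "transmission_params"
  )
}

#' @export
print.transmission_params <- function(x, ...) {
  cat("Transmission parameters\n")
  cat(sprintf("  s_u = %g, s_i = %g (delta = s_i/s_u = %g)%s\n",
              x$s_u, x$s_i, x$delta,
              if (x$rates_placeholder) "  [absolute rates are placeholders]"
              else ""))
  cat(sprintf("  z = %g (symbiont persistence), q = %g /yr (colony mortality)\n",
              x$z, x$q))
  invisible(x)
}

#' Population state of the four colony classes
#'
#' Counts of uninfected/infected foundresses (`F_u`, `F_i`) and mature
#' colonies (`M_u`, `M_i`). Foundress counts are treated as exogenous
#' constants by the model; only the mature classes have dynamics.
#'
#' @param F_u,F_i Foundress counts (without / with symbiont). Nonnegative.
#' @param M_u,M_i Mature colony counts (without / with symbiont). Nonnegative.
#' @return An object of class `population_state`.
#' @examples
#' population_state(F_u = 930, F_i = 70, M_u = 0, M_i = 0)
#' @export
population_state <- function(F_u, F_i, M_u = 0, M_i = 0) {
  for (nm in c("F_u", "F_i", "M_u", "M_i")) {
    v <- get(nm)
    chk_num(v, nm)
    if (v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  structure(list(F_u = F_u, F_i = F_i, M_u = M_u, M_i = M_i),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: F_u = %g, F_i = %g, M_u = %g, M_i = %g\n",
              x$F_u, x$F_i, x$M_u, x$M_i))
  invisible(x)
}

# single finite numeric scalar check
chk_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(TRUE)
}
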