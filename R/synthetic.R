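#' Design for a synthetic foundress-chamber survivorship experiment
#'
#' Describes a daily-checked, two-treatment incipient-garden survivorship
#' experiment: chambers split across nuptial flights, nests nested within
#' flight contributing a shared log-hazard (frailty) effect, an exponential
#' garden-failure time whose hazard is multiplied by `exp(true_log_hr)` in
#' the symbiont treatment, an independent foundress-death process, and right
#' censoring at the end of follow-up. Defaults mirror a 96-chamber,
#' two-flight (53 + 43) design.
#'
#' @param flights Data frame with columns `flight_id`, `n_chambers`;
#'   default `data.frame(flight_id = c("F1","F2"), n_chambers = c(53, 43))`.
#' @param nests_per_flight Distinct source nests per flight (default 4).
#' @param treatment_ratio Fraction of chambers in the symbiont ("roach")
#'   arm; allocation is balanced within flight (default 0.5).
#' @param baseline_daily_hazard Garden-failure hazard in the control arm
#'   (day^-1, default 0.02).
#' @param true_log_hr Log hazard ratio of the symbiont treatment
#'   (default `log(3.36)`).
#' @param frailty_sd SD of the nest-level normal log-hazard effect
#'   (default 0.3).
#' @param foundress_daily_death_hazard Treatment-independent foundress
#'   death hazard (day^-1, default 0.005).
#' @param followup_days Administrative censoring day (default 60).
#' @param disturbance_prob Probability a symbiont-arm chamber shows garden
#'   disturbance (default 0.625).
#' @param seed Integer seed.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(
    flights = data.frame(flight_id = c("F1", "F2"), n_chambers = c(53, 43)),
    nests_per_flight = 4L, treatment_ratio = 0.5,
    baseline_daily_hazard = 0.02, true_log_hr = log(3.36),
    frailty_sd = 0.3, foundress_daily_death_hazard = 0.005,
    followup_days = 60L, disturbance_prob = 0.625, seed = 1L) {
  stopifnot(is.data.frame(flights),
            all(c("flight_id", "n_chambers") %in% names(flights)))
  if (sum(flights$n_chambers) < 2) {
    stop("design needs at least 2 chambers", call. = FALSE)
  }
  if (treatment_ratio < 0 || treatment_ratio > 1) {
    stop("'treatment_ratio' must be in [0, 1]", call. = FALSE)
  }
  if (baseline_daily_hazard < 0 || foundress_daily_death_hazard < 0 ||
      frailty_sd < 0) {
    stop("hazards and frailty_sd must be >= 0", call. = FALSE)
  }
  if (followup_days < 1) stop("'followup_days' must be >= 1", call. = FALSE)
  if (disturbance_prob < 0 || disturbance_prob > 1) {
    stop("'disturbance_prob' must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    flights = flights, nests_per_flight = as.integer(nests_per_flight),
    treatment_ratio = treatment_ratio,
    baseline_daily_hazard = baseline_daily_hazard,
    true_log_hr = true_log_hr, frailty_sd = frailty_sd,
    foundress_daily_death_hazard = foundress_daily_death_hazard,
    followup_days = as.integer(followup_days),
    disturbance_prob = disturbance_prob, seed = as.integer(seed)
  ), class = "experiment_design")
}

#' Generate a synthetic survivorship experiment
#'
#' Draws one dataset from an [experiment_design()]. Each chamber gets a
#' flight, a nest uniformly within its flight, and a treatment (balanced
#' allocation within flight, randomly permuted). Garden-failure times are
#' exponential with hazard
#' `baseline * exp(nest effect + treatment * true_log_hr)` and are rounded
#' up to whole days (the daily-check protocol, which forces ties);
#' foundress death is an independent exponential on its own hazard. The
#' observed outcome is whichever comes first, censored at `followup_days`;
#' same-day collisions resolve to foundress death (a dead caretaker makes
#' the garden effectively dead). Symbiont-arm chambers carry a disturbance
#' flag drawn with `disturbance_prob`; the flag is `NA` in the control arm.
#'
#' @param design An [experiment_design()].
#' @return Data frame of survival records with columns `chamber_id`,
#'   `treatment` (`"roach"`/`"no_roach"`), `flight_id`, `nest_id`, `day`,
#'   `garden_outcome` (`"uncaring"`, `"foundress_dead"`, `"censored"`),
#'   `foundress_died`, `disturbed`. Bit-identical for a fixed seed.
#' @export
generate_survival_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  recs <- lapply(seq_len(nrow(design$flights)), function(i) {
    fl <- design$flights$flight_id[i]
    n <- design$flights$n_chambers[i]
    nest_ids <- paste0(fl, "_N", seq_len(design$nests_per_flight))
    nest_eff <- stats::rnorm(design$nests_per_flight, 0, design$frailty_sd)
    names(nest_eff) <- nest_ids
    nest <- sample(nest_ids, n, replace = TRUE)
    n_roach <- round(n * design$treatment_ratio)
    treatment <- sample(rep(c("roach", "no_roach"),
                            c(n_roach, n - n_roach)))
    haz <- design$baseline_daily_hazard *
      exp(nest_eff[nest] + (treatment == "roach") * design$true_log_hr)
    garden_day <- ifelse(haz > 0, ceiling(stats::rexp(n, pmax(haz, 1e-300))),
                         Inf)
    garden_day[haz == 0] <- Inf
    fh <- design$foundress_daily_death_hazard
    death_day <- if (fh > 0) ceiling(stats::rexp(n, fh)) else rep(Inf, n)
    day <- pmin(garden_day, death_day, design$followup_days)
    outcome <- ifelse(day == design$followup_days &
                        garden_day > day & death_day > day, "censored",
                      ifelse(death_day <= garden_day, "foundress_dead",
                             "uncaring"))
    disturbed <- rep(NA, n)
    roach <- treatment == "roach"
    disturbed[roach] <- stats::runif(sum(roach)) < design$disturbance_prob
    data.frame(flight_id = fl, nest_id = nest, treatment = treatment,
               day = as.integer(day), garden_outcome = outcome,
               foundress_died = outcome == "foundress_dead",
               disturbed = disturbed, row.names = NULL)
  })
  out <- do.call(rbind, recs)
  out <- cbind(chamber_id = sprintf("C%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Design for a synthetic nuptial-flight field survey
#'
#' @param n_colonies Number of mature colonies sampled (default 11).
#' @param p_colony_infected Probability a colony harbours the symbiont
#'   (default 8/11, the field estimate).
#' @param alates_min,alates_max Per-colony female-alate sample size range;
#'   sampled uniformly (defaults 300 and 1000).
#' @param prevalence_low,prevalence_high Per-colony alate-hitchhiker
#'   prevalence range for infected colonies (defaults 0.022 and 0.068).
#' @param seed Integer seed.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(n_colonies = 11L, p_colony_infected = 8 / 11,
                          alates_min = 300L, alates_max = 1000L,
                          prevalence_low = 0.022, prevalence_high = 0.068,
                          seed = 1L) {
  if (p_colony_infected < 0 || p_colony_infected > 1) {
    stop("'p_colony_infected' must be in [0, 1]", call. = FALSE)
  }
  if (!(prevalence_low >= 0 && prevalence_low <= prevalence_high &&
        prevalence_high <= 1)) {
    stop("prevalence range must satisfy 0 <= low <= high <= 1",
         call. = FALSE)
  }
  if (n_colonies < 1 || alates_min < 1 || alates_max < alates_min) {
    stop("invalid colony or alate counts", call. = FALSE)
  }
  structure(list(n_colonies = as.integer(n_colonies),
                 p_colony_infected = p_colony_infected,
                 alates_min = as.integer(alates_min),
                 alates_max = as.integer(alates_max),
                 prevalence_low = prevalence_low,
                 prevalence_high = prevalence_high,
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Generate a synthetic field survey
#'
#' Each colony is infected with probability `p_colony_infected`; infected
#' colonies draw a true per-colony prevalence uniformly from the design's
#' prevalence range and a binomial count of alates bearing a hitchhiker;
#' uninfected colonies have zero. Seed-deterministic.
#'
#' @param design A [survey_design()].
#' @return Data frame of survey records with columns `colony_id`, `site`,
#'   `alates_sampled`, `alates_with_roach`.
#' @export
generate_field_survey <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  set.seed(design$seed)
  n <- design$n_colonies
  alates <- sample(design$alates_min:design$alates_max, n, replace = TRUE)
  infected <- stats::runif(n) < design$p_colony_infected
  prev <- ifelse(infected,
                 stats::runif(n, design$prevalence_low,
                              design$prevalence_high), 0)
  with_roach <- stats::rbinom(n, alates, prev)
  data.frame(colony_id = sprintf("colony_%02d", seq_len(n)),
             site = "synthetic_site",
             alates_sampled = alates, alates_with_roach = with_roach)
}

#' Generate garden-disturbance flags
#'
#' Independent Bernoulli draws emulating the per-chamber "disturbed /
#' undisturbed" scoring of symbiont behaviour.
#'
#' @param n Number of chambers.
#' @param p Disturbance probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Logical vector of length `n`; seed-deterministic.
#' @export
generate_disturbance_flags <- function(n, p, seed = 1L) {
  chk_num(p, "p")
  if (p < 0 || p > 1) stop("'p' must be in [0, 1]", call. = FALSE)
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  set.seed(seed)
  stats::runif(n) < p
}
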