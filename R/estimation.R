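#' Derive endpoint times and event indicators from survival records
#'
#' The survivorship experiment admits two endpoint definitions for a
#' "nonsurviving" incipient garden: `combined` counts both gardens abandoned
#' by an uncaring foundress and gardens whose foundress died as events;
#' `uncaring_only` counts only abandonment, right-censoring foundress-death
#' chambers at the death day (censoring rather than deletion preserves the
#' risk sets). Explicitly censored rows are never events.
#'
#' @param records Data frame of survival records with at least columns
#'   `day` (integer >= 1) and `garden_outcome`
#'   (`"uncaring"`, `"foundress_dead"`, or `"censored"`).
#' @param definition `"combined"` (default) or `"uncaring_only"`.
#' @return Data frame with columns `time` (days) and `event` (logical),
#'   one row per record, in input order.
#' @export
endpoint_events <- function(records, definition = c("combined",
                                                    "uncaring_only")) {
  definition <- match.arg(definition)
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("'records' must be a nonempty data frame", call. = FALSE)
  }
  stopifnot(all(c("day", "garden_outcome") %in% names(records)))
  out <- records$garden_outcome
  bad <- setdiff(unique(out), c("uncaring", "foundress_dead", "censored"))
  if (length(bad)) {
    stop("unknown garden_outcome value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  event <- switch(definition,
    combined = out %in% c("uncaring", "foundress_dead"),
    uncaring_only = out == "uncaring"
  )
  data.frame(time = records$day, event = event)
}

#' Cox proportional-hazards fit for the two-treatment experiment
#'
#' Fits the treatment effect on the garden-failure hazard by maximizing the
#' Cox partial likelihood (via [survival::coxph()]), with the Breslow or
#' Efron correction for the heavy ties that daily checks produce. When
#' `frailty_group` is supplied, a gamma shared frailty (penalized partial
#' likelihood) absorbs group-level (nest-within-flight) heterogeneity.
#' The symbiont virulence ratio is derived as `delta = 1 / hazard ratio`.
#'
#' @param times Positive event/censoring times (days).
#' @param events Logical (or 0/1) event indicators.
#' @param group Binary treatment indicator (0/1, logical, or a two-level
#'   factor); the hazard ratio is for level 1 vs level 0.
#' @param ties_method `"breslow"` (default; explicit because daily checks
#'   guarantee ties) or `"efron"`.
#' @param frailty_group Optional vector of shared-frailty group identifiers.
#' @return An object of class `cox_result`: list with `log_hr`, `hr`, `se`,
#'   `wald_z`, `p_value`, `delta`, `ties_method`, `frailty_variance`
#'   (`NA` when no frailty term), `n`, `n_events`.
#' @export
cox_fit <- function(times, events, group,
                    ties_method = c("breslow", "efron"),
                    frailty_group = NULL) {
  ties_method <- match.arg(ties_method)
  if (any(times <= 0)) stop("'times' must be positive", call. = FALSE)
  events <- as.logical(events)
  g <- as_binary_group(group)
  for (lev in c(0, 1)) {
    if (sum(events[g == lev]) == 0) {
      stop(sprintf(
        "no events in group %s: partial likelihood is monotone (divergent)",
        lev), call. = FALSE)
    }
  }
  dat <- data.frame(time = times, event = events, x = g)
  if (is.null(frailty_group)) {
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                           ties = ties_method)
    fv <- NA_real_
  } else {
    dat$fg <- frailty_group
    fit <- survival::coxph(
      survival::Surv(time, event) ~ x +
        survival::frailty(fg, distribution = "gamma"),
      data = dat, ties = ties_method)
    fv <- tryCatch(fit$history[[1]]$theta, error = function(e) NA_real_)
  }
  log_hr <- unname(stats::coef(fit)["x"])
  se <- sqrt(unname(fit$var[1, 1]))
  z <- log_hr / se
  structure(list(
    log_hr = log_hr, hr = exp(log_hr), se = se, wald_z = z,
    p_value = 2 * stats::pnorm(-abs(z)), delta = exp(-log_hr),
    ties_method = ties_method, frailty_variance = fv,
    n = nrow(dat), n_events = sum(events)
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit (%s ties%s): n = %d, events = %d\n",
    x$ties_method,
    if (!is.na(x$frailty_variance)) {
      sprintf(", gamma frailty var = %.4g", x$frailty_variance)
    } else "",
    x$n, x$n_events))
  cat(sprintf(
    "  hazard ratio = %.3f (log HR %.4f, SE %.4f), z = %.2f, p = %.3g\n",
    x$hr, x$log_hr, x$se, x$wald_z, x$p_value))
  cat(sprintf("  delta = 1/HR = %.4f\n", x$delta))
  invisible(x)
}

as_binary_group <- function(group) {
  if (is.factor(group)) group <- as.integer(group) - 1L
  if (is.logical(group)) group <- as.integer(group)
  u <- sort(unique(group))
  if (!all(u %in% c(0, 1)) || length(u) != 2L) {
    stop("'group' must be binary with both levels present", call. = FALSE)
  }
  as.numeric(group)
}

#' Virulence ratio from a hazard ratio
#'
#' The symbiont's multiplicative effect on a foundress's chance of reaching
#' colony maturity is the inverse of the fitted garden-failure hazard ratio:
#' `delta = 1 / hr`. An HR of 1 (neutral symbiont) gives `delta = 1`; an HR
#' above 1 (harmful) gives `delta < 1`.
#'
#' @param hr Positive hazard ratio.
#' @return `delta = 1 / hr`.
#' @examples
#' delta_from_hr(3.36) # ~0.298, reported as 0.3
#' @export
delta_from_hr <- function(hr) {
  chk_num(hr, "hr")
  if (hr <= 0) stop("'hr' must be > 0", call. = FALSE)
  1 / hr
}

#' Kaplan-Meier survivorship by treatment group
#'
#' Product-limit estimates of garden survivorship per treatment group, with
#' same-day events aggregated (ties pooled by day). Each curve starts at 1
#' at day 0 and is nonincreasing.
#'
#' @param times Nonnegative times (days).
#' @param events Logical event indicators.
#' @param group Group labels (any type with >= 1 level).
#' @return Data frame with columns `group`, `day`, `survival` including a
#'   `day = 0, survival = 1` row per group.
#' @export
km_survivorship <- function(times, events, group) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)
  dat <- data.frame(time = times, event = as.logical(events),
                    group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(unique(dat$group), length(sm$time))
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  curves <- data.frame(group = grp, day = sm$time, survival = sm$surv)
  origins <- data.frame(group = unique(dat$group), day = 0, survival = 1)
  out <- rbind(origins, curves)
  out[order(out$group, out$day), , drop = FALSE]
}

#' Pearson chi-square test on a 2x2 table
#'
#' Tests homogeneity of two proportions from the counts
#' `(a, b)` / `(c, d)` (rows = groups, columns = outcome), with optional
#' Yates continuity correction (the default, matching common statistical
#' practice for 2x2 tables).
#'
#' @param a,b,c,d Nonnegative cell counts.
#' @param continuity_correction Apply the Yates correction (default `TRUE`).
#' @return List with `x2`, `df` (always 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity_correction = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction))
  list(x2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Binomial proportion confidence interval
#'
#' Point estimate and confidence interval for a binomial proportion. The
#' default `clopper_pearson` method gives exact bounds from beta quantiles
#' (equivalently, inversion of the binomial tail probabilities); `wilson`
#' and `wald` are the usual normal approximations.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param method `"clopper_pearson"` (default), `"wilson"`, or `"wald"`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return List with `p_hat`, `lower`, `upper`, `method`, `level`.
#' @examples
#' proportion_ci(60, 96) # ~ (0.520, 0.722)
#' @export
proportion_ci <- function(k, n, method = c("clopper_pearson", "wilson",
                                           "wald"), level = 0.95) {
  method <- match.arg(method)
  chk_num(k, "k"); chk_num(n, "n"); chk_num(level, "level")
  if (n < 1 || k < 0 || k > n) stop("require 0 <= k <= n, n >= 1",
                                    call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)",
                                     call. = FALSE)
  p_hat <- k / n
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else if (method == "wilson") {
    zq <- stats::qnorm(1 - alpha / 2)
    centre <- (p_hat + zq^2 / (2 * n)) / (1 + zq^2 / n)
    half <- zq * sqrt(p_hat * (1 - p_hat) / n + zq^2 / (4 * n^2)) /
      (1 + zq^2 / n)
    lower <- max(0, centre - half); upper <- min(1, centre + half)
  } else {
    zq <- stats::qnorm(1 - alpha / 2)
    half <- zq * sqrt(p_hat * (1 - p_hat) / n)
    lower <- max(0, p_hat - half); upper <- min(1, p_hat + half)
  }
  list(p_hat = p_hat, lower = lower, upper = upper, method = method,
       level = level)
}

#' Summarise a nuptial-flight field survey
#'
#' Per-colony symbiont prevalence among sampled female alates, the fraction
#' of colonies infected (a colony is infected when at least one sampled
#' alate carries a hitchhiking symbiont), and the maximum per-colony
#' prevalence (the conservative upper bound used for the foundress
#' prevalence `J`).
#'
#' @param records Data frame with columns `colony_id`, `alates_sampled`,
#'   `alates_with_roach` (and optionally `site`).
#' @return List with `V_field` (infected colonies / colonies),
#'   `per_colony_prevalence` (data frame `colony_id`, `prevalence`),
#'   `J_max`, and `totals` (`colonies`, `infected_colonies`, `alates`,
#'   `roaches`).
#' @examples
#' sv <- data.frame(colony_id = 1:2, alates_sampled = c(719, 500),
#'                  alates_with_roach = c(50, 0))
#' survey_summary(sv)
#' @export
survey_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("'records' must be a nonempty data frame", call. = FALSE)
  }
  stopifnot(all(c("colony_id", "alates_sampled", "alates_with_roach") %in%
                  names(records)))
  if (any(records$alates_with_roach > records$alates_sampled) ||
      any(records$alates_with_roach < 0)) {
    stop("require 0 <= alates_with_roach <= alates_sampled", call. = FALSE)
  }
  empty <- records$alates_sampled == 0
  if (any(empty)) {
    warning(sum(empty), " colony(ies) with zero alates sampled excluded")
    records <- records[!empty, , drop = FALSE]
    if (nrow(records) == 0) stop("no colonies with sampled alates",
                                 call. = FALSE)
  }
  infected <- records$alates_with_roach > 0
  prev <- records$alates_with_roach / records$alates_sampled
  list(
    V_field = mean(infected),
    per_colony_prevalence = data.frame(colony_id = records$colony_id,
                                       prevalence = prev),
    J_max = max(prev),
    totals = list(colonies = nrow(records),
                  infected_colonies = sum(infected),
                  alates = sum(records$alates_sampled),
                  roaches = sum(records$alates_with_roach))
  )
}
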