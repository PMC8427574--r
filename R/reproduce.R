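#' Run the full vertical-transmission ceiling analysis
#'
#' Ties the stages together: obtain the virulence ratio `delta` (directly,
#' or by fitting the survivorship experiment), the foundress prevalence `J`
#' and field mature-colony prevalence `V_field` (directly, or from a survey
#' table), evaluate the equilibrium prevalence under the estimated `delta`
#' and under a neutral symbiont (`delta = 1`), and compare both with the
#' field prevalence. Every number in the report carries its provenance
#' (`config`, `computed`, or `default`).
#'
#' Defaults are the analysis's conservative choices: perfect symbiont
#' persistence (`z = 1`), the maximum observed alate prevalence as `J`
#' (0.07), and a field prevalence of 0.73.
#'
#' @param delta Virulence ratio; omit to fit from `survival_records`.
#' @param survival_records Data frame of survival records (or a CSV path);
#'   used to fit `delta` when `delta` is missing.
#' @param endpoint Endpoint definition for the fit (see
#'   [endpoint_events()]).
#' @param ties_method Ties correction for the fit (see [cox_fit()]).
#' @param use_frailty Include a nest-within-flight gamma frailty term when
#'   fitting (default `TRUE`).
#' @param J Foundress infection prevalence; omit to take `J_max` from
#'   `survey_records`.
#' @param z Symbiont persistence probability (default 1, conservative).
#' @param V_field Field mature-colony prevalence; omit to take it from
#'   `survey_records`.
#' @param survey_records Data frame of survey records (or a CSV path).
#' @return An object of class `reproduction_report`: list with `delta_lab`,
#'   `delta_neutral`, `J_used`, `z_used`, `V_lab`, `V_neutral`, `V_field`,
#'   `ratio_lab`, `ratio_neutral`, `cox` (the fit, if any), and
#'   `provenance`.
#' @examples
#' run_reproduction() # conservative defaults: delta = 0.3, J = 0.07, z = 1
#' @export
run_reproduction <- function(delta = NULL, survival_records = NULL,
                             endpoint = "combined",
                             ties_method = "breslow", use_frailty = TRUE,
                             J = NULL, z = NULL, V_field = NULL,
                             survey_records = NULL) {
  prov <- list()
  cox <- NULL

  if (is.character(survival_records)) {
    survival_records <- read_survival_csv(survival_records)
  }
  if (is.character(survey_records)) {
    survey_records <- read_survey_csv(survey_records)
  }

  if (is.null(delta)) {
    if (is.null(survival_records)) {
      if (is.null(J) && is.null(survey_records) && is.null(V_field)) {
        # bare call: the conservative default analysis
        delta <- 0.3; prov$delta_lab <- "default"
      } else {
        stop("configuration error: supply 'delta' or 'survival_records'",
             call. = FALSE)
      }
    } else {
      ee <- endpoint_events(survival_records, endpoint)
      fg <- if (use_frailty) {
        interaction(survival_records$flight_id, survival_records$nest_id,
                    drop = TRUE)
      } else NULL
      cox <- cox_fit(ee$time, ee$event,
                     survival_records$treatment == "roach",
                     ties_method = ties_method, frailty_group = fg)
      delta <- cox$delta
      prov$delta_lab <- "computed"
    }
  } else {
    prov$delta_lab <- "config"
  }

  survey <- if (!is.null(survey_records)) survey_summary(survey_records)

  if (is.null(J)) {
    if (!is.null(survey)) { J <- survey$J_max; prov$J_used <- "computed" }
    else { J <- 0.07; prov$J_used <- "default" }
  } else prov$J_used <- "config"

  if (is.null(z)) { z <- 1; prov$z_used <- "default" }
  else prov$z_used <- "config"

  if (is.null(V_field)) {
    if (!is.null(survey)) {
      V_field <- survey$V_field; prov$V_field <- "computed"
    } else { V_field <- 0.73; prov$V_field <- "default" }
  } else prov$V_field <- "config"

  V_lab <- equilibrium_prevalence(delta, J, z)
  V_neutral <- equilibrium_prevalence(1, J, z)
  prov$delta_neutral <- "default"
  prov$V_lab <- "computed"; prov$V_neutral <- "computed"
  prov$ratio_lab <- "computed"; prov$ratio_neutral <- "computed"

  structure(list(
    delta_lab = delta, delta_neutral = 1, J_used = J, z_used = z,
    V_lab = V_lab, V_neutral = V_neutral, V_field = V_field,
    ratio_lab = vertical_contribution_ratio(V_lab, V_field),
    ratio_neutral = vertical_contribution_ratio(V_neutral, V_field),
    cox = cox, provenance = prov
  ), class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  src <- function(f) sprintf(" [%s]", x$provenance[[f]])
  cat("Vertical-transmission ceiling analysis\n")
  cat(sprintf("  delta (lab estimate)     = %.2f%s\n",
              x$delta_lab, src("delta_lab")))
  cat(sprintf("  delta (neutral symbiont) = %.2f%s\n",
              x$delta_neutral, src("delta_neutral")))
  cat(sprintf("  J (foundress prevalence) = %.2f%s\n", x$J_used,
              src("J_used")))
  cat(sprintf("  z (persistence)          = %.2f%s\n", x$z_used,
              src("z_used")))
  cat(sprintf("  V_field (observed)       = %.2f%s\n", x$V_field,
              src("V_field")))
  cat(sprintf("  V under lab delta        = %.2f (raw %.5f)\n",
              round(x$V_lab, 2), x$V_lab))
  cat(sprintf("  V under neutral delta    = %.2f (raw %.5f)\n",
              round(x$V_neutral, 2), x$V_neutral))
  cat(sprintf(
    "  vertical transmission accounts for at most %d%% (lab delta) or %d%% (neutral) of field prevalence\n",
    round(100 * x$ratio_lab), round(100 * x$ratio_neutral)))
  if (!is.null(x$cox)) {
    cat("\nUnderlying survivorship fit:\n")
    print(x$cox)
  }
  invisible(x)
}

#' Write a reproduction report as JSON
#'
#' @param report A `reproduction_report` from [run_reproduction()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "reproduction_report"))
  out <- report[c("delta_lab", "delta_neutral", "J_used", "z_used",
                  "V_lab", "V_neutral", "V_field", "ratio_lab",
                  "ratio_neutral")]
  out$provenance <- report$provenance
  if (!is.null(report$cox)) {
    out$cox <- report$cox[c("log_hr", "hr", "se", "wald_z", "p_value",
                            "delta", "ties_method", "frailty_variance")]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
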