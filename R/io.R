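#' Read and write the survival-experiment CSV dialect
#'
#' Columns: `chamber_id, treatment, flight_id, nest_id, day, garden_outcome,
#' foundress_died, disturbed`; booleans as `true`/`false`, `disturbed`
#' empty for control-arm rows.
#'
#' @param path File path.
#' @param records Data frame of survival records.
#' @return `read_survival_csv` returns the validated records data frame;
#'   `write_survival_csv` returns `path` invisibly.
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(disturbed = "character"))
  validate_survival_records(parse_survival_booleans(d))
}

parse_survival_booleans <- function(d) {
  to_lgl <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1")] <- TRUE
    out[x %in% c("false", "f", "0")] <- FALSE
    out
  }
  d$foundress_died <- to_lgl(d$foundress_died)
  d$disturbed <- to_lgl(d$disturbed)
  d
}

validate_survival_records <- function(d) {
  req <- c("chamber_id", "treatment", "flight_id", "nest_id", "day",
           "garden_outcome", "foundress_died", "disturbed")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("survival records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(d$day < 1)) stop("'day' must be >= 1", call. = FALSE)
  if (!all(d$treatment %in% c("roach", "no_roach"))) {
    stop("treatment must be 'roach' or 'no_roach'", call. = FALSE)
  }
  if (any(!is.na(d$disturbed) & d$treatment == "no_roach")) {
    stop("'disturbed' may be set only for roach-treatment rows",
         call. = FALSE)
  }
  if (any(d$garden_outcome == "foundress_dead" & !d$foundress_died)) {
    stop("garden_outcome 'foundress_dead' requires foundress_died = TRUE",
         call. = FALSE)
  }
  d
}

#' @rdname read_survival_csv
#' @export
write_survival_csv <- function(records, path) {
  d <- validate_survival_records(records)
  d$foundress_died <- tolower(as.character(d$foundress_died))
  d$disturbed <- ifelse(is.na(d$disturbed), "",
                        tolower(as.character(d$disturbed)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write the field-survey CSV dialect
#'
#' Columns: `colony_id, site, alates_sampled, alates_with_roach`.
#'
#' @param path File path.
#' @param records Data frame of survey records.
#' @return `read_survey_csv` returns the records data frame;
#'   `write_survey_csv` returns `path` invisibly.
#' @export
read_survey_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("colony_id", "alates_sampled", "alates_with_roach")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("survey records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(d$alates_with_roach > d$alates_sampled |
            d$alates_with_roach < 0)) {
    stop("require 0 <= alates_with_roach <= alates_sampled", call. = FALSE)
  }
  d
}

#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model-parameter JSON config
#'
#' Accepts keys `s_u`, `s_i` or `delta` (either pair or ratio, never both),
#' plus optional `z`, `q`, `J`, `F_i`, `F_u`. Returns the parsed
#' [transmission_params()] together with the auxiliary entries.
#'
#' @param path Path to a JSON file.
#' @return List with `params` (a `transmission_params`) and any of `J`,
#'   `F_i`, `F_u` present in the file.
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  has_rates <- !is.null(cfg$s_i)
  has_delta <- !is.null(cfg$delta)
  if (has_rates && has_delta) {
    stop("config may give (s_u, s_i) or delta, never both", call. = FALSE)
  }
  args <- list(z = cfg$z %||% 1, q = cfg$q %||% 0.1)
  if (has_delta) {
    args$delta <- cfg$delta
    if (!is.null(cfg$s_u)) args$s_u <- cfg$s_u
  } else {
    args$s_u <- cfg$s_u; args$s_i <- cfg$s_i
  }
  out <- list(params = do.call(transmission_params, args))
  for (nm in c("J", "F_i", "F_u")) out[[nm]] <- cfg[[nm]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
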