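`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table non-standard-evaluation columns
utils::globalVariables(c(
  ".fda", ".pid", "CASEID", "DRUGNAME", "DRUG_SEQ", "DSG_DRUG_SEQ", "OUTC_COD",
  "PRIMARYID", "PT", "ROLE_COD", "START_DT", "a", "alpha", "alpha_hi",
  "alpha_lo", "b", "bcpnn_flag", "beta", "beta_hi", "beta_lo", "caseid",
  "case", "case_version", "chi2", "code", "count", "d", "drug", "drugname",
  "drug_seq", "eb", "ebgm", "ebgm05", "ebgm_flag", "event", "event_dt",
  "failure_type", "fda", "fda_dt", "from", "ic", "ic025", "max", "median",
  "min", "n_drug", "n_event", "name", "or", "or_hi", "or_lo", "p",
  "p_adjusted", "p_raw", "primaryid", "prr", "prr_flag", "prr_hi", "prr_lo",
  "pt", "q1", "q3", "role_cod", "ror", "ror_flag", "ror_hi", "ror_lo",
  "score", "seq", "signal", "start_dt", "stratum", "term", "to", "variable",
  "version"
))

# Classed condition so callers can distinguish bad inputs from bugs; the
# offending field name travels in the condition and the message.
stop_invalid <- function(field, msg, class = "pvkit_validation_error") {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg),
         call = sys.call(-1), field = field)
  )
  stop(cond)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_invalid(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

norm_name <- function(x) toupper(trimws(x))

#' Parse dates in the FAERS numeric dialect
#'
#' FAERS date fields carry `YYYYMMDD`, `YYYYMM`, or `YYYY` strings. Under the
#' default `"strict_day"` policy only full `YYYYMMDD` values parse; partial
#' dates become `NA` (day resolution is required for time-to-onset work).
#' `"pad_first"` pads partial dates to the first day of the month / year.
#'
#' @param x character (or numeric) vector of raw date fields.
#' @param policy `"strict_day"` (default) or `"pad_first"`.
#' @return a `Date` vector; unparseable values are `NA`, never an error.
#' @export
parse_faers_date <- function(x, policy = c("strict_day", "pad_first")) {
  policy <- match.arg(policy)
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  if (policy == "pad_first") {
    ym <- !is.na(x) & grepl("^[0-9]{6}$", x)
    out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
    yy <- !is.na(x) & grepl("^[0-9]{4}$", x)
    out[yy] <- as.Date(paste0(x[yy], "0101"), format = "%Y%m%d")
  }
  out
}

format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
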