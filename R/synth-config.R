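#' Default demographic mix for the report generator
#'
#' Categorical distributions for sex, age and weight, each with an explicit
#' missingness probability. The defaults emulate the large "unknown" fractions
#' typical of spontaneous-report databases: roughly 10% of reports lack sex,
#' 40% lack age and 50% lack weight, with observed ages concentrated in the
#' 18–65 band and observed weights in the 50–100 kg band. Ages and weights are
#' drawn uniformly within their bin.
#'
#' @return a list with components `sex` (named probabilities over
#'   male/female), `sex_missing`, `age_breaks`/`age_probs`/`age_missing`
#'   (years), `weight_breaks`/`weight_probs`/`weight_missing` (kg).
#' @export
default_demographic_mix <- function() {
  list(
    sex = c(male = 0.47, female = 0.43), sex_missing = 0.10,
    age_breaks = c(0, 18, 65, 85, 100),
    age_probs = c(0.02, 0.90, 0.07, 0.01), age_missing = 0.40,
    weight_breaks = c(30, 50, 80, 100, 160),
    weight_probs = c(0.05, 0.45, 0.30, 0.20), weight_missing = 0.50
  )
}

#' Configure a synthetic spontaneous-report dataset
#'
#' Describes the generative world for [simulate_faers()]: vocabulary sizes,
#' a background reporting rate, a planted rate-ratio matrix, demographic
#' distributions with missingness, Weibull time-to-onset parameters,
#' duplicate-version emission and covariate effects on the log-odds of event
#' occurrence.
#'
#' @param n_cases number of unique cases (case ids) to generate; `0` gives an
#'   empty dataset.
#' @param drugs either a count or a character vector of drug names.
#' @param events either a count or a character vector of MedDRA-style
#'   preferred terms.
#' @param background_rate probability that a report mentions a given event in
#'   the absence of signal.
#' @param signal_matrix `n_drugs x n_events` matrix of true reporting-rate
#'   ratios (>= 0); default all 1 (no signal). The ratio multiplies the
#'   background reporting odds: for a report whose primary-suspect drug is
#'   `d`, event probability is
#'   `plogis(qlogis(background_rate) + log(signal_matrix[d, e]))`, further
#'   shifted on the log-odds scale by `risk_effects`. The planted ratio is
#'   therefore exactly the reporting odds ratio the disproportionality stage
#'   estimates; for rare events it is indistinguishable from multiplying the
#'   probability itself.
#' @param demographic_mix see [default_demographic_mix()].
#' @param tto_params default Weibull latency `list(scale_days, shape)` used
#'   for every (drug, event) pair; days from therapy start to event onset.
#' @param tto_overrides optional named list of per-pair overrides, keyed
#'   `"DRUG|EVENT"`, each a `list(scale_days, shape)`.
#' @param duplicate_rate probability that a case is re-emitted as a second,
#'   later version (a literal duplicate with a new primary id, a higher case
#'   version and a later receipt date).
#' @param concomitant_mean Poisson mean of the number of concomitant (role C)
#'   drugs added to each report.
#' @param risk_effects named numeric vector of log-odds effects applied to
#'   event occurrence; recognised names are `"sex_female"`, `"age_le65"`,
#'   `"weight_gt80"`. Effects use the true (pre-masking) covariate values.
#' @param start_window character vector of two `YYYYMMDD` dates bounding the
#'   therapy start dates.
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of the config.
#' @return a validated object of class `"sim_config"`.
#' @export
sim_config <- function(n_cases,
                       drugs = 10,
                       events = 20,
                       background_rate = 0.01,
                       signal_matrix = NULL,
                       demographic_mix = default_demographic_mix(),
                       tto_params = list(scale_days = 900, shape = 1),
                       tto_overrides = list(),
                       duplicate_rate = 0.1,
                       concomitant_mean = 1,
                       risk_effects = numeric(0),
                       start_window = c("20040101", "20240401"),
                       seed = 1L) {
  check_count(n_cases, "n_cases", min = 0L)
  if (is.numeric(drugs) && length(drugs) == 1L) {
    check_count(drugs, "n_drugs")
    drugs <- sprintf("DRUG_%02d", seq_len(drugs))
  }
  if (is.numeric(events) && length(events) == 1L) {
    check_count(events, "n_events")
    events <- sprintf("PT_%03d", seq_len(events))
  }
  drugs <- norm_name(drugs); events <- norm_name(events)
  if (anyDuplicated(drugs)) stop_invalid("drugs", "names must be unique")
  if (anyDuplicated(events)) stop_invalid("events", "names must be unique")
  check_prob(background_rate, "background_rate")
  if (is.null(signal_matrix)) {
    signal_matrix <- matrix(1, length(drugs), length(events),
                            dimnames = list(drugs, events))
  }
  if (!is.matrix(signal_matrix) ||
      nrow(signal_matrix) != length(drugs) ||
      ncol(signal_matrix) != length(events))
    stop_invalid("signal_matrix", "must be an n_drugs x n_events matrix")
  if (any(!is.finite(signal_matrix)) || any(signal_matrix < 0))
    stop_invalid("signal_matrix", "rate ratios must be finite and >= 0")
  dimnames(signal_matrix) <- list(drugs, events)

  mix <- demographic_mix
  check_prob(mix$sex_missing, "demographic_mix$sex_missing")
  if (abs(sum(mix$sex) + mix$sex_missing - 1) > 1e-8)
    stop_invalid("demographic_mix$sex",
                 "sex probabilities plus sex_missing must sum to 1")
  for (f in c("age", "weight")) {
    p <- mix[[paste0(f, "_probs")]]; br <- mix[[paste0(f, "_breaks")]]
    check_prob(mix[[paste0(f, "_missing")]], paste0("demographic_mix$", f, "_missing"))
    if (length(br) != length(p) + 1L || is.unsorted(br, strictly = TRUE))
      stop_invalid(paste0("demographic_mix$", f, "_breaks"),
                   "breaks must be strictly increasing with length(probs) + 1")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_invalid(paste0("demographic_mix$", f, "_probs"),
                   "bin probabilities must be non-negative and sum to 1")
  }

  check_weibull <- function(w, field) {
    if (!is.list(w) || !is.numeric(w$scale_days) || !is.numeric(w$shape) ||
        w$scale_days <= 0 || w$shape <= 0)
      stop_invalid(field, "needs scale_days > 0 and shape > 0")
  }
  check_weibull(tto_params, "tto_params")
  for (k in names(tto_overrides)) check_weibull(tto_overrides[[k]], paste0("tto_overrides$", k))
  check_prob(duplicate_rate, "duplicate_rate")
  if (!is.numeric(concomitant_mean) || concomitant_mean < 0)
    stop_invalid("concomitant_mean", "must be >= 0")
  if (length(risk_effects)) {
    allowed <- c("sex_female", "age_le65", "weight_gt80")
    if (is.null(names(risk_effects)) || !all(names(risk_effects) %in% allowed))
      stop_invalid("risk_effects",
                   paste("names must be among:", paste(allowed, collapse = ", ")))
  }
  if (length(start_window) != 2L ||
      any(is.na(parse_faers_date(start_window))))
    stop_invalid("start_window", "must be two YYYYMMDD dates")
  check_count(seed, "seed", min = -.Machine$integer.max)

  structure(
    list(n_cases = as.integer(n_cases), drugs = drugs, events = events,
         background_rate = background_rate, signal_matrix = signal_matrix,
         demographic_mix = mix, tto_params = tto_params,
         tto_overrides = tto_overrides, duplicate_rate = duplicate_rate,
         concomitant_mean = concomitant_mean, risk_effects = risk_effects,
         start_window = start_window, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cases, "cases,", length(x$drugs), "drugs,",
      length(x$events), "events\n")
  cat("  background rate", x$background_rate,
      "| planted pairs:", sum(x$signal_matrix != 1), "\n")
  invisible(x)
}
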