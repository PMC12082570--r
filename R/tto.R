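#' Compute time-to-onset for a drug's event reports
#'
#' Time-to-onset is the number of days between event onset (`EVENT_DT`) and
#' the initiation of therapy with the primary-suspect drug (`START_DT`); when
#' the drug has several therapy episodes the earliest dated start anchors the
#' latency. Reports with either date missing are excluded and counted in
#' `n_excluded_missing`; differences <= 0 days are excluded and counted in
#' `n_excluded_nonpositive`.
#'
#' @param fd a deduplicated `"faers_data"`.
#' @param drug target drug (primary-suspect role).
#' @param event_flags optional logical vector in report order restricting to
#'   target-event reports; default all PS reports of the drug.
#' @return class `"pv_tto"`: `values` (positive day counts),
#'   `n_excluded_missing`, `n_excluded_nonpositive`, `drug`.
#' @export
compute_tto <- function(fd, drug, event_flags = NULL) {
  stopifnot(inherits(fd, "faers_data"))
  ids <- ps_report_ids(fd, drug)
  if (!is.null(event_flags)) {
    stopifnot(length(event_flags) == nrow(fd$reports))
    ids <- intersect(ids, fd$reports$primaryid[event_flags])
  }
  starts <- fd$drugs[primaryid %in% ids & role_cod == "PS" &
                       norm_name(drugname) == norm_name(drug),
                     .(start_dt = suppressWarnings(min(start_dt, na.rm = TRUE))),
                     by = primaryid]
  starts[is.infinite(as.numeric(start_dt)), start_dt := as.Date(NA)]
  rep_sub <- fd$reports[primaryid %in% ids, .(primaryid, event_dt)]
  m <- merge(rep_sub, starts, by = "primaryid", all.x = TRUE)
  tto <- as.numeric(m$event_dt - m$start_dt)
  n_missing <- sum(is.na(tto))
  n_nonpos <- sum(!is.na(tto) & tto <= 0)
  structure(list(values = tto[!is.na(tto) & tto > 0],
                 n_excluded_missing = n_missing,
                 n_excluded_nonpositive = n_nonpos,
                 drug = norm_name(drug)),
            class = "pv_tto")
}

#' @export
print.pv_tto <- function(x, ...) {
  cat("<pv_tto>", length(x$values), "onsets for", x$drug,
      sprintf("(excluded: %d missing, %d non-positive)\n",
              x$n_excluded_missing, x$n_excluded_nonpositive))
  invisible(x)
}

as_tto_values <- function(s) {
  if (inherits(s, "pv_tto")) return(s$values)
  stopifnot(is.numeric(s), all(s > 0))
  s
}

#' Summarize a time-to-onset sample
#'
#' Median and quartiles use the linear-interpolation convention (R quantile
#' type 7); min and max are exact.
#'
#' @param s a [compute_tto()] result or a positive numeric vector.
#' @return a list with `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_tto <- function(s) {
  x <- as_tto_values(s)
  if (!length(x)) stop("empty time-to-onset sample")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       min = min(x), max = max(x))
}

# profile log-likelihood machinery: for fixed shape b the scale MLE is
# (mean(x^b))^(1/b); the profiled score in b is
#   1/b + mean(log x) - sum(x^b log x)/sum(x^b)
# which is strictly decreasing, so a sign-bracketed uniroot is deterministic.
weibull_profile_score <- function(b, logx, x) {
  xb <- exp(b * logx)
  1 / b + mean(logx) - sum(xb * logx) / sum(xb)
}

weibull_negloglik <- function(par, x) {
  # par = (log alpha, log beta)
  al <- exp(par[1]); be <- exp(par[2])
  -(length(x) * (log(be) - be * log(al)) + (be - 1) * sum(log(x)) -
      sum((x / al)^be))
}

#' Fit a two-parameter Weibull to uncensored onset times
#'
#' Maximum likelihood via a profiled shape parameter: the scale has a closed
#' form given the shape, and the one-dimensional profiled score equation is
#' solved by deterministic bisection-based root finding, bracketed around a
#' method-of-moments start. 95% confidence intervals are Wald intervals on
#' the log-parameters using the observed information at the MLE. The
#' resulting shape interval drives the hazard classification (see
#' [classify_failure()]).
#'
#' @param s a [compute_tto()] result or positive numeric vector (days).
#' @param min_n soft floor on the sample size; below it the fit is still
#'   returned with a warning.
#' @param conf_level interval coverage for the Wald intervals.
#' @return class `"pv_weibull_fit"`: `alpha` (scale, days), `beta` (shape),
#'   `alpha_ci95`, `beta_ci95`, `failure_type`, `loglik`, the sample summary
#'   and `n`.
#' @export
fit_weibull <- function(s, min_n = 30, conf_level = 0.95) {
  x <- as_tto_values(s)
  n <- length(x)
  if (n < 2L) stop("need at least 2 onset times to fit a Weibull")
  if (n < min_n)
    warning(sprintf("only %d onset times (< %d); Weibull fit is unstable", n, min_n))
  # scale out the geometric mean for numerical range, restored afterwards
  gm <- exp(mean(log(x)))
  y <- x / gm
  logy <- log(y)
  if (all(abs(logy) < 1e-12)) stop("degenerate sample: all onset times equal")

  # method-of-moments start: shape from the CV of the sample
  cv <- stats::sd(x) / mean(x)
  b0 <- max(min(cv^(-1.086), 50), 0.05)
  lo <- b0; hi <- b0
  f_lo <- weibull_profile_score(lo, logy, y)
  tries <- 0L
  while (f_lo < 0 && tries < 60L) { lo <- lo / 1.5; f_lo <- weibull_profile_score(lo, logy, y); tries <- tries + 1L }
  f_hi <- weibull_profile_score(hi, logy, y)
  while (f_hi > 0 && tries < 120L) { hi <- hi * 1.5; f_hi <- weibull_profile_score(hi, logy, y); tries <- tries + 1L }
  if (f_lo < 0 || f_hi > 0)
    stop("Weibull MLE failed to bracket the profiled score ",
         sprintf("(start %.3f, lo %.3g, hi %.3g after %d expansions)", b0, lo, hi, tries))
  root <- stats::uniroot(weibull_profile_score, c(lo, hi), logx = logy, x = y,
                         tol = 1e-10)
  beta <- root$root
  alpha <- gm * mean(y^beta)^(1 / beta)

  par <- c(log(alpha), log(beta))
  H <- optimHess(par, weibull_negloglik, x = x)
  se <- sqrt(diag(solve(H)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  alpha_ci <- exp(par[1] + c(-1, 1) * z * se[1])
  beta_ci <- exp(par[2] + c(-1, 1) * z * se[2])

  summ <- summarize_tto(x)
  structure(
    list(alpha = alpha, beta = beta,
         alpha_ci95 = alpha_ci, beta_ci95 = beta_ci,
         se_log = se, n = n,
         loglik = -weibull_negloglik(par, x),
         failure_type = classify_failure(beta, beta_ci[1], beta_ci[2]),
         median = summ$median, q1 = summ$q1, q3 = summ$q3,
         min = summ$min, max = summ$max,
         drug = if (inherits(s, "pv_tto")) s$drug else NA_character_),
    class = "pv_weibull_fit"
  )
}

#' @export
print.pv_weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull fit> n=%d  alpha=%.2f (%.2f-%.2f)  beta=%.3f (%.3f-%.3f)\n",
              x$n, x$alpha, x$alpha_ci95[1], x$alpha_ci95[2],
              x$beta, x$beta_ci95[1], x$beta_ci95[2]))
  cat("  hazard over time:", gsub("_", "-", x$failure_type), "failure type;",
      sprintf("median TTO %.0f days (IQR %.0f-%.0f)\n", x$median, x$q1, x$q3))
  invisible(x)
}

#' Classify the hazard shape from the Weibull shape parameter
#'
#' Wear-out failure (risk increasing over time) when `beta > 1` with the
#' whole 95% interval above 1; early failure (risk decreasing) when
#' `beta < 1` with the whole interval below 1; random failure (roughly
#' constant hazard) otherwise, i.e. whenever the interval spans 1.
#'
#' @param beta shape estimate, or a `"pv_weibull_fit"`.
#' @param lower,upper the 95% interval bounds (ignored when a fit is given).
#' @return one of `"early"`, `"random"`, `"wear_out"`.
#' @export
classify_failure <- function(beta, lower = NULL, upper = NULL) {
  if (inherits(beta, "pv_weibull_fit")) {
    lower <- beta$beta_ci95[1]; upper <- beta$beta_ci95[2]; beta <- beta$beta
  }
  stopifnot(is.numeric(beta), is.numeric(lower), is.numeric(upper),
            lower <= upper)
  if (beta > 1 && lower > 1) "wear_out"
  else if (beta < 1 && upper < 1) "early"
  else "random"
}
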