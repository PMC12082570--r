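#' Prior pseudo-counts for the BCPNN information component
#'
#' Defaults are the standard non-informative choice: `alpha1 = beta1 =
#' gamma11 = 1`, `alpha = beta = 2`.
#'
#' @param alpha1,beta1,gamma11 marginal and joint prior pseudo-counts.
#' @param alpha,beta prior totals.
#' @return class `"bcpnn_priors"`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, gamma11 = 1, alpha = 2, beta = 2) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, gamma11 = gamma11,
            alpha = alpha, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("priors", "all prior pseudo-counts must be strictly positive")
  structure(as.list(vals), class = "bcpnn_priors")
}

#' Joint signal criteria thresholds
#'
#' Defaults follow the conventional four-algorithm standard: ROR requires
#' `a >= 3` and lower 95% CI > 1; PRR requires `PRR >= 2`, `chi2 >= 4`,
#' `a >= 3`; BCPNN requires `a >= 3` and `IC025 > 0`; EBGM requires `a > 0`
#' and `EBGM05 > 2`. A pair is a signal iff all four flags hold.
#'
#' @param ror_min_a,ror_ci_gt,prr_min,chi2_min,prr_min_a,bcpnn_min_a,
#'   ic025_gt,ebgm_min_a,ebgm05_gt the individual cutoffs.
#' @return class `"signal_thresholds"`.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_ci_gt = 1,
                              prr_min = 2, chi2_min = 4, prr_min_a = 3,
                              bcpnn_min_a = 3, ic025_gt = 0,
                              ebgm_min_a = 1, ebgm05_gt = 2) {
  structure(list(ror_min_a = ror_min_a, ror_ci_gt = ror_ci_gt,
                 prr_min = prr_min, chi2_min = chi2_min, prr_min_a = prr_min_a,
                 bcpnn_min_a = bcpnn_min_a, ic025_gt = ic025_gt,
                 ebgm_min_a = ebgm_min_a, ebgm05_gt = ebgm05_gt),
            class = "signal_thresholds")
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Within the (optionally filtered) report universe: `a` = reports with the
#' target drug (primary-suspect role) and the target event; `b` = target
#' drug, other events; `c` = other drugs, target event; `d` = neither.
#'
#' @param fd a deduplicated `"faers_data"`.
#' @param drug target drug name (PS role, case-insensitive exact match).
#' @param event_flags logical vector in report order (e.g. from
#'   [flag_event_cases()]).
#' @param stratum optional logical vector in report order restricting the
#'   universe; an all-`FALSE` stratum yields a table of zeros.
#' @return class `"pv_contingency"`: list with `a`, `b`, `c`, `d`, `n`.
#' @export
build_table <- function(fd, drug, event_flags, stratum = NULL) {
  stopifnot(inherits(fd, "faers_data"),
            length(event_flags) == nrow(fd$reports))
  in_univ <- if (is.null(stratum)) rep(TRUE, nrow(fd$reports)) else stratum
  stopifnot(length(in_univ) == nrow(fd$reports))
  has_drug <- fd$reports$primaryid %in% ps_report_ids(fd, drug)
  a <- sum(in_univ & has_drug & event_flags)
  b <- sum(in_univ & has_drug & !event_flags)
  cc <- sum(in_univ & !has_drug & event_flags)
  d <- sum(in_univ & !has_drug & !event_flags)
  contingency_table(a, b, cc, d, drug = drug)
}

#' @rdname build_table
#' @param a,b,c,d the four cell counts (non-negative integers).
#' @param event optional event label.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop_invalid("cells", "a, b, c, d must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 drug = drug, event = event),
            class = "pv_contingency")
}

#' @export
print.pv_contingency <- function(x, ...) {
  cat(sprintf("<2x2> a=%d b=%d c=%d d=%d (N=%d)\n", x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' All four disproportionality statistics, vectorized over tables
#'
#' Computes, per table: the reporting odds ratio `ROR = ad/(bc)` with
#' `exp(log ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))` interval; the proportional
#' reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with
#' `exp(log PRR +/- 1.96*sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))` interval and the
#' Pearson statistic `chi2 = (ad-bc)^2 N /[(a+b)(c+d)(a+c)(b+d)]` (1 df upper
#' tail gives `p_raw`); the BCPNN information component `E(IC)` with its
#' `IC025 = E(IC) - 2*sqrt(V(IC))` lower bound; and the relative reporting
#' ratio `EBGM = aN/[(a+c)(a+b)]` with the one-sided lower bound
#' `EBGM05 = exp(log EBGM - 1.64*sqrt(1/a+1/b+1/c+1/d))`.
#'
#' When any cell of a table is zero, a Haldane–Anscombe 0.5 continuity
#' correction is applied to all four cells for the ROR, PRR and EBGM point
#' and interval computations (the BCPNN is regularized by its priors and the
#' chi-square uses the raw cells); such rows are flagged `zero_corrected`.
#' Tables with an empty margin get `chi2 = 0`, `p_raw = 1`.
#'
#' @param a,b,c,d equal-length numeric vectors of cell counts.
#' @param priors a [bcpnn_priors()].
#' @return a `data.table`, one row per table: cells, `ror`, `ror_lo`,
#'   `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `p_raw`, `ic`, `ic025`,
#'   `ebgm`, `ebgm05`, `zero_corrected`.
#' @export
disprop_stats <- function(a, b, c, d, priors = bcpnn_priors()) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  # doubles throughout: the chi-square denominator overflows 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  zc <- a == 0 | b == 0 | c == 0 | d == 0
  a_ <- a + 0.5 * zc; b_ <- b + 0.5 * zc; c_ <- c + 0.5 * zc; d_ <- d + 0.5 * zc
  n_ <- a_ + b_ + c_ + d_

  se_or <- sqrt(1 / a_ + 1 / b_ + 1 / c_ + 1 / d_)
  ror <- a_ * d_ / (b_ * c_)
  ror_lo <- exp(log(ror) - 1.96 * se_or)
  ror_hi <- exp(log(ror) + 1.96 * se_or)

  prr <- (a_ / (a_ + b_)) / (c_ / (c_ + d_))
  se_prr <- sqrt(pmax(1 / a_ - 1 / (a_ + b_) + 1 / c_ - 1 / (c_ + d_), 0))
  prr_lo <- exp(log(prr) - 1.96 * se_prr)
  prr_hi <- exp(log(prr) + 1.96 * se_prr)

  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, (a * d - b * c)^2 * n / denom, 0)
  p_raw <- ifelse(denom > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)

  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gam) * (a + b + a1) * (a + c + b1)))
  vic <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
            (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
            (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  ic025 <- ic - 2 * sqrt(vic)

  ebgm <- a_ * n_ / ((a_ + c_) * (a_ + b_))
  ebgm05 <- exp(log(ebgm) - 1.64 * se_or)

  data.table(a = a, b = b, c = c, d = d, n = n,
             ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
             prr = prr, prr_lo = prr_lo, prr_hi = prr_hi,
             chi2 = chi2, p_raw = p_raw,
             ic = ic, ic025 = ic025, ebgm = ebgm, ebgm05 = ebgm05,
             zero_corrected = zc)
}

#' @rdname disprop_stats
#' @param t a `"pv_contingency"`.
#' @return for the single-table wrappers: a list with `point` and `ci95`
#'   (plus `chi2` for [prr_stat()], `ic`/`ic025` for [bcpnn_stat()],
#'   `ebgm`/`ebgm05` for [ebgm_stat()]).
#' @export
ror_stat <- function(t) {
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(point = s$ror, ci95 = c(s$ror_lo, s$ror_hi),
       zero_corrected = s$zero_corrected)
}

#' @rdname disprop_stats
#' @export
prr_stat <- function(t) {
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(point = s$prr, ci95 = c(s$prr_lo, s$prr_hi), chi2 = s$chi2,
       p_raw = s$p_raw, zero_corrected = s$zero_corrected)
}

#' @rdname disprop_stats
#' @export
bcpnn_stat <- function(t, priors = bcpnn_priors()) {
  s <- disprop_stats(t$a, t$b, t$c, t$d, priors)
  list(ic = s$ic, ic025 = s$ic025)
}

#' @rdname disprop_stats
#' @export
ebgm_stat <- function(t) {
  s <- disprop_stats(t$a, t$b, t$c, t$d)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, zero_corrected = s$zero_corrected)
}

#' Apply the joint signal criteria
#'
#' @param stats a [disprop_stats()] row set (any number of rows).
#' @param thresholds a [signal_thresholds()].
#' @return the input with logical columns `ror_flag`, `prr_flag`,
#'   `bcpnn_flag`, `ebgm_flag` and `signal` (the conjunction) appended.
#' @export
signal_decision <- function(stats, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  s <- copy(as.data.table(stats))
  th <- thresholds
  s[, ror_flag := a >= th$ror_min_a & ror_lo > th$ror_ci_gt]
  s[, prr_flag := prr >= th$prr_min & chi2 >= th$chi2_min & a >= th$prr_min_a]
  s[, bcpnn_flag := a >= th$bcpnn_min_a & ic025 > th$ic025_gt]
  s[, ebgm_flag := a >= th$ebgm_min_a & ebgm05 > th$ebgm05_gt]
  s[, signal := ror_flag & prr_flag & bcpnn_flag & ebgm_flag]
  s[]
}

#' Multiplicity adjustment across a run's drug-event pairs
#'
#' @param results a data.frame/data.table with a `p_raw` column.
#' @param method `"BH"` (Benjamini–Hochberg, default) or `"bonferroni"`.
#' @return the input with `p_adjusted` added/replaced.
#' @export
adjust_pvalues <- function(results, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  r <- copy(as.data.table(results))
  r[, p_adjusted := p.adjust(p_raw, method = method)]
  r[]
}

#' Scan all (or selected) drug-event pairs for signals
#'
#' Counts PS reports per drug and reaction reports per preferred term with a
#' single pass of joins, evaluates all four algorithms on every pair, applies
#' the joint criteria, and adjusts p-values across the scanned pairs. Passing
#' an [smq_definition()] instead of `events` scans one composite event (the
#' SMQ scope) per drug.
#'
#' @param fd a deduplicated `"faers_data"`.
#' @param drugs drugs to scan; default all drugs appearing with role PS.
#' @param events preferred terms to scan; default all observed PTs. Ignored
#'   when `smq` is given.
#' @param smq optional [smq_definition()].
#' @param scope SMQ scope when `smq` is given.
#' @param priors,thresholds,adjust_method see [disprop_stats()],
#'   [signal_decision()], [adjust_pvalues()].
#' @return a `data.table` of signal results, one row per pair, ordered by
#'   descending `ror`.
#' @export
scan_signals <- function(fd, drugs = NULL, events = NULL, smq = NULL,
                         scope = "narrow", priors = bcpnn_priors(),
                         thresholds = signal_thresholds(),
                         adjust_method = "BH") {
  stopifnot(inherits(fd, "faers_data"))
  n_total <- nrow(fd$reports)
  ps <- unique(fd$drugs[role_cod == "PS",
                        .(primaryid, drug = norm_name(drugname))])
  if (!is.null(drugs)) ps <- ps[drug %in% norm_name(drugs)]
  drug_n <- ps[, .(n_drug = .N), by = drug]

  if (!is.null(smq)) {
    flags <- flag_event_cases(fd, smq, scope)
    ev <- data.table(primaryid = fd$reports$primaryid[flags],
                     event = paste0(smq$name, " (", scope, ")"))
  } else {
    ev <- unique(fd$reactions[, .(primaryid, event = norm_name(pt))])
    if (!is.null(events)) ev <- ev[event %in% norm_name(events)]
  }
  event_n <- ev[, .(n_event = .N), by = event]

  a_tab <- merge(ps, ev, by = "primaryid",
                 allow.cartesian = TRUE)[, .(a = .N), by = .(drug, event)]
  grid <- CJ(drug = drug_n$drug, event = event_n$event)
  grid <- merge(grid, a_tab, by = c("drug", "event"), all.x = TRUE)
  grid[is.na(a), a := 0L]
  grid <- merge(grid, drug_n, by = "drug")
  grid <- merge(grid, event_n, by = "event")
  grid[, b := n_drug - a]
  grid[, c := n_event - a]
  grid[, d := n_total - a - b - c]

  stats <- disprop_stats(grid$a, grid$b, grid$c, grid$d, priors)
  res <- cbind(grid[, .(drug, event)], stats)
  res <- signal_decision(res, thresholds)
  res <- adjust_pvalues(res, adjust_method)
  setorder(res, -ror)
  res[]
}

#' Default demographic stratification scheme
#'
#' Sex (male / female), age at 65 years and weight at 80 kg, each variable
#' split into two half-open bins `(lo, hi]`.
#'
#' @param age_cut,weight_cut bin boundaries.
#' @return a named list of stratum specifications for [stratified_scan()].
#' @export
default_strata <- function(age_cut = 65, weight_cut = 80) {
  list(
    sex = list(var = "sex", bins = list(male = "male", female = "female")),
    age = list(var = "age_years",
               bins = list("age<=65" = c(-Inf, age_cut),
                           "age>65" = c(age_cut, Inf))),
    weight = list(var = "weight_kg",
                  bins = list("weight<=80" = c(-Inf, weight_cut),
                              "weight>80" = c(weight_cut, Inf)))
  )
}

#' Stratified signal scan for one drug
#'
#' Re-evaluates the four algorithms within demographic strata. For each
#' stratification variable, reports with that variable missing are excluded
#' from that stratification only (they stay in every other one). Numeric bins
#' are half-open intervals `(lo, hi]` and must be disjoint.
#'
#' @param fd a deduplicated `"faers_data"`.
#' @param drug target drug.
#' @param event_flags logical event flags in report order.
#' @param strata a specification as produced by [default_strata()].
#' @param priors,thresholds,adjust_method as in [scan_signals()].
#' @return a `data.table` with one row per stratum (plus an `"overall"` row),
#'   carrying the cells, statistics, flags and adjusted p-values.
#' @export
stratified_scan <- function(fd, drug, event_flags, strata = default_strata(),
                            priors = bcpnn_priors(),
                            thresholds = signal_thresholds(),
                            adjust_method = "BH") {
  stopifnot(inherits(fd, "faers_data"))
  rows <- list()
  tab <- build_table(fd, drug, event_flags)
  rows[["overall"]] <- c(variable = "overall", stratum = "overall",
                         as.list(tab[c("a", "b", "c", "d")]))
  for (sv in names(strata)) {
    spec <- strata[[sv]]
    vals <- fd$reports[[spec$var]]
    bins <- spec$bins
    numeric_bins <- vapply(bins, is.numeric, logical(1))
    if (all(numeric_bins) && length(bins) > 1) {
      iv <- do.call(rbind, bins)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping bins in stratum spec '", sv, "'")
    }
    for (bn in names(bins)) {
      b <- bins[[bn]]
      member <- if (is.numeric(b)) !is.na(vals) & vals > b[1] & vals <= b[2]
                else !is.na(vals) & vals %in% b
      tab <- build_table(fd, drug, event_flags, stratum = member)
      rows[[paste(sv, bn)]] <- c(variable = sv, stratum = bn,
                                 as.list(tab[c("a", "b", "c", "d")]))
    }
  }
  cells <- rbindlist(lapply(rows, as.data.table))
  stats <- disprop_stats(cells$a, cells$b, cells$c, cells$d, priors)
  res <- cbind(cells[, .(variable, stratum)], stats)
  res <- signal_decision(res, thresholds)
  res <- adjust_pvalues(res, adjust_method)
  res[, drug := norm_name(drug)]
  res[]
}
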