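#' Simulate a spontaneous-report dataset with known ground truth
#'
#' Draws a FAERS-dialect dataset from a [sim_config()]. Each case gets one
#' primary-suspect (PS) drug (uniform over the vocabulary) plus a Poisson
#' number of concomitant (role C) drugs; event indicators are Bernoulli, the
#' planted rate ratio multiplying the background reporting odds for the
#' case's PS drug, with `risk_effects` shifting the same log-odds scale. Reports with at least one
#' event get an event date equal to therapy start plus a Weibull latency
#' (whole days, at least 1) drawn from the (PS drug, first reported event)
#' pair's parameters; reports without events carry no event date. With
#' probability `duplicate_rate` a case is re-emitted verbatim under a new
#' primary id, case version 2 and a strictly later receipt date.
#'
#' Draw order is part of the contract (same seed, same config, byte-identical
#' output): sex, age bin, age value, age missingness, weight bin, weight
#' value, weight missingness, country, reporter occupation, PS drug,
#' concomitant counts, concomitant names, therapy start, event matrix
#' (column-major), latencies, receipt-date offsets, outcome counts, outcome
#' codes, duplicate mask, duplicate receipt offsets.
#'
#' @param config a [sim_config()].
#' @return an object of class `"synthetic_faers"`: list with the five record
#'   tables (`demo`, `drug`, `reac`, `ther`, `outc`, all `data.table`s of
#'   character columns in the FAERS dialect) and `truth`, itself a list with
#'   `reports` (one row per case: true demographics, missingness masks, PS
#'   drug, dates, planted latency, and the primary id that deduplication must
#'   retain), `event_matrix` (cases x events logical) and `config`.
#' @seealso [write_faers_tables()], [as_case_reports()]
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  mix <- config$demographic_mix
  drugs <- config$drugs
  events <- config$events
  ne <- length(events)

  caseid <- sprintf("%d", 10000000L + seq_len(n))

  if (n > 0L) {
    sex <- sample(c(names(mix$sex), "unknown"), n, TRUE,
                  c(mix$sex, mix$sex_missing))
    abin <- sample.int(length(mix$age_probs), n, TRUE, mix$age_probs)
    age <- runif(n, mix$age_breaks[abin], mix$age_breaks[abin + 1L])
    age_miss <- runif(n) < mix$age_missing
    wbin <- sample.int(length(mix$weight_probs), n, TRUE, mix$weight_probs)
    wt <- runif(n, mix$weight_breaks[wbin], mix$weight_breaks[wbin + 1L])
    wt_miss <- runif(n) < mix$weight_missing
    country <- sample(c("US", "CA", "GB", "FR", "DE", "IN"), n, TRUE,
                      c(0.75, 0.05, 0.05, 0.05, 0.05, 0.05))
    occp <- sample(c("CN", "MD", "PH", "OT", "LW", "HP"), n, TRUE,
                   c(0.30, 0.20, 0.05, 0.20, 0.15, 0.10))
    ps_idx <- sample.int(length(drugs), n, TRUE)
    n_con <- rpois(n, config$concomitant_mean)
    if (length(drugs) < 2L) n_con[] <- 0L
    con_names <- if (sum(n_con) > 0L) {
      # draw concomitants per report, excluding the PS drug
      unlist(lapply(which(n_con > 0L), function(i) {
        sample(drugs[-ps_idx[i]], min(n_con[i], length(drugs) - 1L))
      }), use.names = FALSE)
    } else character(0)
    w0 <- parse_faers_date(config$start_window[1])
    w1 <- parse_faers_date(config$start_window[2])
    start_dt <- w0 + sample.int(as.integer(w1 - w0) + 1L, n, TRUE) - 1L

    # event occurrence: base probability from the planted rate-ratio matrix,
    # shifted on the log-odds scale by the true covariate values
    eta <- rep(0, n)
    re <- config$risk_effects
    if ("sex_female" %in% names(re)) eta <- eta + re[["sex_female"]] * (sex == "female")
    if ("age_le65" %in% names(re)) eta <- eta + re[["age_le65"]] * (age <= 65)
    if ("weight_gt80" %in% names(re)) eta <- eta + re[["weight_gt80"]] * (wt > 80)
    # the planted ratio multiplies the reporting odds, so it is exactly the
    # estimand of the downstream reporting odds ratio (for rare events this
    # coincides with multiplying the probability); risk effects shift the
    # same log-odds scale
    pmat <- plogis(qlogis(config$background_rate) +
                     log(config$signal_matrix[ps_idx, , drop = FALSE]) + eta)
    emat <- matrix(runif(n * ne), n, ne) < pmat
    dimnames(emat) <- list(caseid, events)

    first_ev <- apply(emat, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
    has_ev <- !is.na(first_ev)
    latency <- rep(NA_integer_, n)
    if (any(has_ev)) {
      ii <- which(has_ev)
      key <- paste0(drugs[ps_idx[ii]], "|", events[first_ev[ii]])
      ov <- config$tto_overrides
      sc <- rep(config$tto_params$scale_days, length(ii))
      sh <- rep(config$tto_params$shape, length(ii))
      if (length(ov)) {
        hit <- match(key, names(ov))
        for (j in which(!is.na(hit))) {
          sc[j] <- ov[[hit[j]]]$scale_days
          sh[j] <- ov[[hit[j]]]$shape
        }
      }
      latency[ii] <- as.integer(ceiling(rweibull(length(ii), shape = sh, scale = sc)))
    }
    event_dt <- start_dt + latency  # NA where no event
    fda_base <- ifelse(has_ev, as.integer(latency), 0L)
    fda_dt <- start_dt + fda_base + sample.int(300L, n, TRUE)

    n_outc <- sample(0:2, n, TRUE, c(0.25, 0.55, 0.20))
    outc_codes <- if (sum(n_outc) > 0L)
      sample(c("HO", "OT", "DE", "LT", "DS", "RI"), sum(n_outc), TRUE,
             c(0.35, 0.40, 0.08, 0.07, 0.05, 0.05)) else character(0)

    dup <- runif(n) < config$duplicate_rate
    dup_gap <- sample(30:400, n, TRUE)
  } else {
    sex <- character(0); age <- wt <- numeric(0)
    age_miss <- wt_miss <- dup <- logical(0)
    country <- occp <- character(0)
    ps_idx <- first_ev <- integer(0); n_con <- n_outc <- integer(0)
    con_names <- outc_codes <- character(0)
    start_dt <- event_dt <- fda_dt <- as.Date(character(0))
    latency <- integer(0); dup_gap <- integer(0)
    emat <- matrix(logical(0), 0, ne, dimnames = list(NULL, events))
    has_ev <- logical(0)
  }

  # one row per emitted version; duplicates are verbatim re-emissions with a
  # new primary id, version 2 and a strictly later receipt date
  versions <- data.table(
    case = c(seq_len(n), which(dup)),
    version = c(rep(1L, n), rep(2L, sum(dup)))
  )
  versions[, caseid := caseid[case]]
  versions[, primaryid := paste0(caseid, version)]
  versions[, fda := fda_dt[case] + (version - 1L) * dup_gap[case]]
  setorder(versions, case, version)

  i <- versions$case
  demo <- data.table(
    PRIMARYID = versions$primaryid,
    CASEID = versions$caseid,
    CASEVERSION = as.character(versions$version),
    FDA_DT = format_faers_date(versions$fda),
    EVENT_DT = format_faers_date(event_dt[i]),
    SEX = c(male = "M", female = "F", unknown = "UNK")[sex[i]],
    AGE = ifelse(age_miss[i], "", sprintf("%.0f", age[i])),
    AGE_COD = ifelse(age_miss[i], "", "YR"),
    WT = ifelse(wt_miss[i], "", sprintf("%.1f", wt[i])),
    WT_COD = ifelse(wt_miss[i], "", "KG"),
    OCCP_COD = occp[i],
    REPORTER_COUNTRY = country[i]
  )
  if (n == 0L) demo[, SEX := character(0)]

  con_case <- rep(seq_len(n), pmin(n_con, max(0L, length(drugs) - 1L)))
  drug_per_case <- data.table(
    case = c(seq_len(n), con_case),
    seq = c(rep(1L, n), if (length(con_case)) {
      unlist(lapply(rle_counts(con_case), seq_len), use.names = FALSE) + 1L
    } else integer(0)),
    role = c(rep("PS", n), rep("C", length(con_case))),
    name = c(drugs[ps_idx], con_names)
  )
  drug <- merge(versions, drug_per_case, by = "case", allow.cartesian = TRUE)
  setorder(drug, case, version, seq)
  drug_tab <- drug[, .(PRIMARYID = primaryid, CASEID = caseid,
                       DRUG_SEQ = as.character(seq), ROLE_COD = role,
                       DRUGNAME = name)]

  reac_idx <- which(emat, arr.ind = TRUE)
  reac_per_case <- data.table(case = as.integer(reac_idx[, 1L]),
                              pt = events[reac_idx[, 2L]])
  setorder(reac_per_case, case, pt)
  reac <- merge(versions, reac_per_case, by = "case", allow.cartesian = TRUE)
  setorder(reac, case, version, pt)
  reac_tab <- reac[, .(PRIMARYID = primaryid, CASEID = caseid, PT = pt)]

  ther_tab <- versions[, .(PRIMARYID = primaryid, CASEID = caseid,
                           DSG_DRUG_SEQ = "1",
                           START_DT = format_faers_date(start_dt[case]))]

  outc_per_case <- data.table(case = rep(seq_len(n), n_outc), code = outc_codes)
  outc <- merge(versions, outc_per_case, by = "case", allow.cartesian = TRUE)
  setorder(outc, case, version, code)
  outc_tab <- outc[, .(PRIMARYID = primaryid, CASEID = caseid, OUTC_COD = code)]

  truth_reports <- data.table(
    caseid = caseid,
    primaryid = paste0(caseid, ifelse(dup, 2L, 1L)),  # version dedup must keep
    n_versions = 1L + as.integer(dup),
    sex = sex, age_years = age, age_missing = age_miss,
    weight_kg = wt, weight_missing = wt_miss,
    ps_drug = drugs[ps_idx],
    start_dt = start_dt,
    first_event = ifelse(has_ev, events[first_ev], NA_character_),
    latency_days = latency,
    event_dt = event_dt,
    fda_dt = fda_dt + ifelse(dup, dup_gap, 0L)
  )

  structure(
    list(demo = demo, drug = drug_tab, reac = reac_tab, ther = ther_tab,
         outc = outc_tab,
         truth = list(reports = truth_reports, event_matrix = emat,
                      config = config)),
    class = "synthetic_faers"
  )
}

# per-group running index for an already-sorted integer vector
rle_counts <- function(x) {
  if (!length(x)) return(integer(0))
  rle(x)$lengths
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat("<synthetic_faers>", nrow(x$truth$reports), "cases,",
      nrow(x$demo), "demo rows,", nrow(x$reac), "reaction rows\n")
  invisible(x)
}

#' Write a synthetic dataset as FAERS quarterly ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt` and `OUTC.txt` in the
#' `$`-delimited dialect with a header row. The dialect has no escaping, so
#' any field containing the delimiter is rejected.
#'
#' @param ds a [simulate_faers()] result.
#' @param directory output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_faers_tables <- function(ds, directory) {
  stopifnot(inherits(ds, "synthetic_faers"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory) || file.access(directory, 2L) != 0L)
    stop("cannot write to directory: ", directory)
  tabs <- list(DEMO = ds$demo, DRUG = ds$drug, REAC = ds$reac,
               THER = ds$ther, OUTC = ds$outc)
  paths <- character(0)
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    bad <- vapply(tab, function(col) any(grepl("$", col, fixed = TRUE)), logical(1))
    if (any(bad))
      stop("field(s) ", paste(names(tab)[bad], collapse = ", "), " in ", nm,
           " contain the '$' delimiter; the dialect has no escaping")
    p <- file.path(directory, paste0(nm, ".txt"))
    data.table::fwrite(tab, p, sep = "$", quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
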