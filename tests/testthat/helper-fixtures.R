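# Shared fixtures: all synthetic, generated in code.

AP_PT <- "PANCREATITIS ACUTE"

ap_smq <- function(broad = c("Lipase increased", "Amylase increased"))
  smq_definition("Acute pancreatitis", AP_PT, broad)

# Small four-drug world; drug 1 carries the (optional) planted signal on the
# target preferred term.
small_config <- function(seed = 1, n_cases = 2000, rr = 1, n_drugs = 4,
                         n_events = 8, background_rate = 0.02, ...) {
  events <- c(AP_PT, sprintf("PT_%03d", seq_len(n_events - 1)))
  drugs <- c("OLANZAPINE", "QUETIAPINE",
             sprintf("DRUG_%02d", seq_len(max(0, n_drugs - 2))))
  m <- matrix(1, n_drugs, n_events)
  m[1, 1] <- rr
  sim_config(n_cases = n_cases, drugs = drugs, events = events,
             background_rate = background_rate, signal_matrix = m,
             seed = seed, ...)
}

# Build a faers_data directly from minimal row specs (defaults filled in),
# for hand-enumerable unit cases.
mk_fd <- function(reports, drugs = NULL, reacs = NULL, thers = NULL,
                  date_policy = "strict_day") {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  defaults <- list(version = "1", fda = "20200101", event = "", sex = "M",
                   age = "50", age_cod = "YR", wt = "70", wt_cod = "KG",
                   occp = "MD", country = "US")
  for (nm in names(defaults))
    if (is.null(reports[[nm]])) reports[[nm]] <- defaults[[nm]]
  demo <- data.table::data.table(
    PRIMARYID = reports$primaryid, CASEID = reports$caseid,
    CASEVERSION = as.character(reports$version), FDA_DT = reports$fda,
    EVENT_DT = reports$event, SEX = reports$sex, AGE = reports$age,
    AGE_COD = reports$age_cod, WT = reports$wt, WT_COD = reports$wt_cod,
    OCCP_COD = reports$occp, REPORTER_COUNTRY = reports$country)
  empty <- function(...) data.table::data.table(...)[0]
  drug <- if (is.null(drugs))
    empty(PRIMARYID = "", CASEID = "", DRUG_SEQ = "", ROLE_COD = "", DRUGNAME = "")
  else {
    drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
    if (is.null(drugs$seq)) drugs$seq <- "1"
    data.table::data.table(PRIMARYID = drugs$primaryid, CASEID = drugs$primaryid,
                           DRUG_SEQ = as.character(drugs$seq),
                           ROLE_COD = drugs$role, DRUGNAME = drugs$name)
  }
  reac <- if (is.null(reacs))
    empty(PRIMARYID = "", CASEID = "", PT = "")
  else {
    reacs <- as.data.frame(reacs, stringsAsFactors = FALSE)
    data.table::data.table(PRIMARYID = reacs$primaryid, CASEID = reacs$primaryid,
                           PT = reacs$pt)
  }
  ther <- if (is.null(thers))
    empty(PRIMARYID = "", CASEID = "", DSG_DRUG_SEQ = "", START_DT = "")
  else {
    thers <- as.data.frame(thers, stringsAsFactors = FALSE)
    if (is.null(thers$seq)) thers$seq <- "1"
    data.table::data.table(PRIMARYID = thers$primaryid, CASEID = thers$primaryid,
                           DSG_DRUG_SEQ = as.character(thers$seq),
                           START_DT = thers$start)
  }
  outc <- empty(PRIMARYID = "", CASEID = "", OUTC_COD = "")
  raw <- structure(list(DEMO = demo, DRUG = drug, REAC = reac, THER = ther,
                        OUTC = outc), class = "faers_raw")
  as_case_reports(raw, date_policy = date_policy)
}

# random 2x2 cell draws used by several oracle suites
random_tables <- function(n, lo = 1, hi = 1e5, seed = 1) {
  set.seed(seed)
  data.frame(a = sample(lo:hi, n, TRUE), b = sample(lo:hi, n, TRUE),
             c = sample(lo:hi, n, TRUE), d = sample(lo:hi, n, TRUE))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
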