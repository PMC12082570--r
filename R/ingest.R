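FAERS_FILES <- c(DEMO = "DEMO.txt", DRUG = "DRUG.txt", REAC = "REAC.txt",
                 THER = "THER.txt", OUTC = "OUTC.txt")

FAERS_COLUMNS <- list(
  DEMO = c("PRIMARYID", "CASEID", "CASEVERSION", "FDA_DT", "EVENT_DT", "SEX",
           "AGE", "AGE_COD", "WT", "WT_COD", "OCCP_COD", "REPORTER_COUNTRY"),
  DRUG = c("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
  REAC = c("PRIMARYID", "CASEID", "PT"),
  THER = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT"),
  OUTC = c("PRIMARYID", "CASEID", "OUTC_COD")
)

#' Read the five FAERS-dialect tables from a directory
#'
#' Expects `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`,
#' `$`-delimited with a header row. All columns are read as character;
#' typing happens in [as_case_reports()].
#'
#' @param directory path holding the five files.
#' @return a list of five raw `data.table`s, class `"faers_raw"`.
#' @export
read_faers_tables <- function(directory) {
  out <- list()
  for (nm in names(FAERS_FILES)) {
    p <- file.path(directory, FAERS_FILES[[nm]])
    if (!file.exists(p))
      stop("missing FAERS table file: ", FAERS_FILES[[nm]], " in ", directory)
    tab <- data.table::fread(p, sep = "$", colClasses = "character",
                             header = TRUE, na.strings = NULL)
    need <- FAERS_COLUMNS[[nm]]
    if (!all(need %in% names(tab)))
      stop("malformed header in ", FAERS_FILES[[nm]], ": missing column(s) ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    out[[nm]] <- tab
  }
  structure(out, class = "faers_raw")
}

#' Type raw FAERS tables into a normalized case-report set
#'
#' Produces the package's central container: a list of linked tables keyed by
#' primary id. Unparseable dates become missing (never a row failure); ages
#' are converted to years (`YR`, `DEC`, `MON`, `WK`, `DY` codes) and weights
#' to kilograms (`KG`, `LBS`); sex is normalized to male/female/unknown; role
#' codes outside PS/SS/C/I become `NA`. Therapy start dates are joined onto
#' the drug rows by (primary id, drug sequence).
#'
#' @param raw a [read_faers_tables()] result or a `synthetic_faers` object.
#' @param date_policy passed to [parse_faers_date()].
#' @return class `"faers_data"`: `reports` (one row per primary id),
#'   `drugs`, `reactions`, `outcomes` tables, plus an ingest `log`.
#' @export
as_case_reports <- function(raw, date_policy = c("strict_day", "pad_first")) {
  date_policy <- match.arg(date_policy)
  if (inherits(raw, "synthetic_faers"))
    raw <- structure(list(DEMO = raw$demo, DRUG = raw$drug, REAC = raw$reac,
                          THER = raw$ther, OUTC = raw$outc),
                     class = "faers_raw")
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$DEMO

  age_mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25, DY = 1 / 365.25)
  age_num <- suppressWarnings(as.numeric(demo$AGE))
  age_years <- age_num * age_mult[toupper(trimws(demo$AGE_COD))]
  age_years[!is.finite(age_years) | age_years < 0] <- NA_real_

  wt_num <- suppressWarnings(as.numeric(demo$WT))
  wt_mult <- c(KG = 1, KGS = 1, LBS = 0.45359237, LB = 0.45359237)
  weight_kg <- wt_num * wt_mult[toupper(trimws(demo$WT_COD))]
  weight_kg[!is.finite(weight_kg) | weight_kg <= 0] <- NA_real_

  sex_raw <- toupper(trimws(demo$SEX))
  sex <- ifelse(sex_raw == "M", "male", ifelse(sex_raw == "F", "female", "unknown"))

  reports <- data.table(
    primaryid = demo$PRIMARYID,
    caseid = demo$CASEID,
    case_version = suppressWarnings(as.integer(demo$CASEVERSION)),
    fda_dt = parse_faers_date(demo$FDA_DT, date_policy),
    event_dt = parse_faers_date(demo$EVENT_DT, date_policy),
    sex = sex, age_years = age_years, weight_kg = weight_kg,
    reporter = demo$OCCP_COD, country = demo$REPORTER_COUNTRY
  )

  role <- toupper(trimws(raw$DRUG$ROLE_COD))
  role[!role %in% c("PS", "SS", "C", "I")] <- NA_character_
  drugs <- data.table(
    primaryid = raw$DRUG$PRIMARYID,
    drug_seq = raw$DRUG$DRUG_SEQ,
    role_cod = role,
    drugname = raw$DRUG$DRUGNAME
  )
  ther <- data.table(
    primaryid = raw$THER$PRIMARYID,
    drug_seq = raw$THER$DSG_DRUG_SEQ,
    start_dt = parse_faers_date(raw$THER$START_DT, date_policy)
  )
  drugs <- merge(drugs, ther, by = c("primaryid", "drug_seq"),
                 all.x = TRUE, sort = FALSE)

  reactions <- data.table(primaryid = raw$REAC$PRIMARYID, pt = raw$REAC$PT)
  outcomes <- data.table(primaryid = raw$OUTC$PRIMARYID,
                         outc_cod = raw$OUTC$OUTC_COD)

  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes,
         log = list(date_policy = date_policy,
                    n_raw_reports = nrow(reports),
                    n_invalid_role = sum(is.na(role)))),
    class = "faers_data"
  )
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>", nrow(x$reports), "reports,",
      length(unique(x$reports$caseid)), "cases,",
      nrow(x$drugs), "drug rows,", nrow(x$reactions), "reaction rows\n")
  invisible(x)
}

#' Deduplicate to one report per case
#'
#' Retains, for each case id, the version with the latest receipt date
#' (`FDA_DT`), ties broken by highest case version, then highest primary id
#' (compared numerically). Rows with missing receipt dates lose to any dated
#' row. Idempotent and invariant to input row order. All linked tables are
#' filtered to the surviving primary ids.
#'
#' @param fd a [as_case_reports()] result.
#' @return a deduplicated `"faers_data"`; `log$n_deduplicated` records the
#'   number of dropped versions.
#' @export
deduplicate_reports <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  r <- copy(fd$reports)
  r[, `:=`(.fda = as.numeric(fda_dt), .pid = suppressWarnings(as.numeric(primaryid)))]
  r[is.na(.fda), .fda := -Inf]
  setorder(r, caseid, .fda, case_version, .pid)
  keep <- r[, primaryid[.N], by = caseid]$V1
  dropped <- nrow(fd$reports) - length(keep)
  out <- filter_faers(fd, keep)
  out$log$n_deduplicated <- dropped
  out$log$n_cases <- length(keep)
  out
}

# subset every linked table to a set of primary ids, preserving report order
filter_faers <- function(fd, primaryids) {
  out <- fd
  out$reports <- fd$reports[primaryid %in% primaryids]
  out$drugs <- fd$drugs[primaryid %in% primaryids]
  out$reactions <- fd$reactions[primaryid %in% primaryids]
  out$outcomes <- fd$outcomes[primaryid %in% primaryids]
  out
}

#' Select reports where a drug appears with the primary-suspect role
#'
#' Name matching is case-insensitive exact after trimming.
#'
#' @param fd a (deduplicated) `"faers_data"`.
#' @param drug_name target drug.
#' @return the subset `"faers_data"` containing only PS reports of the drug.
#' @export
select_ps_reports <- function(fd, drug_name) {
  stopifnot(inherits(fd, "faers_data"))
  ids <- ps_report_ids(fd, drug_name)
  filter_faers(fd, ids)
}

ps_report_ids <- function(fd, drug_name) {
  unique(fd$drugs[role_cod == "PS" &
                    norm_name(drugname) == norm_name(drug_name), primaryid])
}

#' Read a Standardized MedDRA Query definition file
#'
#' Plain-text format: one preferred term per line under `[narrow]` and
#' optional `[broad]` section headers; `#` starts a comment. The broad scope
#' is the union of the two sections.
#'
#' @param path file path.
#' @param name query name; defaults to the file name.
#' @return class `"smq_definition"` with `name`, `narrow_pts`, `broad_pts`.
#' @export
read_smq <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- "narrow"
  narrow <- character(0); broad <- character(0)
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      if (!section %in% c("narrow", "broad"))
        stop("unknown SMQ section: [", section, "]")
    } else if (section == "narrow") narrow <- c(narrow, ln)
    else broad <- c(broad, ln)
  }
  smq_definition(name, narrow, broad)
}

#' Construct an SMQ definition
#'
#' @param name query name.
#' @param narrow_pts preferred terms of the narrow scope (non-empty).
#' @param broad_pts additional terms for the broad scope (may be empty).
#' @return class `"smq_definition"`.
#' @export
smq_definition <- function(name, narrow_pts, broad_pts = character(0)) {
  narrow_pts <- unique(norm_name(narrow_pts))
  broad_pts <- unique(norm_name(broad_pts))
  if (!length(narrow_pts)) stop_invalid("narrow_pts", "must be non-empty")
  structure(list(name = name, narrow_pts = narrow_pts, broad_pts = broad_pts),
            class = "smq_definition")
}

#' Flag reports whose reactions intersect an SMQ scope
#'
#' A report is a target case iff its reaction set intersects the scope's
#' preferred-term set (case-insensitive exact match after trimming). The
#' broad scope is `narrow_pts` plus `broad_pts`.
#'
#' @param fd a `"faers_data"`.
#' @param smq an [smq_definition()].
#' @param scope `"narrow"` or `"broad"`.
#' @return a logical vector named by primary id, in report order.
#' @export
flag_event_cases <- function(fd, smq, scope = c("narrow", "broad")) {
  stopifnot(inherits(fd, "faers_data"), inherits(smq, "smq_definition"))
  scope <- match.arg(scope)
  pts <- if (scope == "narrow") smq$narrow_pts else union(smq$narrow_pts, smq$broad_pts)
  hit_ids <- unique(fd$reactions[norm_name(pt) %in% pts, primaryid])
  setNames(fd$reports$primaryid %in% hit_ids, fd$reports$primaryid)
}
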