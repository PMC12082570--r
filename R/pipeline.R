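#' Run the full pharmacovigilance pipeline on a directory of report tables
#'
#' Orchestrates ingest, deduplication, SMQ case finding, the overall and
#' stratified four-algorithm signal scan, time-to-onset Weibull analysis,
#' logistic risk modelling with nomogram and ROC, and (when edge-list inputs
#' are configured) the gene-set intersection / hub-ranking stage. Every
#' stage's record counts, the full config snapshot and input file hashes go
#' into `manifest.json`, so a run is reproducible from its manifest.
#'
#' @param config a list (or path to a JSON file) with components:
#'   `input_dir` (directory of the five dialect files); `drugs` (drug names
#'   to analyse; default every primary-suspect drug); `smq_file` (path to an
#'   SMQ definition, see [read_smq()]) or `smq_narrow_pts`; `scope`;
#'   `date_policy`; `adjust_method`; `age_cut`/`weight_cut`; `tto_min_n`;
#'   `risk` (list: `concomitants`, `comorbidity_pts`, `p_cut`,
#'   `auto_concomitants`); optional `nettox` (list: `targets_file`,
#'   `disease_file`, `edges_file`, `score_floor`, `top_k`); optional
#'   `thresholds` / `priors` overrides (named lists).
#' @param out_dir output directory; created if needed.
#' @return invisibly, the output directory. Stage outputs are written as CSV
#'   / JSON files plus `manifest.json`.
#' @export
run_faers_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- config
  cfg$scope <- cfg$scope %||% "narrow"
  cfg$date_policy <- cfg$date_policy %||% "strict_day"
  cfg$adjust_method <- cfg$adjust_method %||% "BH"
  cfg$age_cut <- cfg$age_cut %||% 65
  cfg$weight_cut <- cfg$weight_cut %||% 80
  cfg$tto_min_n <- cfg$tto_min_n %||% 30
  cfg$risk <- cfg$risk %||% list()
  cfg$risk$p_cut <- cfg$risk$p_cut %||% 0.05
  cfg$risk$auto_concomitants <- cfg$risk$auto_concomitants %||% 5

  thresholds <- do.call(signal_thresholds, as.list(cfg$thresholds %||% list()))
  priors <- do.call(bcpnn_priors, as.list(cfg$priors %||% list()))

  manifest <- list(
    software = paste("pvkit", as.character(utils::packageVersion("pvkit"))),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg_snapshot(cfg, thresholds, priors),
    input_hashes = as.list(tools::md5sum(
      list.files(cfg$input_dir, full.names = TRUE))),
    stages = list()
  )
  flush_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      flush_manifest()
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # -- ingest ---------------------------------------------------------------
  fd <- run_stage("ingest", {
    raw <- read_faers_tables(cfg$input_dir)
    as_case_reports(raw, date_policy = cfg$date_policy)
  })
  manifest$stages$ingest <- list(n_reports = nrow(fd$reports),
                                 n_drug_rows = nrow(fd$drugs),
                                 n_reaction_rows = nrow(fd$reactions))

  fd <- run_stage("deduplicate", deduplicate_reports(fd))
  manifest$stages$deduplicate <- list(n_reports = nrow(fd$reports),
                                      n_dropped = fd$log$n_deduplicated)

  smq <- run_stage("smq", {
    if (!is.null(cfg$smq_file)) read_smq(cfg$smq_file)
    else smq_definition(cfg$smq_name %||% "target event",
                        cfg$smq_narrow_pts,
                        cfg$smq_broad_pts %||% character(0))
  })
  flags <- flag_event_cases(fd, smq, cfg$scope)
  manifest$stages$case_finding <- list(
    smq = smq$name, scope = cfg$scope,
    n_flagged_reports = sum(flags),
    n_pt_occurrences = nrow(fd$reactions[norm_name(pt) %in%
      (if (cfg$scope == "narrow") smq$narrow_pts
       else union(smq$narrow_pts, smq$broad_pts))]))

  drugs <- cfg$drugs %||%
    sort(unique(norm_name(fd$drugs[role_cod == "PS", drugname])))

  # -- signal scan (overall + strata) ---------------------------------------
  signals <- run_stage("signal_scan", {
    scan_signals(fd, drugs = drugs, smq = smq, scope = cfg$scope,
                 priors = priors, thresholds = thresholds,
                 adjust_method = cfg$adjust_method)
  })
  fwrite_plain(signals, file.path(out_dir, "signals.csv"))
  manifest$stages$signal_scan <- list(n_pairs = nrow(signals),
                                      n_signals = sum(signals$signal))

  strata_tab <- run_stage("stratified_scan", {
    rbindlist(lapply(drugs, function(dg)
      stratified_scan(fd, dg, flags,
                      strata = default_strata(cfg$age_cut, cfg$weight_cut),
                      priors = priors, thresholds = thresholds,
                      adjust_method = cfg$adjust_method)))
  })
  fwrite_plain(strata_tab, file.path(out_dir, "strata.csv"))
  manifest$stages$stratified_scan <- list(n_rows = nrow(strata_tab))

  descr <- run_stage("descriptive", descriptive_table(fd, drugs, flags))
  fwrite_plain(descr, file.path(out_dir, "descriptive.csv"))

  # -- time to onset --------------------------------------------------------
  tto_tab <- run_stage("tto", {
    rbindlist(lapply(drugs, function(dg) {
      s <- compute_tto(fd, dg, flags)
      if (length(s$values) < max(2, cfg$tto_min_n))
        return(data.table(drug = norm_name(dg), n = length(s$values),
                          n_excluded_missing = s$n_excluded_missing,
                          n_excluded_nonpositive = s$n_excluded_nonpositive,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          min = NA_real_, max = NA_real_, alpha = NA_real_,
                          alpha_lo = NA_real_, alpha_hi = NA_real_,
                          beta = NA_real_, beta_lo = NA_real_,
                          beta_hi = NA_real_, failure_type = NA_character_))
      fit <- fit_weibull(s, min_n = cfg$tto_min_n)
      data.table(drug = norm_name(dg), n = fit$n,
                 n_excluded_missing = s$n_excluded_missing,
                 n_excluded_nonpositive = s$n_excluded_nonpositive,
                 median = fit$median, q1 = fit$q1, q3 = fit$q3,
                 min = fit$min, max = fit$max,
                 alpha = fit$alpha, alpha_lo = fit$alpha_ci95[1],
                 alpha_hi = fit$alpha_ci95[2],
                 beta = fit$beta, beta_lo = fit$beta_ci95[1],
                 beta_hi = fit$beta_ci95[2],
                 failure_type = fit$failure_type)
    }))
  })
  fwrite_plain(tto_tab, file.path(out_dir, "tto.csv"))
  manifest$stages$tto <- list(n_drugs = nrow(tto_tab))

  # -- risk model -----------------------------------------------------------
  # a drug whose model is degenerate (separation, single-class outcome) is
  # logged and skipped rather than aborting the stage for every other drug
  risk_out <- run_stage("risk_model", {
    lapply(setNames(drugs, drugs), function(dg)
      tryCatch(risk_stage_one(fd, dg, flags, cfg),
               error = function(e)
                 list(note = paste("skipped:", conditionMessage(e)))))
  })
  uni_tab <- rbindlist(lapply(risk_out, `[[`, "uni"), fill = TRUE)
  multi_tab <- rbindlist(lapply(risk_out, `[[`, "multi"), fill = TRUE)
  fwrite_plain(uni_tab, file.path(out_dir, "risk_univariable.csv"))
  fwrite_plain(multi_tab, file.path(out_dir, "risk_multivariable.csv"))
  roc_tab <- rbindlist(lapply(risk_out, `[[`, "roc"), fill = TRUE)
  fwrite_plain(roc_tab, file.path(out_dir, "roc.csv"))
  nomos <- lapply(risk_out, `[[`, "nomogram")
  nomos <- nomos[!vapply(nomos, is.null, logical(1))]
  jsonlite::write_json(nomos, file.path(out_dir, "nomogram.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$stages$risk_model <- list(
    aucs = lapply(risk_out, function(x) x$auc %||% NA),
    notes = lapply(risk_out, function(x) x$note %||% ""))

  # -- network toxicology tail (optional) -----------------------------------
  if (!is.null(cfg$nettox)) {
    nt <- run_stage("nettox", {
      targets <- read_gene_list(cfg$nettox$targets_file)
      disease <- read_gene_list(cfg$nettox$disease_file)
      overlap <- intersect_sets(targets, disease)
      g <- load_edges(cfg$nettox$edges_file,
                      score_floor = cfg$nettox$score_floor %||% 0.15)
      hubs <- degree_hubs(g, k = cfg$nettox$top_k %||% 3)
      list(n_targets = length(targets$symbols),
           n_disease = length(disease$symbols),
           overlap = overlap$symbols, n_overlap = length(overlap$symbols),
           hubs = hubs)
    })
    jsonlite::write_json(nt, file.path(out_dir, "nettox.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$nettox <- list(n_overlap = nt$n_overlap,
                                   hubs = nt$hubs$gene)
  }

  jsonlite::write_json(c(fd$log, list(n_flagged = sum(flags))),
                       file.path(out_dir, "ingest_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  flush_manifest()
  invisible(out_dir)
}

# CSV writer with deterministic formatting (no scientific notation drift);
# stage tables can legitimately be empty (every drug skipped)
fwrite_plain <- function(x, path) {
  if (is.null(x) || ncol(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  data.table::fwrite(x, path, quote = TRUE, na = "NA", scipen = 50)
}

cfg_snapshot <- function(cfg, thresholds, priors) {
  snap <- cfg
  snap$thresholds <- unclass(thresholds)
  snap$priors <- unclass(priors)
  snap
}

descriptive_table <- function(fd, drugs, flags) {
  rbindlist(lapply(drugs, function(dg) {
    sel <- fd$reports$primaryid %in% ps_report_ids(fd, dg) & flags
    r <- fd$reports[sel]
    n <- nrow(r)
    rows <- list(
      data.table(characteristic = "sex",
                 level = c("male", "female", "unknown"),
                 count = c(sum(r$sex == "male"), sum(r$sex == "female"),
                           sum(r$sex == "unknown"))),
      data.table(characteristic = "age",
                 level = c("<18", "18-65", "65-85", ">85", "unknown"),
                 count = c(sum(!is.na(r$age_years) & r$age_years < 18),
                           sum(!is.na(r$age_years) & r$age_years >= 18 & r$age_years < 65),
                           sum(!is.na(r$age_years) & r$age_years >= 65 & r$age_years <= 85),
                           sum(!is.na(r$age_years) & r$age_years > 85),
                           sum(is.na(r$age_years)))),
      data.table(characteristic = "weight",
                 level = c("<50kg", "50-100kg", ">100kg", "unknown"),
                 count = c(sum(!is.na(r$weight_kg) & r$weight_kg < 50),
                           sum(!is.na(r$weight_kg) & r$weight_kg >= 50 & r$weight_kg <= 100),
                           sum(!is.na(r$weight_kg) & r$weight_kg > 100),
                           sum(is.na(r$weight_kg))))
    )
    out <- rbindlist(rows)
    out[, `:=`(drug = norm_name(dg), total = n,
               pct = ifelse(n > 0, round(100 * count / n, 1), 0))]
    setcolorder(out, c("drug", "characteristic", "level", "count", "pct", "total"))
    out
  }))
}

risk_stage_one <- function(fd, dg, flags, cfg) {
  ids <- ps_report_ids(fd, dg)
  sel <- fd$reports$primaryid %in% ids
  concoms <- cfg$risk$concomitants
  if (is.null(concoms) && cfg$risk$auto_concomitants > 0) {
    cand <- fd$drugs[primaryid %in% ids & (is.na(role_cod) | role_cod != "PS"),
                     .N, by = .(name = norm_name(drugname))]
    setorder(cand, -N, name)
    concoms <- head(cand$name, cfg$risk$auto_concomitants)
  }
  frame <- risk_model_frame(fd, dg, flags,
                            concomitants = concoms %||% character(0),
                            comorbidity_pts = cfg$risk$comorbidity_pts %||% character(0),
                            age_cut = cfg$age_cut, weight_cut = cfg$weight_cut)
  covs <- setdiff(names(frame), c("primaryid", "event"))
  # drop covariates that are constant after the missing-data drop; the stage
  # logs them instead of aborting the whole run
  usable <- covs[vapply(covs, function(cv) {
    v <- frame[[cv]][!is.na(frame[[cv]])]
    length(unique(v)) >= 2L
  }, logical(1))]
  dropped <- setdiff(covs, usable)
  if (length(unique(frame$event)) < 2L || !length(usable))
    return(list(note = paste("skipped: single-class outcome or no usable",
                             "covariates for", norm_name(dg))))
  # sparse indicators can separate on small strata; keep whatever fits
  uni_fits <- list()
  for (cv in usable) {
    f <- tryCatch(fit_logistic(frame, cv), error = function(e) NULL)
    if (is.null(f)) dropped <- c(dropped, cv) else uni_fits[[cv]] <- f
  }
  if (!length(uni_fits))
    return(list(note = paste("skipped: no covariate fit for", norm_name(dg))))
  uni <- structure(uni_fits, class = "pv_logistic_list")
  attr(uni, "table") <- rbindlist(lapply(uni_fits, `[[`, "table"))
  uni_tab <- copy(attr(uni, "table"))[, `:=`(drug = norm_name(dg), mode = "univariable")]
  selected <- select_covariates(uni, cfg$risk$p_cut)
  if (!length(selected)) selected <- names(uni_fits)
  multi <- tryCatch(fit_logistic(frame, selected, mode = "multivariable"),
                    error = function(e) NULL)
  if (is.null(multi)) {
    # fall back to the single strongest screened covariate
    best <- names(uni_fits)[which.min(vapply(uni_fits, function(f)
      f$table[term != "(Intercept)", min(p)], numeric(1)))]
    multi <- fit_logistic(frame, best, mode = "multivariable")
  }
  multi_tab <- copy(multi$table)[, `:=`(drug = norm_name(dg), mode = "multivariable")]
  nomo <- build_nomogram(multi)
  roc <- roc_auc(multi)
  list(uni = uni_tab, multi = multi_tab,
       nomogram = list(drug = norm_name(dg), points = nomo$points,
                       points_per_unit = nomo$points_per_unit,
                       base_lp = nomo$base_lp, auc = roc$auc),
       roc = copy(roc$curve)[, drug := norm_name(dg)],
       auc = roc$auc,
       note = if (length(dropped))
         paste("dropped degenerate covariates:", paste(dropped, collapse = ", "))
       else "")
}

#' Assemble a human-readable summary report from pipeline outputs
#'
#' Renders `report.md` from the stage CSVs in a pipeline output directory:
#' the signal table, the stratification table, the regression table and the
#' time-to-onset table. Missing stage outputs are flagged as gaps rather than
#' failing. Regeneration from unchanged outputs is byte-identical.
#'
#' @param out_dir a [run_faers_pipeline()] output directory.
#' @return invisibly, the path of the written report.
#' @export
make_report <- function(out_dir) {
  path <- file.path(out_dir, "report.md")
  con <- c("# Pharmacovigilance run summary", "")
  section <- function(title, file, render) {
    p <- file.path(out_dir, file)
    con <<- c(con, paste("##", title), "")
    if (!file.exists(p)) {
      con <<- c(con, paste0("*Missing stage output: `", file, "`.*"), "")
    } else {
      tab <- if (file.size(p) == 0) data.table::data.table()
             else data.table::fread(p)
      con <<- c(con, render(tab), "")
    }
  }
  section("Signal detection", "signals.csv", function(tab) {
    sig <- tab[signal == TRUE]
    if (nrow(sig) == 0) return("No significant signals under the joint four-algorithm criteria.")
    md_table(sig[, .(drug, event, a,
                     ROR = sprintf("%.2f (%.2f-%.2f)", ror, ror_lo, ror_hi),
                     PRR = sprintf("%.2f (%.2f-%.2f)", prr, prr_lo, prr_hi),
                     chi2 = sprintf("%.2f", chi2),
                     IC025 = sprintf("%.2f", ic025),
                     EBGM05 = sprintf("%.2f", ebgm05),
                     adj_p = signif(p_adjusted, 3))])
  })
  section("Stratified analysis", "strata.csv", function(tab) {
    md_table(tab[, .(drug, stratum, a,
                     ROR = sprintf("%.2f (%.2f-%.2f)", ror, ror_lo, ror_hi),
                     chi2 = sprintf("%.2f", chi2),
                     IC025 = sprintf("%.2f", ic025),
                     EBGM05 = sprintf("%.2f", ebgm05),
                     signal = signal)])
  })
  section("Risk factors (logistic regression)", "risk_multivariable.csv", function(tab) {
    if (nrow(tab) == 0) return("No multivariable model was estimable.")
    md_table(tab[term != "(Intercept)",
                 .(drug, term, OR = sprintf("%.2f (%.2f-%.2f)", or, or_lo, or_hi),
                   p = signif(p, 3))])
  })
  section("Time to onset (Weibull)", "tto.csv", function(tab) {
    md_table(tab[, .(drug, n,
                     median_IQR = ifelse(is.na(median), "-",
                       sprintf("%.0f (%.0f-%.0f)", median, q1, q3)),
                     min_max = ifelse(is.na(min), "-", sprintf("%.0f-%.0f", min, max)),
                     alpha = ifelse(is.na(alpha), "-",
                       sprintf("%.2f (%.2f-%.2f)", alpha, alpha_lo, alpha_hi)),
                     beta = ifelse(is.na(beta), "-",
                       sprintf("%.2f (%.2f-%.2f)", beta, beta_lo, beta_hi)),
                     type = failure_type)])
  })
  writeLines(con, path)
  invisible(path)
}

md_table <- function(dt) {
  dt <- as.data.table(dt)
  hdr <- paste0("| ", paste(names(dt), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(dt)), collapse = "|"), "|")
  rows <- apply(dt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
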