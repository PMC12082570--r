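test_that("build_table partitions a hand-enumerated universe", {
  fd <- mk_fd(
    data.frame(primaryid = c("11", "21", "31", "41"),
               caseid = c("1", "2", "3", "4"), sex = c("M", "M", "F", "F")),
    drugs = data.frame(primaryid = c("11", "21", "31", "41"),
                       role = c("PS", "PS", "PS", "PS"),
                       name = c("TARGET", "TARGET", "OTHER", "OTHER")),
    reacs = data.frame(primaryid = c("11", "31"),
                       pt = c("Pancreatitis acute", "Pancreatitis acute"))
  )
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  tab <- build_table(fd, "TARGET", flags)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
  # an all-FALSE stratum yields zeros, not an error
  empty <- build_table(fd, "TARGET", flags, stratum = rep(FALSE, 4))
  expect_equal(empty$n, 0)
  # stratum restricted to males
  males <- build_table(fd, "TARGET", flags, stratum = fd$reports$sex == "male")
  expect_equal(unlist(males[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 0, d = 0))
})

test_that("the a cell matches the simulator truth", {
  cfg <- small_config(seed = 11, n_cases = 4000, rr = 8, duplicate_rate = 0.1)
  ds <- simulate_faers(cfg)
  fd <- deduplicate_reports(as_case_reports(ds))
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  tab <- build_table(fd, "OLANZAPINE", flags)
  truth_a <- sum(ds$truth$reports$ps_drug == "OLANZAPINE" &
                   ds$truth$event_matrix[, AP_PT])
  expect_equal(tab$a, truth_a)
  expect_equal(tab$n, cfg$n_cases)
})

test_that("ROR matches hand arithmetic and its symmetries", {
  t1 <- contingency_table(20, 80, 100, 9800)
  r <- ror_stat(t1)
  expect_equal(r$point, 24.5)
  expect_equal(r$ci95,
               exp(log(24.5) + c(-1.96, 1.96) * sqrt(1/20 + 1/80 + 1/100 + 1/9800)))
  expect_equal(ror_stat(contingency_table(10, 90, 10, 90))$point, 1)
  swapped <- ror_stat(contingency_table(100, 9800, 20, 80))
  expect_equal(swapped$point, 1 / r$point)
})

test_that("PRR and chi-square match hand arithmetic and the Pearson oracle", {
  t1 <- contingency_table(20, 80, 100, 9800)
  p <- prr_stat(t1)
  expect_equal(p$point, (20 / 100) / (100 / 9900))
  expect_equal(p$point, 19.8)
  oracle <- unname(suppressWarnings(
    chisq.test(matrix(c(20, 80, 100, 9800), 2, byrow = TRUE),
               correct = FALSE))$statistic)
  expect_equal(p$chi2, oracle, tolerance = 1e-12)
  ind <- prr_stat(contingency_table(10, 90, 10, 90))
  expect_equal(ind$point, 1)
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p_raw, 1)
})

test_that("BCPNN information component behaves at independence and degeneracy", {
  b <- bcpnn_stat(contingency_table(100, 900, 900, 8100))
  expect_lt(abs(b$ic), 0.05)
  expect_lt(b$ic025, b$ic)
  empty <- bcpnn_stat(contingency_table(0, 0, 0, 0))
  expect_true(is.finite(empty$ic))
  # prior influence washes out monotonically as an independent table scales up
  ics <- sapply(10^(0:4), function(k)
    abs(bcpnn_stat(contingency_table(10 * k, 90 * k, 90 * k, 810 * k))$ic))
  expect_true(all(diff(ics) < 0))
})

test_that("EBGM is the relative reporting ratio with a one-sided lower bound", {
  e <- ebgm_stat(contingency_table(20, 80, 100, 9800))
  expect_equal(e$ebgm, 20 * 10000 / (120 * 100))
  expect_equal(e$ebgm, 16.667, tolerance = 1e-4)
  expect_equal(ebgm_stat(contingency_table(10, 90, 10, 90))$ebgm, 1)
  tabs <- random_tables(50, lo = 1, hi = 1000, seed = 3)
  s <- disprop_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(s$ebgm05 < s$ebgm))
})

test_that("zero cells trigger the continuity correction and are flagged", {
  s <- disprop_stats(5, 0, 3, 100)
  expect_true(s$zero_corrected)
  expect_true(all(is.finite(unlist(s[, .(ror, ror_lo, prr, prr_hi, ebgm05)]))))
  expect_false(disprop_stats(5, 1, 3, 100)$zero_corrected)
})

test_that("joint signal criteria follow the four printed rules", {
  # a below 3 fails ROR/PRR/BCPNN gates no matter how extreme the ratio
  s_small <- signal_decision(disprop_stats(2, 3, 1, 10000))
  expect_false(s_small$ror_flag)
  expect_false(s_small$signal)
  s_big <- signal_decision(disprop_stats(20, 80, 100, 9800))
  expect_true(all(unlist(s_big[, .(ror_flag, prr_flag, bcpnn_flag, ebgm_flag, signal)])))
  s_ind <- signal_decision(disprop_stats(10, 90, 10, 90))
  expect_false(any(unlist(s_ind[, .(ror_flag, prr_flag, bcpnn_flag, ebgm_flag)])))
})

test_that("all four point statistics are non-decreasing in a", {
  b <- 500; cc <- 300; d <- 10000
  s <- disprop_stats(1:60, rep(b, 60), rep(cc, 60), rep(d, 60))
  for (col in c("ror", "prr", "ic", "ebgm"))
    expect_true(all(diff(s[[col]]) >= 0), label = paste(col, "monotone in a"))
})

test_that("2^E(IC) approaches EBGM as cells grow at fixed ratios", {
  ratio <- sapply(10^(1:5), function(k) {
    s <- disprop_stats(3 * k, 7 * k, 11 * k, 79 * k)
    abs(2^s$ic - s$ebgm) / s$ebgm
  })
  expect_true(all(diff(ratio) < 0))
  expect_lt(ratio[5], 1e-4)
})

test_that("p-value adjustment matches hand BH and rejects unknown methods", {
  one <- adjust_pvalues(data.frame(p_raw = 0.02))
  expect_equal(one$p_adjusted, 0.02)
  bh <- adjust_pvalues(data.frame(p_raw = c(0.01, 0.02, 0.03)))
  expect_equal(bh$p_adjusted, c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(data.frame(p_raw = rep(1, 5)))$p_adjusted, rep(1, 5))
  bonf <- adjust_pvalues(data.frame(p_raw = c(0.01, 0.5)), method = "bonferroni")
  expect_equal(bonf$p_adjusted, c(0.02, 1))
  expect_error(adjust_pvalues(data.frame(p_raw = 0.1), method = "holm"))
})

test_that("scan_signals agrees with per-pair build_table on a small world", {
  cfg <- small_config(seed = 12, n_cases = 1500, rr = 6)
  fd <- deduplicate_reports(as_case_reports(simulate_faers(cfg)))
  res <- scan_signals(fd)
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  tab <- build_table(fd, "OLANZAPINE", flags)
  row <- res[drug == "OLANZAPINE" & event == AP_PT]
  expect_equal(row$a, tab$a)
  expect_equal(row$b, tab$b)
  expect_equal(row$c, tab$c)
  expect_equal(row$d, tab$d)
  # p_adjusted is BH across all scanned pairs
  expect_equal(row$p_adjusted,
               p.adjust(res$p_raw, "BH")[which(res$drug == "OLANZAPINE" &
                                                 res$event == AP_PT)])
})

test_that("stratified scan drops missing values per variable and conserves a", {
  cfg <- small_config(seed = 13, n_cases = 3000, rr = 8)
  fd <- deduplicate_reports(as_case_reports(simulate_faers(cfg)))
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  st <- stratified_scan(fd, "OLANZAPINE", flags)
  overall_a <- st[stratum == "overall", a]
  for (v in c("sex", "age", "weight")) {
    strata_a <- st[variable == v, sum(a)]
    expect_lte(strata_a, overall_a)
  }
  # age strata miss exactly the missing-age flagged drug reports
  sel <- fd$reports$primaryid %in% select_ps_reports(fd, "OLANZAPINE")$reports$primaryid
  n_missing_age <- sum(sel & flags & is.na(fd$reports$age_years))
  expect_equal(st[variable == "age", sum(a)], overall_a - n_missing_age)
})

test_that("single-sex worlds give empty other-sex strata without crashing", {
  mix <- default_demographic_mix()
  mix$sex <- c(male = 0.9, female = 0)
  mix$sex_missing <- 0.1
  cfg <- small_config(seed = 14, n_cases = 800, rr = 5, demographic_mix = mix)
  fd <- deduplicate_reports(as_case_reports(simulate_faers(cfg)))
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  st <- stratified_scan(fd, "OLANZAPINE", flags)
  expect_equal(st[stratum == "female", a + b], 0)
  expect_false(st[stratum == "female", signal])
})

test_that("overlapping numeric bins are rejected", {
  fd <- deduplicate_reports(as_case_reports(simulate_faers(small_config(n_cases = 100))))
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  bad <- list(age = list(var = "age_years",
                         bins = list(lo = c(-Inf, 70), hi = c(65, Inf))))
  expect_error(stratified_scan(fd, "OLANZAPINE", flags, strata = bad),
               "overlapping")
})

test_that("sex-independent signals give overlapping male/female ROR CIs", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- small_config(seed = 100 + seed, n_cases = 8000, rr = 8,
                        background_rate = 0.02, duplicate_rate = 0)
    fd <- deduplicate_reports(as_case_reports(simulate_faers(cfg)))
    flags <- flag_event_cases(fd, ap_smq(), "narrow")
    st <- stratified_scan(fd, "OLANZAPINE", flags)
    lo <- st[variable == "sex", ror_lo]; hi <- st[variable == "sex", ror_hi]
    if (max(lo) <= min(hi)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
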