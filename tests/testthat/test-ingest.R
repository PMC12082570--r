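test_that("missing files and malformed headers give named errors", {
  dir <- withr::local_tempdir()
  expect_error(read_faers_tables(dir), "DEMO.txt")
  write_faers_tables(simulate_faers(small_config(n_cases = 10)), dir)
  writeLines("PRIMARYID$CASEID", file.path(dir, "REAC.txt"))
  expect_error(read_faers_tables(dir), "REAC.txt.*PT")
})

test_that("partial dates follow the configured policy", {
  fd <- mk_fd(data.frame(primaryid = c("11", "21", "31"),
                         caseid = c("1", "2", "3"),
                         event = c("2015", "201507", "20150710")))
  expect_equal(is.na(fd$reports$event_dt), c(TRUE, TRUE, FALSE))
  fd2 <- mk_fd(data.frame(primaryid = c("11", "21"), caseid = c("1", "2"),
                          event = c("2015", "201507")),
               date_policy = "pad_first")
  expect_equal(fd2$reports$event_dt,
               as.Date(c("2015-01-01", "2015-07-01")))
})

test_that("empty reaction table ingests without error", {
  fd <- mk_fd(data.frame(primaryid = "11", caseid = "1"))
  expect_equal(nrow(fd$reactions), 0L)
  expect_s3_class(fd, "faers_data")
})

test_that("unit conversions normalize age and weight", {
  fd <- mk_fd(data.frame(primaryid = c("11", "21", "31"),
                         caseid = c("1", "2", "3"),
                         age = c("600", "5", "abc"),
                         age_cod = c("MON", "DEC", "YR"),
                         wt = c("154.32", "70", ""),
                         wt_cod = c("LBS", "KG", "")))
  expect_equal(fd$reports$age_years, c(50, 50, NA))
  expect_equal(fd$reports$weight_kg, c(70.0004, 70, NA), tolerance = 1e-4)
})

test_that("dedup keeps the latest receipt, then highest version, then highest id", {
  fd <- mk_fd(data.frame(primaryid = c("421", "422"), caseid = c("42", "42"),
                         version = c("1", "2"),
                         fda = c("20200101", "20210101")))
  dd <- deduplicate_reports(fd)
  expect_equal(dd$reports$primaryid, "422")
  # receipt-date tie: version wins
  fd <- mk_fd(data.frame(primaryid = c("422", "421"), caseid = "42",
                         version = c("2", "1"), fda = "20200101"))
  expect_equal(deduplicate_reports(fd)$reports$primaryid, "422")
  # full tie: numerically highest primary id wins
  fd <- mk_fd(data.frame(primaryid = c("429", "4210"), caseid = "42",
                         version = "1", fda = "20200101"))
  expect_equal(deduplicate_reports(fd)$reports$primaryid, "4210")
})

test_that("dedup without duplicates is the identity", {
  fd <- mk_fd(data.frame(primaryid = c("11", "21", "31"),
                         caseid = c("1", "2", "3")))
  dd <- deduplicate_reports(fd)
  expect_setequal(dd$reports$primaryid, fd$reports$primaryid)
  expect_equal(dd$log$n_deduplicated, 0L)
})

test_that("dedup recovers the simulator's most-recent-version truth and is stable", {
  cfg <- small_config(seed = 3, n_cases = 2000, duplicate_rate = 0.3)
  ds <- simulate_faers(cfg)
  fd <- as_case_reports(ds)
  dd <- deduplicate_reports(fd)
  expect_setequal(dd$reports$primaryid, ds$truth$reports$primaryid)
  # idempotent
  dd2 <- deduplicate_reports(dd)
  expect_identical(dd2$reports$primaryid, dd$reports$primaryid)
  # order-independent: shuffle every raw table
  set.seed(99)
  raw <- structure(list(DEMO = ds$demo[sample(.N)], DRUG = ds$drug[sample(.N)],
                        REAC = ds$reac[sample(.N)], THER = ds$ther[sample(.N)],
                        OUTC = ds$outc[sample(.N)]), class = "faers_raw")
  dd3 <- deduplicate_reports(as_case_reports(raw))
  expect_setequal(dd3$reports$primaryid, ds$truth$reports$primaryid)
})

test_that("primary-suspect selection is role- and case-insensitive-name exact", {
  fd <- mk_fd(
    data.frame(primaryid = c("11", "21", "31"), caseid = c("1", "2", "3")),
    drugs = data.frame(primaryid = c("11", "21", "21", "31"),
                       seq = c("1", "1", "2", "1"),
                       role = c("C", "PS", "C", "PS"),
                       name = c("Olanzapine", " olanzapine ", "OTHER", "OTHER"))
  )
  sel <- select_ps_reports(fd, "OLANZAPINE")
  expect_equal(sel$reports$primaryid, "21")
})

test_that("PS counts match the simulator's planted assignment and are disjoint", {
  cfg <- small_config(seed = 6, n_cases = 3000, duplicate_rate = 0)
  ds <- simulate_faers(cfg)
  fd <- deduplicate_reports(as_case_reports(ds))
  ids <- lapply(cfg$drugs, function(dg) select_ps_reports(fd, dg)$reports$primaryid)
  for (i in seq_along(cfg$drugs))
    expect_length(ids[[i]], sum(ds$truth$reports$ps_drug == cfg$drugs[i]))
  for (i in 2:length(ids))
    expect_length(intersect(ids[[1]], ids[[i]]), 0L)
})

test_that("SMQ flagging matches scope semantics", {
  smq <- ap_smq()
  fd <- mk_fd(
    data.frame(primaryid = c("11", "21", "31"), caseid = c("1", "2", "3")),
    reacs = data.frame(primaryid = c("11", "31"),
                       pt = c("Pancreatitis acute", "Lipase increased"))
  )
  expect_equal(unname(flag_event_cases(fd, smq, "narrow")),
               c(TRUE, FALSE, FALSE))
  expect_equal(unname(flag_event_cases(fd, smq, "broad")),
               c(TRUE, FALSE, TRUE))
  expect_error(flag_event_cases(fd, smq, "wide"))
})

test_that("broad flags are a superset of narrow flags on random reaction draws", {
  set.seed(11)
  smq <- ap_smq()
  universe <- c(smq$narrow_pts, smq$broad_pts, sprintf("PT_%02d", 1:20))
  for (rep in 1:10) {
    n <- 40
    reacs <- data.frame(primaryid = as.character(rep(1:n, each = 2)),
                        pt = sample(universe, 2 * n, TRUE))
    fd <- mk_fd(data.frame(primaryid = as.character(1:n),
                           caseid = as.character(1:n)), reacs = reacs)
    narrow <- flag_event_cases(fd, smq, "narrow")
    broad <- flag_event_cases(fd, smq, "broad")
    expect_true(all(broad[narrow]))
  }
})

test_that("SMQ files parse sections and reject unknown ones", {
  p <- withr::local_tempfile(lines = c("# comment", "[narrow]",
                                       "Pancreatitis acute", "",
                                       "[broad]", "Lipase increased"))
  smq <- read_smq(p, name = "AP")
  expect_equal(smq$narrow_pts, "PANCREATITIS ACUTE")
  expect_equal(smq$broad_pts, "LIPASE INCREASED")
  bad <- withr::local_tempfile(lines = c("[wide]", "X"))
  expect_error(read_smq(bad), "section")
  expect_error(smq_definition("empty", character(0)), "narrow_pts")
})
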