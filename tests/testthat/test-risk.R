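expand_2x2 <- function(a, b, c, d) {
  data.frame(event = rep(c(1, 0, 1, 0), c(a, b, c, d)),
             x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

test_that("a saturated 2x2 logistic recovers the cross-product odds ratio", {
  fit <- fit_logistic(expand_2x2(20, 80, 100, 9800), "x")
  or <- fit$table[term == "x", or]
  expect_equal(or, 24.5, tolerance = 1e-6)
  expect_equal(fit$table$or, exp(fit$table$estimate))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("degenerate inputs raise named errors", {
  d <- expand_2x2(5, 5, 5, 5)
  d$z <- 1
  expect_error(fit_logistic(d, "z"), "degenerate covariate `z`")
  d1 <- d; d1$event <- 1
  expect_error(fit_logistic(d1, "x"), "single-class")
  # complete separation: x perfectly predicts the outcome
  sep <- data.frame(event = rep(c(1, 0), each = 50), x = rep(c(1, 0), each = 50))
  expect_error(fit_logistic(sep, "x"), "separation")
})

test_that("univariable mode fits one model per covariate and screens by p", {
  set.seed(41)
  n <- 1500
  d <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5))
  d$event <- rbinom(n, 1, plogis(-2 + 1.2 * d$x1))
  uni <- fit_logistic(d, c("x1", "x2"), mode = "univariable")
  expect_named(uni, c("x1", "x2"))
  expect_equal(nrow(attr(uni, "table")), 4L)
  # screening agrees with the per-covariate Wald p-values, and the planted
  # effect always passes
  sel <- select_covariates(uni, 0.05)
  expect_true("x1" %in% sel)
  by_hand <- names(uni)[vapply(uni, function(f)
    f$table[term != "(Intercept)", min(p)] < 0.05, logical(1))]
  expect_equal(sel, by_hand)
})

test_that("planted covariate effects are covered by the Wald CI", {
  covered <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_cases = 15000, drugs = c("DRUGX", "DRUGY"),
                      events = c(AP_PT, "PT_001", "PT_002"),
                      background_rate = 0.05,
                      risk_effects = c(weight_gt80 = 0.8),
                      duplicate_rate = 0, seed = 500 + seed)
    fd <- deduplicate_reports(as_case_reports(simulate_faers(cfg)))
    flags <- flag_event_cases(fd, ap_smq(), "narrow")
    frame <- risk_model_frame(fd, "DRUGX", flags)
    fit <- fit_logistic(frame, "weight")
    row <- fit$table[term == "weight>80"]
    if (row$or_lo <= exp(0.8) && exp(0.8) <= row$or_hi) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("the model frame encodes references and concomitant indicators", {
  fd <- mk_fd(
    data.frame(primaryid = c("11", "21", "31"), caseid = c("1", "2", "3"),
               sex = c("M", "F", "UNK"), age = c("70", "30", ""),
               age_cod = c("YR", "YR", ""), wt = c("90", "60", "75")),
    drugs = data.frame(primaryid = c("11", "11", "21", "31"),
                       seq = c("1", "2", "1", "1"),
                       role = c("PS", "C", "PS", "PS"),
                       name = c("TARGET", "ASPIRIN", "TARGET", "TARGET")),
    reacs = data.frame(primaryid = "11", pt = "Pancreatitis acute")
  )
  flags <- flag_event_cases(fd, ap_smq(), "narrow")
  fr <- risk_model_frame(fd, "TARGET", flags, concomitants = "Aspirin")
  expect_equal(levels(fr$age), c(">65", "<=65"))
  expect_equal(levels(fr$weight), c("<=80", ">80"))
  expect_equal(levels(fr$sex), c("male", "female"))
  expect_equal(fr$event, c(1L, 0L, 0L))
  expect_equal(fr$con_aspirin, c(1L, 0L, 0L))
  expect_true(is.na(fr$sex[3]) && is.na(fr$age[3]))
})

risk_demo_model <- function(seed = 77, n = 6000) {
  set.seed(seed)
  d <- data.frame(
    age = factor(sample(c(">65", "<=65"), n, TRUE), levels = c(">65", "<=65")),
    weight = factor(sample(c("<=80", ">80"), n, TRUE), levels = c("<=80", ">80")),
    sex = factor(sample(c("male", "female"), n, TRUE), levels = c("male", "female"))
  )
  lp <- -2.5 + 0.9 * (d$age == "<=65") + 0.6 * (d$weight == ">80") +
    0.3 * (d$sex == "female")
  d$event <- rbinom(n, 1, plogis(lp))
  fit_logistic(d, c("age", "weight", "sex"))
}

test_that("nomogram scaling: widest covariate spans 100 points, mapping is exact", {
  model <- risk_demo_model()
  nomo <- build_nomogram(model)
  spans <- vapply(nomo$points, max, numeric(1))
  expect_equal(max(spans), 100)
  pred <- nomogram_predict(nomo, model)
  expect_equal(pred$probability, unname(model$fitted), tolerance = 1e-9)
  # single-covariate model: that covariate spans exactly 100 points
  uni <- fit_logistic(model$data, "age")
  expect_equal(max(build_nomogram(uni)$points$age), 100)
})

test_that("nomogram point assignments are invariant to rescaling coefficients", {
  model <- risk_demo_model()
  doubled <- model
  doubled$model$coefficients <- 2 * doubled$model$coefficients
  n1 <- build_nomogram(model)
  n2 <- build_nomogram(doubled)
  for (nm in names(n1$points))
    expect_equal(n1$points[[nm]], n2$points[[nm]], tolerance = 1e-12)
})

test_that("nomogram probability map is monotone", {
  nomo <- build_nomogram(risk_demo_model())
  expect_true(all(diff(nomo$probability_map$probability) > 0))
})

test_that("AUC matches pair enumeration, tie and transform conventions", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
  expect_equal(r$auc, 5 / 6)
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  # half credit for ties
  expect_equal(roc_auc(c(1, 1), c(1, 0))$auc, 0.5)
  # invariance under strictly monotone transforms
  set.seed(6)
  s <- runif(300); y <- rbinom(300, 1, s)
  expect_equal(roc_auc(qlogis(s), y)$auc, roc_auc(s, y)$auc)
  expect_equal(roc_auc(s^3, y)$auc, roc_auc(s, y)$auc)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "single-class")
})

test_that("null scores give AUC near one half", {
  set.seed(19)
  n1 <- 400; n0 <- 600
  y <- rep(c(1, 0), c(n1, n0))
  a <- roc_auc(runif(n1 + n0), y)$auc
  sd_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * sd_null)
})

test_that("ROC curve endpoints and monotonicity", {
  set.seed(23)
  s <- runif(200); y <- rbinom(200, 1, plogis(3 * s - 1.5))
  curve <- roc_auc(s, y)$curve
  expect_true(all(diff(curve$tpr) >= 0))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
})
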