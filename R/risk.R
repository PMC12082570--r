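#' Build the per-report model frame for risk-factor modelling
#'
#' Rows are the drug's primary-suspect reports; the outcome is the target
#' event flag. Covariates follow the conventional encodings: age dichotomized
#' at `age_cut` with `>65` as reference, weight at `weight_cut` with `<=80`
#' as reference, sex with male as reference (unknown sex becomes `NA`), one
#' 0/1 indicator per requested concomitant drug (any non-PS role row with
#' that name) and one per requested comorbidity preferred term (presence
#' among the report's reactions).
#'
#' @param fd a deduplicated `"faers_data"`.
#' @param drug target drug.
#' @param event_flags logical event flags in report order (full `fd`).
#' @param concomitants character vector of concomitant drug names.
#' @param comorbidity_pts character vector of preferred terms treated as
#'   comorbidity indicators.
#' @param age_cut,weight_cut dichotomization points (years, kg).
#' @return a `data.table` with `event` (0/1) and one column per covariate;
#'   factor levels put the reference first.
#' @export
risk_model_frame <- function(fd, drug, event_flags,
                             concomitants = character(0),
                             comorbidity_pts = character(0),
                             age_cut = 65, weight_cut = 80) {
  stopifnot(inherits(fd, "faers_data"),
            length(event_flags) == nrow(fd$reports))
  ids <- ps_report_ids(fd, drug)
  sel <- fd$reports$primaryid %in% ids
  r <- fd$reports[sel]
  out <- data.table(
    primaryid = r$primaryid,
    event = as.integer(event_flags[sel]),
    age = factor(ifelse(is.na(r$age_years), NA,
                        ifelse(r$age_years <= age_cut, "<=65", ">65")),
                 levels = c(">65", "<=65")),
    weight = factor(ifelse(is.na(r$weight_kg), NA,
                           ifelse(r$weight_kg > weight_cut, ">80", "<=80")),
                    levels = c("<=80", ">80")),
    sex = factor(ifelse(r$sex %in% c("male", "female"), r$sex, NA),
                 levels = c("male", "female"))
  )
  if (length(concomitants)) {
    dr <- fd$drugs[primaryid %in% ids & (is.na(role_cod) | role_cod != "PS")]
    dn <- norm_name(dr$drugname)
    for (cm in concomitants) {
      hit <- unique(dr$primaryid[dn == norm_name(cm)])
      out[, (paste0("con_", tolower(gsub("[^A-Za-z0-9]", "_", cm)))) :=
            as.integer(primaryid %in% hit)]
    }
  }
  if (length(comorbidity_pts)) {
    re <- fd$reactions[primaryid %in% ids]
    pn <- norm_name(re$pt)
    for (pt in comorbidity_pts) {
      hit <- unique(re$primaryid[pn == norm_name(pt)])
      out[, (paste0("com_", tolower(gsub("[^A-Za-z0-9]", "_", pt)))) :=
            as.integer(primaryid %in% hit)]
    }
  }
  out[]
}

#' Fit logistic risk models
#'
#' Maximum-likelihood logistic regression of the event flag on the requested
#' covariates. `mode = "univariable"` fits one single-covariate model per
#' covariate; `mode = "multivariable"` fits the joint model. Rows with a
#' missing value in any modelled covariate are dropped (counted in
#' `n_dropped`). A covariate constant on the analysis rows raises a
#' degeneracy error naming it; complete separation (a diverging coefficient)
#' and non-convergence also error.
#'
#' @param data a [risk_model_frame()] or any data.frame with a 0/1 outcome.
#' @param covariates covariate column names.
#' @param mode `"multivariable"` or `"univariable"`.
#' @param outcome outcome column name.
#' @return for multivariable mode, a `"pv_logistic"`: coefficient table
#'   (`term`, `estimate`, `se`, `or`, `or_lo`, `or_hi`, `p`), `fitted`,
#'   the `glm` object, `n`, `n_dropped`. For univariable mode, a named list
#'   of `"pv_logistic"` objects, one per covariate, with a combined `table`
#'   attribute.
#' @export
fit_logistic <- function(data, covariates,
                         mode = c("multivariable", "univariable"),
                         outcome = "event") {
  mode <- match.arg(mode)
  dt <- as.data.table(data)
  missing_cov <- setdiff(c(outcome, covariates), names(dt))
  if (length(missing_cov))
    stop("column(s) not in data: ", paste(missing_cov, collapse = ", "))
  if (mode == "univariable") {
    fits <- lapply(covariates, function(cv)
      fit_logistic(dt, cv, mode = "multivariable", outcome = outcome))
    names(fits) <- covariates
    attr(fits, "table") <- rbindlist(lapply(fits, function(f) f$table))
    class(fits) <- "pv_logistic_list"
    return(fits)
  }

  cols <- c(outcome, covariates)
  cc <- stats::complete.cases(dt[, ..cols])
  d <- dt[cc]
  n_dropped <- sum(!cc)
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("degenerate covariate `", cv, "`: constant on the analysis rows")
  }
  if (length(unique(d[[outcome]])) < 2L)
    stop("outcome is single-class on the analysis rows")

  f <- stats::as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  fit <- glm(f, family = binomial(), data = d)
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " IRLS iterations")
  est <- coef(fit)
  if (any(!is.finite(est)) || any(abs(est[-1]) > 15)) {
    bad <- names(est)[-1][!is.finite(est[-1]) | abs(est[-1]) > 15]
    stop("complete or quasi-complete separation on covariate(s): ",
         paste(bad, collapse = ", "))
  }
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  tab <- data.table(
    term = names(est), estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    or_lo = exp(unname(est - 1.96 * se)),
    or_hi = exp(unname(est + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(list(table = tab, fitted = fit$fitted.values, model = fit,
                 covariates = covariates, outcome = outcome,
                 n = nrow(d), n_dropped = n_dropped, data = d),
            class = "pv_logistic")
}

#' @export
print.pv_logistic <- function(x, ...) {
  cat("<logistic risk model>", x$n, "reports (", x$n_dropped, "dropped )\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Select covariates by univariable screening
#'
#' The conventional rule: covariates with univariable Wald p below `p_cut`
#' enter the multivariable model.
#'
#' @param uni a `"pv_logistic_list"` from univariable [fit_logistic()].
#' @param p_cut inclusion threshold.
#' @return character vector of selected covariate names.
#' @export
select_covariates <- function(uni, p_cut = 0.05) {
  stopifnot(inherits(uni, "pv_logistic_list"))
  sel <- vapply(names(uni), function(cv) {
    tb <- uni[[cv]]$table
    any(tb$p[tb$term != "(Intercept)"] < p_cut)
  }, logical(1))
  names(uni)[sel]
}

#' Rescale a fitted logistic model to nomogram points
#'
#' Each covariate level's coefficient is shifted so its smallest level scores
#' 0 points and scaled so the covariate with the widest coefficient span gets
#' exactly 100 points; the intercept plus the per-covariate shifts become a
#' base linear predictor, so total points map exactly through the inverse
#' logit back to the model's fitted probability. The mapping is invariant to
#' rescaling all coefficients jointly.
#'
#' @param model a multivariable `"pv_logistic"`.
#' @return class `"pv_nomogram"`: `points` (named list: per covariate, a
#'   named vector of points per level), `points_per_unit`, `base_lp`, and a
#'   monotone `probability_map` data.table (total points to probability).
#' @export
build_nomogram <- function(model) {
  stopifnot(inherits(model, "pv_logistic"))
  fit <- model$model
  est <- coef(fit)
  assign_idx <- attr(stats::model.matrix(fit), "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  contribs <- list()
  for (j in seq_along(terms_lab)) {
    coefs_j <- est[assign_idx == j]
    # reference level contributes 0
    lv <- c("(ref)" = 0, coefs_j)
    contribs[[terms_lab[j]]] <- lv
  }
  spans <- vapply(contribs, function(v) diff(range(v)), numeric(1))
  if (all(spans == 0)) stop("all covariates have zero coefficient span")
  k <- 100 / max(spans)
  points <- lapply(contribs, function(v) (v - min(v)) * k)
  base_lp <- unname(est["(Intercept)"]) +
    sum(vapply(contribs, min, numeric(1)))
  max_total <- sum(vapply(points, max, numeric(1)))
  grid <- seq(0, max_total, length.out = 101)
  probability_map <- data.table(total_points = grid,
                                probability = plogis(base_lp + grid / k))
  structure(list(points = points, points_per_unit = k, base_lp = base_lp,
                 probability_map = probability_map),
            class = "pv_nomogram")
}

#' @export
print.pv_nomogram <- function(x, ...) {
  cat("<nomogram>", length(x$points), "covariates; 100 points =",
      sprintf("%.3f on the log-odds scale\n", 100 / x$points_per_unit))
  invisible(x)
}

#' Score rows through a nomogram
#'
#' @param nomo a [build_nomogram()] result.
#' @param model the `"pv_logistic"` it was built from.
#' @param newdata rows to score (defaults to the model's analysis rows).
#' @return a list with `total_points` and `probability` per row; the
#'   probability equals the model's fitted probability exactly.
#' @export
nomogram_predict <- function(nomo, model, newdata = NULL) {
  stopifnot(inherits(nomo, "pv_nomogram"), inherits(model, "pv_logistic"))
  d <- if (is.null(newdata)) model$data else as.data.table(newdata)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(model$model)),
                            data = d)
  assign_idx <- attr(mm, "assign")
  est <- coef(model$model)
  total <- rep(0, nrow(mm))
  for (j in seq_along(nomo$points)) {
    cols <- which(assign_idx == j)
    contrib <- as.vector(mm[, cols, drop = FALSE] %*% est[cols])
    # the covariate's minimum contribution (reference included) scores 0 points
    shift <- min(c(0, est[cols]))
    total <- total + (contrib - shift) * nomo$points_per_unit
  }
  prob <- plogis(nomo$base_lp + total / nomo$points_per_unit)
  list(total_points = total, probability = prob)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) AUC with the half-credit tie convention, plus
#' the ROC curve evaluated at every distinct score threshold.
#'
#' @param scores numeric risk scores (higher means more likely positive), or
#'   a `"pv_logistic"` (its fitted probabilities are used).
#' @param labels 0/1 (or logical) outcomes; omitted when `scores` is a model.
#' @return a list with `auc` and `curve` (`data.table`: threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, labels = NULL) {
  if (inherits(scores, "pv_logistic")) {
    labels <- scores$data[[scores$outcome]]
    scores <- unname(scores$fitted)
  }
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("single-class outcome: AUC is undefined")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)  # average ranks give the 0.5 tie credit
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ys); cum_fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)
  curve <- data.table(threshold = ss[last],
                      tpr = cum_tp[last] / n1,
                      fpr = cum_fp[last] / n0)
  list(auc = auc, curve = curve)
}
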