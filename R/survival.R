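# Normalize an event column to the survival-package 0/1 convention
# (1 = death). Accepts 0/1 integers, logicals, or a factor/character of
# "death"/"censored".
normalize_event <- function(event) {
  if (is.factor(event) || is.character(event)) {
    ev <- as.character(event)
    if (!all(ev %in% c("death", "censored"))) {
      abort("Character/factor events must be 'death' or 'censored'.",
        class = "mtvsurv_invalid_argument")
    }
    return(as.integer(ev == "death"))
  }
  ev <- as.integer(event)
  if (anyNA(ev) || !all(ev %in% c(0L, 1L))) {
    abort("Events must be 0/1, logical, or death/censored.",
      class = "mtvsurv_invalid_argument")
  }
  ev
}

#' Cox proportional-hazards regression for overall survival
#'
#' Fits a Cox model by partial likelihood with Efron tie handling and
#' reports hazard ratios with Wald 95% confidence intervals, the format of
#' clinical prognostic-factor tables. One covariate gives the univariable
#' model; several give the multivariable model.
#'
#' @param data Cohort data frame (one row per patient).
#' @param covariates Character vector of covariate column names. Factors are
#'   expanded to treatment contrasts by the model matrix.
#' @param time,event Names of the survival-time (months) and event columns.
#'   Events may be 0/1, logical, or `"death"`/`"censored"`.
#' @return An object of class `mtv_cox` wrapping the [survival::coxph()]
#'   fit; use [tidy()] for the coefficient table and [glance()] for model
#'   summaries.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200, seed = 1))$records |>
#'   add_composite()
#' fit <- fit_cox(cohort, c("mtv_cga_composite", "age"))
#' tidy(fit)
#' @export
fit_cox <- function(data, covariates, time = "os_months", event = "event") {
  stopifnot(is.data.frame(data), length(covariates) >= 1L)
  missing_cols <- setdiff(c(covariates, time, event), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "mtvsurv_invalid_argument")
  }
  df <- droplevels(as.data.frame(data[, c(time, event, covariates)]))
  df[[event]] <- normalize_event(df[[event]])
  if (any(!is.finite(df[[time]])) || any(df[[time]] <= 0)) {
    abort("Survival times must be finite and > 0.",
      class = "mtvsurv_invalid_argument")
  }
  if (sum(df[[event]]) < 2L) {
    abort("Cox regression needs at least 2 events.",
      class = "mtvsurv_degenerate_model")
  }
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v) && any(!is.finite(v))) {
      abort(sprintf("Covariate '%s' has non-finite values.", cv),
        class = "mtvsurv_invalid_argument")
    }
    if (length(unique(v)) < 2L) {
      abort(sprintf("Covariate '%s' is constant.", cv),
        class = "mtvsurv_invalid_argument")
    }
  }
  n_events <- sum(df[[event]])
  if (n_events < 10 * length(covariates)) {
    warn(sprintf(
      "Only %d events for %d covariate(s); Cox estimates may be unstable (rule of thumb: >= 10 events per covariate).",
      n_events, length(covariates)))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  conv_warnings <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", x = TRUE),
    warning = function(w) {
      conv_warnings <<- c(conv_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # monotone likelihood drives a coefficient to +/- infinity
  if (any(!is.finite(fit$coefficients)) || any(abs(fit$coefficients) > 15) ||
      any(grepl("converge|infinite", conv_warnings))) {
    abort(paste(c("Cox model did not converge (possible separation).",
      conv_warnings), collapse = " "),
      class = "mtvsurv_convergence_error")
  }
  structure(
    list(fit = fit, covariates = covariates, time = time, event = event,
      n = nrow(df), n_events = n_events),
    class = "mtv_cox"
  )
}

#' @export
print.mtv_cox <- function(x, ...) {
  cat(sprintf("<mtv_cox> %d patients, %d events; covariates: %s\n",
    x$n, x$n_events, paste(x$covariates, collapse = ", ")))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy the coefficient table of a Cox fit
#'
#' @param x An `mtv_cox` object from [fit_cox()].
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate` (log
#'   hazard ratio), `std.error`, `statistic`, `p.value`, `hazard_ratio`,
#'   `conf.low`, `conf.high` (95% Wald interval on the HR scale).
#' @method tidy mtv_cox
#' @export
tidy.mtv_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    std.error = co[, "se(coef)"],
    statistic = co[, "z"],
    p.value = co[, "Pr(>|z|)"],
    hazard_ratio = exp(co[, "coef"]),
    conf.low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
    conf.high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"])
  )
}

#' @rdname tidy.mtv_cox
#' @return `glance()` returns a one-row tibble with `n`, `n_events`,
#'   `concordance`, `logLik`, and the likelihood-ratio test statistic and
#'   p-value.
#' @method glance mtv_cox
#' @export
glance.mtv_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n,
    n_events = x$n_events,
    concordance = unname(s$concordance["C"]),
    logLik = unname(stats::logLik(x$fit)),
    statistic.log = unname(s$logtest["test"]),
    p.value.log = unname(s$logtest["pvalue"])
  )
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Tests, per covariate and globally, whether the scaled Schoenfeld
#' residuals trend with time — the standard diagnostic for a time-varying
#' hazard ratio.
#'
#' @param fit An `mtv_cox` object from [fit_cox()].
#' @param transform Time transform handed to [survival::cox.zph()];
#'   default `"km"`.
#' @return Tibble with `term`, `chisq`, `df`, `p.value`; the last row is
#'   `GLOBAL`.
#' @export
ph_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "mtv_cox"))
  if (fit$n_events < 2L) {
    abort("Proportional-hazards test needs >= 2 events.",
      class = "mtvsurv_insufficient_data")
  }
  z <- survival::cox.zph(fit$fit, transform = transform)
  tb <- z$table
  tibble(
    term = rownames(tb),
    chisq = tb[, "chisq"],
    df = tb[, "df"],
    p.value = tb[, "p"]
  )
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator, optionally stratified by a grouping column.
#'
#' @inheritParams fit_cox
#' @param group Optional name of a grouping column for stratified curves.
#' @return An object of class `mtv_km` wrapping the [survival::survfit()]
#'   object; `tidy()` gives the step-curve table, [survival_at()] evaluates
#'   the curve, [autoplot()] draws it.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 7))$records
#' km <- km_estimate(cohort)
#' survival_at(km, 60)
#' @export
km_estimate <- function(data, time = "os_months", event = "event",
                        group = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  df <- as.data.frame(data)
  df$.event <- normalize_event(df[[event]])
  df$.time <- df[[time]]
  if (any(!is.finite(df$.time)) || any(df$.time <= 0)) {
    abort("Survival times must be finite and > 0.",
      class = "mtvsurv_invalid_argument")
  }
  fml <- if (is.null(group)) {
    survival::Surv(.time, .event) ~ 1
  } else {
    stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", group))
  }
  sf <- survival::survfit(fml, data = df, conf.type = "log-log")
  structure(list(fit = sf, group = group, n = nrow(df)), class = "mtv_km")
}

#' @export
print.mtv_km <- function(x, ...) {
  cat(sprintf("<mtv_km> Kaplan-Meier curve, n = %d%s\n", x$n,
    if (is.null(x$group)) "" else paste0(", grouped by ", x$group)))
  print(x$fit, ...)
  invisible(x)
}

#' @method tidy mtv_km
#' @export
tidy.mtv_km <- function(x, ...) {
  sf <- x$fit
  out <- tibble(
    time = sf$time,
    n.risk = sf$n.risk,
    n.event = sf$n.event,
    n.censor = sf$n.censor,
    estimate = sf$surv,
    conf.low = sf$lower,
    conf.high = sf$upper
  )
  if (!is.null(sf$strata)) {
    out$strata <- rep(names(sf$strata), sf$strata)
  }
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step convention: `S(t)` is the estimate just after the
#' last event time `<= t`, and 1 before the first event.
#'
#' @param curve An `mtv_km` object (must be ungrouped).
#' @param t Times in months. Vectorized.
#' @return Survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "mtv_km"))
  if (!is.null(curve$group)) {
    abort("`survival_at()` expects an ungrouped curve.",
      class = "mtvsurv_invalid_argument")
  }
  sf <- curve$fit
  fn <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  fn(t)
}

#' Log-rank comparison of two or more survival curves
#'
#' @inheritParams fit_cox
#' @param group Name of the grouping column.
#' @return One-row tibble with `statistic` (chi-squared), `df`, `p.value`.
#' @export
logrank_test <- function(data, group, time = "os_months", event = "event") {
  df <- as.data.frame(data)
  df$.event <- normalize_event(df[[event]])
  df$.time <- df[[time]]
  g <- df[[group]]
  if (length(unique(g)) < 2L || any(table(g) == 0)) {
    abort("Log-rank needs >= 2 non-empty groups.",
      class = "mtvsurv_invalid_argument")
  }
  if (sum(df$.event) < 1L) {
    abort("Log-rank needs at least one event.",
      class = "mtvsurv_invalid_argument")
  }
  fml <- stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", group))
  sdf <- survival::survdiff(fml, data = df)
  df_stat <- length(sdf$n) - 1L
  tibble(
    statistic = sdf$chisq,
    df = df_stat,
    p.value = stats::pchisq(sdf$chisq, df_stat, lower.tail = FALSE)
  )
}

# Empirical AUC by the rank (Mann-Whitney) statistic; ties count 1/2.
empirical_auc <- function(cases, controls) {
  r <- rank(c(cases, controls))
  m <- length(cases)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(controls))
}

# DeLong variance of the empirical AUC via placement values.
delong_se <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  psi <- outer(cases, controls, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)   # per-case placements
  v01 <- colMeans(psi)   # per-control placements
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' Fixed-horizon ROC analysis of a prognostic marker
#'
#' Dichotomizes overall survival at a horizon (default 60 months, i.e.
#' 5-year survival): patients who die on or before the horizon are cases,
#' patients followed beyond it are controls, and patients censored before
#' the horizon without an event carry no outcome information at the horizon
#' and are excluded. The empirical ROC of the marker against this binary
#' outcome is computed assuming higher marker values indicate the poorer
#' outcome; the optimal cutoff maximizes Youden's J = sensitivity +
#' specificity - 1, with ties broken toward higher specificity. Candidate
#' cutoffs are midpoints between consecutive distinct marker values (plus
#' open ends), so a reported cutoff of e.g. 112.5 means "marker > 112.5".
#' The AUC confidence interval and the p-value against AUC = 0.5 use the
#' DeLong variance estimate; for very small groups (fewer than 5 cases or
#' controls) a 2000-replicate stratified bootstrap is used instead.
#'
#' @inheritParams fit_cox
#' @param marker Name of the marker column (higher = worse prognosis).
#' @param horizon Horizon in months. Default 60.
#' @return An object of class `mtv_roc` with `auc`, `auc_ci95`, `p.value`,
#'   `cutoff`, `sensitivity`, `specificity`, `n_cases`, `n_controls`, and
#'   the full `curve` tibble; `tidy()` returns the curve, `glance()` the
#'   summary row.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200, seed = 3))$records
#' roc <- roc_fixed_horizon(cohort, "mtv_ml")
#' glance(roc)
#' @export
roc_fixed_horizon <- function(data, marker, time = "os_months",
                              event = "event", horizon = 60) {
  df <- as.data.frame(data)
  ev <- normalize_event(df[[event]])
  tm <- df[[time]]
  mk <- df[[marker]]
  if (!is.finite(horizon) || horizon <= 0) {
    abort("`horizon` must be > 0 months.", class = "mtvsurv_invalid_argument")
  }
  case <- ev == 1L & tm <= horizon
  control <- tm > horizon
  keep <- case | control
  mk <- mk[keep]; case <- case[keep]
  if (any(!is.finite(mk))) {
    abort("Marker values must be finite.", class = "mtvsurv_invalid_argument")
  }
  cases <- mk[case]; controls <- mk[!case]
  m <- length(cases); n <- length(controls)
  if (m < 1L || n < 1L) {
    abort("Fixed-horizon ROC needs at least one case and one control.",
      class = "mtvsurv_degenerate_outcome")
  }
  auc <- empirical_auc(cases, controls)
  # candidate cutoffs: midpoints between distinct marker values, open ends
  uv <- sort(unique(mk))
  cuts <- c(min(uv) - 1, (head(uv, -1) + uv[-1]) / 2, max(uv) + 1)
  sens <- vapply(cuts, function(cc) mean(cases > cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(controls <= cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])] # ties toward higher specificity
  if (m >= 5L && n >= 5L) {
    se <- delong_se(cases, controls)
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
    p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
    ci_method <- "delong"
  } else {
    boot <- replicate(2000, {
      empirical_auc(sample(cases, m, replace = TRUE),
        sample(controls, n, replace = TRUE))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975)))
    se <- stats::sd(boot)
    p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
    ci_method <- "bootstrap"
  }
  structure(
    list(
      auc = auc, auc_ci95 = ci, p.value = p,
      cutoff = cuts[best], sensitivity = sens[best], specificity = spec[best],
      n_cases = m, n_controls = n, horizon = horizon, marker = marker,
      ci_method = ci_method,
      curve = tibble(cutoff = cuts, sensitivity = sens, specificity = spec)
    ),
    class = "mtv_roc"
  )
}

#' @export
print.mtv_roc <- function(x, ...) {
  cat(sprintf(
    "<mtv_roc> %s at %g-month horizon: AUC %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
    x$marker, x$horizon, x$auc, x$auc_ci95[1], x$auc_ci95[2], x$p.value))
  cat(sprintf("  optimal cutoff > %.4g: sensitivity %.2f, specificity %.2f (%d cases / %d controls)\n",
    x$cutoff, x$sensitivity, x$specificity, x$n_cases, x$n_controls))
  invisible(x)
}

#' @method tidy mtv_roc
#' @export
tidy.mtv_roc <- function(x, ...) x$curve

#' @method glance mtv_roc
#' @export
glance.mtv_roc <- function(x, ...) {
  tibble(
    marker = x$marker, horizon = x$horizon,
    auc = x$auc, conf.low = x$auc_ci95[1], conf.high = x$auc_ci95[2],
    p.value = x$p.value, cutoff = x$cutoff,
    sensitivity = x$sensitivity, specificity = x$specificity,
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}

#' Mann-Whitney U comparison of two samples
#'
#' Two-sided Wilcoxon rank-sum test (exact for small tie-free samples,
#' normal approximation otherwise), the standard comparison for non-normal
#' SUV distributions between responders and non-responders.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return One-row tibble with `statistic` (U) and `p.value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.",
      class = "mtvsurv_invalid_argument")
  }
  wt <- suppressWarnings(wilcox.test(a, b, exact = NULL))
  tibble(statistic = unname(wt$statistic), p.value = wt$p.value)
}
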