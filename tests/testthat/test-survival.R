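sim_simple <- function(n, beta = 0.7, seed = 1, cens = 0) {
  set.seed(seed)
  x <- rnorm(n)
  t <- rexp(n, 0.02 * exp(beta * x))
  cmax <- if (cens > 0) rexp(n, cens) else Inf
  tibble::tibble(
    os_months = pmin(t, cmax) + 1e-9,
    event = as.integer(t <= cmax),
    x = x)
}

test_that("Cox estimate matches a brute-force partial-likelihood grid", {
  df <- tibble::tibble(
    os_months = c(2, 5, 8, 11, 14),
    event = c(1L, 1L, 0L, 1L, 0L),
    x = c(1.2, -0.4, 0.5, -1.0, 0.3))
  fit <- suppressWarnings(fit_cox(df, "x"))
  oracle <- cox_pl_grid_oracle(df$os_months, df$event, df$x)
  expect_equal(tidy(fit)$estimate, oracle, tolerance = 1e-3)
})

test_that("Cox recovers a known log hazard ratio on simulated data", {
  df <- sim_simple(2000, beta = 0.98, seed = 4, cens = 0.01)
  est <- tidy(fit_cox(df, "x"))
  expect_lt(abs(est$estimate - 0.98), 0.12)
  expect_equal(est$hazard_ratio, exp(est$estimate))
  expect_true(est$conf.low <= est$hazard_ratio &&
    est$hazard_ratio <= est$conf.high)
})

test_that("Cox estimates rescale with affine covariate rescaling", {
  df <- sim_simple(400, beta = 0.5, seed = 9)
  b1 <- tidy(fit_cox(df, "x"))$estimate
  df$x10 <- df$x * 10
  expect_equal(tidy(fit_cox(df, "x10"))$estimate, b1 / 10, tolerance = 1e-6)
})

test_that("degenerate Cox inputs raise classed errors", {
  df <- sim_simple(50, seed = 2)
  df0 <- df; df0$event <- 0L
  expect_error(fit_cox(df0, "x"), class = "mtvsurv_degenerate_model")
  dfc <- df; dfc$x <- 1
  expect_error(fit_cox(dfc, "x"), class = "mtvsurv_invalid_argument")
  # perfect separation: the largest covariate values all fail first
  dfs <- tibble::tibble(os_months = c(1, 2, 3, 10, 11, 12),
    event = c(1L, 1L, 1L, 0L, 0L, 0L), x = c(5, 5, 5, -5, -5, -5))
  expect_error(suppressWarnings(fit_cox(dfs, "x")),
    class = "mtvsurv_convergence_error")
  few <- df[1:30, ]
  few$event <- c(rep(1L, 4), rep(0L, 26))
  expect_warning(fit_cox(few, "x"), "events")
})

test_that("Schoenfeld test agrees with an independent score-test oracle", {
  df <- sim_simple(150, beta = 0.6, seed = 11)
  fit <- fit_cox(df, "x")
  ours <- ph_test(fit, transform = "identity")
  oracle <- zph_score_oracle(fit$fit)
  expect_equal(unname(ours$p.value[ours$term == "x"]), oracle$p,
    tolerance = 1e-6)
  expect_equal(unname(ours$chisq[ours$term == "x"]), oracle$chisq,
    tolerance = 1e-6)
})

test_that("Schoenfeld test flags a sign-reversing effect", {
  set.seed(21)
  n <- 500
  x <- rnorm(n)
  m <- 35 # effect reverses at the typical median follow-up
  t1 <- rexp(n, (1 / 60) * exp(x))
  t <- ifelse(t1 < m, t1, m + rexp(n, (1 / 60) * exp(-x)))
  df <- tibble::tibble(os_months = t, event = 1L, x = x)
  p <- ph_test(fit_cox(df, "x"))$p.value[1]
  expect_lt(p, 0.05)
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  df <- tibble::tibble(os_months = c(1, 2, 3, 4), event = 1L)
  km <- km_estimate(df)
  expect_equal(survival_at(km, 2.5), 0.5)
  expect_equal(survival_at(km, 0.5), 1)
  expect_equal(survival_at(km, 4), 0)
  # right-continuous step convention: value at an event time is post-jump
  expect_equal(survival_at(km, 2), 0.5)
  set.seed(14)
  t <- round(rexp(60, 0.05), 1) + 0.1
  km2 <- km_estimate(tibble::tibble(os_months = t, event = 1L))
  grid <- seq(0.1, 50, by = 0.7)
  emp <- vapply(grid, function(g) mean(t > g), numeric(1))
  expect_equal(survival_at(km2, grid), emp)
})

test_that("all-censored data give a flat survival curve at 1", {
  km <- km_estimate(tibble::tibble(os_months = c(5, 10, 20), event = 0L))
  expect_equal(survival_at(km, c(1, 10, 100)), c(1, 1, 1))
})

test_that("KM curve invariants hold on simulated cohorts", {
  co <- generate_cohort(cohort_config(n = 150, seed = 31))$records
  km <- km_estimate(co)
  tb <- tidy(km)
  expect_true(all(diff(tb$estimate) <= 1e-12))
  expect_true(all(tb$estimate >= 0 & tb$estimate <= 1))
  expect_equal(survival_at(km, 0), 1)
})

test_that("log-rank is zero for identical groups and detects separation", {
  base <- tibble::tibble(os_months = c(3, 6, 9, 12, 15), event = c(1L, 1L, 0L, 1L, 1L))
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, grp = "a"),
    dplyr::mutate(base, grp = "b"))
  res <- logrank_test(dup, "grp")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)

  set.seed(17)
  strong <- tibble::tibble(
    os_months = c(rexp(100, 0.03), rexp(100, 0.09)),
    event = 1L,
    grp = rep(c("lo", "hi"), each = 100))
  expect_lt(logrank_test(strong, "grp")$p.value, 0.01)
  expect_error(logrank_test(dplyr::mutate(base, grp = "a"), "grp"),
    class = "mtvsurv_invalid_argument")
})

test_that("log-rank p matches the Cox score test asymptotically", {
  set.seed(19)
  df <- tibble::tibble(
    os_months = c(rexp(400, 0.03), rexp(400, 0.05)),
    event = rbinom(800, 1, 0.8),
    grp = rep(c(0, 1), each = 400))
  df$os_months <- df$os_months + 1e-9
  lr <- logrank_test(df, "grp")$p.value
  sc <- summary(fit_cox(df, "grp")$fit)$sctest["pvalue"]
  expect_equal(lr, unname(sc), tolerance = 1e-2)
})

test_that("fixed-horizon ROC handles degenerate and perfect markers", {
  df <- tibble::tibble(
    marker = rep(1, 20),
    os_months = c(rep(20, 10), rep(90, 10)),
    event = c(rep(1L, 10), rep(0L, 10)))
  r <- roc_fixed_horizon(df, "marker")
  expect_equal(r$auc, 0.5)
  perfect <- tibble::tibble(
    marker = c(rep(5, 10), rep(1, 10)),
    os_months = c(rep(20, 10), rep(90, 10)),
    event = c(rep(1L, 10), rep(0L, 10)))
  rp <- roc_fixed_horizon(perfect, "marker")
  expect_equal(rp$auc, 1.0)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)
  expect_true(rp$cutoff > 1 && rp$cutoff < 5)
  # no controls after dichotomization
  allcase <- tibble::tibble(marker = 1:5, os_months = rep(10, 5),
    event = rep(1L, 5))
  expect_error(roc_fixed_horizon(allcase, "marker"),
    class = "mtvsurv_degenerate_outcome")
})

test_that("patients censored before the horizon are excluded from the ROC", {
  df <- tibble::tibble(
    marker = c(10, 9, 8, 1, 2, 100),
    os_months = c(20, 30, 40, 80, 90, 30),
    event = c(1L, 1L, 1L, 0L, 0L, 0L)) # last row: censored at 30, no event
  r <- roc_fixed_horizon(df, "marker")
  expect_equal(r$n_cases, 3)
  expect_equal(r$n_controls, 2)
  expect_equal(r$auc, 1)
})

test_that("ROC AUC is invariant under strictly monotone marker transforms", {
  co <- generate_cohort(cohort_config(n = 150, seed = 23))$records
  r1 <- roc_fixed_horizon(co, "mtv_ml")
  co$mtv_log <- log(co$mtv_ml)
  r2 <- roc_fixed_horizon(co, "mtv_log")
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_identical(r1$specificity, r2$specificity)
})

test_that("empirical AUC and DeLong interval match pROC", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_config(n = 250, seed = 29))$records
  r <- roc_fixed_horizon(co, "mtv_ml")
  keep <- (co$event == 1 & co$os_months <= 60) | co$os_months > 60
  outcome <- as.integer(co$event == 1 & co$os_months <= 60)[keep]
  pr <- pROC::roc(outcome, co$mtv_ml[keep], direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci95, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("Youden ties break toward higher specificity", {
  # two cutoffs reach J = 0.5; the higher one has better specificity
  df <- tibble::tibble(
    marker = c(1, 2, 3, 4, 2, 3, 4, 5),
    os_months = c(rep(90, 4), rep(20, 4)),
    event = c(rep(0L, 4), rep(1L, 4)))
  r <- roc_fixed_horizon(df, "marker")
  curve <- tidy(r)
  j <- curve$sensitivity + curve$specificity - 1
  best_spec <- max(curve$specificity[j == max(j)])
  expect_equal(r$specificity, best_spec)
})

test_that("Mann-Whitney handles identity, separation and ties", {
  a <- c(1.2, 3.4, 5.6, 7.8)
  expect_gte(mann_whitney(a, a)$p.value, 0.99)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_error(mann_whitney(numeric(0), a), class = "mtvsurv_invalid_argument")
  res <- mann_whitney(rnorm(30), rnorm(30))
  expect_true(res$p.value >= 0 && res$p.value <= 1)
})
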