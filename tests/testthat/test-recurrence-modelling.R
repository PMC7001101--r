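test_that("logistic fitter recovers closed-form and null cases", {
  d <- data.frame(recurrence = c(rep(1, 17), rep(0, 51)))
  m <- fit_logistic(d, character(0))
  expect_equal(unname(m$coefficients["(Intercept)"]), log(17 / 51),
               tolerance = 1e-8)
  expect_equal(m$aic, m$deviance + 2 * (length(m$terms) + 1))

  set.seed(20)
  d2 <- data.frame(x = rnorm(5000), recurrence = rbinom(5000, 1, 0.3))
  m2 <- fit_logistic(d2, "x")
  expect_lt(abs(unname(m2$coefficients["x"])), 0.06)

  expect_error(fit_logistic(data.frame(recurrence = rep(1, 10)), character(0)),
               "single class")
  expect_error(fit_logistic(data.frame(recurrence = c(0, 1), x = 1:2), "x"),
               "too small")
})

test_that("complete separation raises the flag rather than a silent fit", {
  d <- data.frame(x = c(1:5, 11:15),
                  recurrence = c(rep(0, 5), rep(1, 5)))
  m <- fit_logistic(d, "x")
  expect_true(m$separation)
  expect_false(m$converged)
})

test_that("stepwise AIC equals exhaustive best-subset search for <= 3 candidates", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 120
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    lp <- -1 + 1.2 * d$x1 + 0.4 * d$x2
    d$recurrence <- rbinom(n, 1, plogis(lp))
    sel <- stepwise_aic(c("x1", "x2", "x3"), d)
    subsets <- unlist(lapply(0:3, function(k)
      utils::combn(c("x1", "x2", "x3"), k, simplify = FALSE)), recursive = FALSE)
    aics <- vapply(subsets, function(s) fit_logistic(d, s)$aic, numeric(1))
    expect_equal(sort(sel$terms), sort(subsets[[which.min(aics)]]))
    expect_equal(sel$aic, min(aics), tolerance = 1e-9)
  }
})

test_that("stepwise selection finds signal and rejects pure noise", {
  # Closed-form oracle for the null behaviour: a noise term enters iff its
  # deviance drop exceeds 2, i.e. with probability P(chi2_1 > 2) = 0.157;
  # with two independent noise candidates the intercept-only model is kept
  # with probability ~0.843^2 = 0.711. Assertions sit 3 binomial SEs below
  # the oracle values (200 draws: se ~ 0.032).
  set.seed(22)
  n_draws <- 200
  picks <- t(vapply(seq_len(n_draws), function(i) {
    n <- 500
    d <- data.frame(signal = rnorm(n), noise = rnorm(n))
    d$recurrence <- rbinom(n, 1, plogis(-1.5 + 1.5 * d$signal))
    sel <- stepwise_aic(c("signal", "noise"), d)
    c(has_signal = "signal" %in% sel$terms,
      only_signal = identical(sel$terms, "signal"))
  }, logical(2)))
  expect_gte(mean(picks[, "has_signal"]), 0.99)
  p_noise_out <- pchisq(2, 1)             # 0.843
  expect_gte(mean(picks[, "only_signal"]),
             p_noise_out - 3 * sqrt(p_noise_out * (1 - p_noise_out) / n_draws))

  null_only <- vapply(seq_len(n_draws), function(i) {
    n <- 500
    d <- data.frame(n1 = rnorm(n), n2 = rnorm(n))
    d$recurrence <- rbinom(n, 1, 0.15)
    length(stepwise_aic(c("n1", "n2"), d)$terms) == 0
  }, logical(1))
  p_null <- pchisq(2, 1)^2                # 0.711
  expect_gte(mean(null_only), p_null - 3 * sqrt(p_null * (1 - p_null) / n_draws))

  # final AIC never exceeds the intercept-only AIC
  set.seed(23)
  d <- data.frame(a = rnorm(200), b = rnorm(200),
                  recurrence = rbinom(200, 1, 0.2))
  sel <- stepwise_aic(c("a", "b"), d)
  expect_lte(sel$aic, fit_logistic(d, character(0))$aic + 1e-9)
})

test_that("ROC analysis matches pair enumeration, symmetry and Youden", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])

  r_flip <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0))
  expect_equal(r_flip$auc, 1 - r$auc)

  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$threshold, 10)  # lowest threshold achieving max J

  set.seed(24)
  for (i in 1:10) {
    sc <- round(rnorm(40), 1)  # rounding forces ties
    lb <- rbinom(40, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, with_threshold = FALSE)$auc,
                 oracle_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("DeLong CIs tighten with sample size and stay ordered", {
  set.seed(25)
  width <- function(n) {
    x <- c(rnorm(n / 2), rnorm(n / 2, 1))
    y <- rep(0:1, each = n / 2)
    r <- roc_auc(x, y, with_threshold = FALSE)
    expect_true(r$ci[1] <= r$ci[2])
    expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
    r$ci[2] - r$ci[1]
  }
  expect_lt(width(500), width(50))
})

test_that("Somers' D and AUC are exact transforms of one another", {
  set.seed(26)
  for (i in 1:20) {
    sc <- rnorm(30)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    d <- somers_d(sc, lb)
    a <- roc_auc(sc, lb, with_threshold = FALSE)$auc
    expect_equal(d, 2 * a - 1, tolerance = 1e-12)
    expect_equal(a, (1 + d) / 2, tolerance = 1e-12)
  }
  expect_equal(somers_d(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("likelihood-ratio test is a calibrated nested-model chi-square", {
  set.seed(27)
  d <- data.frame(x = rnorm(100), recurrence = rbinom(100, 1, 0.3))
  m0 <- fit_logistic(d, character(0))
  m1 <- fit_logistic(d, "x")
  lrt <- likelihood_ratio_test(m0, m1)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$delta_deviance, m0$deviance - m1$deviance)
  expect_equal(lrt$p, pchisq(lrt$delta_deviance, 1, lower.tail = FALSE))

  self <- likelihood_ratio_test(m1, m1)
  expect_equal(self$delta_deviance, 0)
  expect_equal(self$p, 1)

  d$z <- rnorm(100)
  m2 <- fit_logistic(d, "z")
  expect_error(likelihood_ratio_test(m2, m1), "not nested")

  # null p-values are uniform: KS distance below 0.05 over 500 draws
  set.seed(28)
  ps <- vapply(1:500, function(i) {
    dd <- data.frame(x = rnorm(200), recurrence = rbinom(200, 1, 0.3))
    likelihood_ratio_test(fit_logistic(dd, character(0)),
                          fit_logistic(dd, "x"))$p
  }, numeric(1))
  ks <- max(abs(sort(ps) - ppoints(500, a = 0)))
  expect_lt(ks, 0.05)
})

test_that("bootstrap validation is reproducible and near-zero-optimism when easy", {
  set.seed(29)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$recurrence <- rbinom(n, 1, plogis(-1 + 2.5 * d$x))  # true AUC ~ 0.9
  v1 <- bootstrap_validate("x", d, B = 1, seed = 42)
  v2 <- bootstrap_validate("x", d, B = 1, seed = 42)
  expect_identical(v1, v2)
  expect_equal(v1$corrected_auc, v1$apparent_auc - v1$mean_optimism,
               tolerance = 1e-12)

  v <- bootstrap_validate("x", d, B = 100, seed = 7)
  expect_lt(abs(v$corrected_auc - v$apparent_auc), 0.03)
  expect_gt(v$apparent_auc, 0.85)
})

test_that("scenario filters reproduce the published accounting and guard degeneracy", {
  n <- 80
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    volume_cm3 = c(rep(1, 70), rep(10, 10)),
    treatment = c(rep("surgery", 70), rep("chemoradiation", 10)),
    adjuvant = c(rep(1, 14), rep(0, 56), rep(0, 10)),
    followup = c(rep(1, 68), 0, 0, rep(1, 10)),
    recurrence = c(rbinom(68, 1, 0.1), NA, NA, rbinom(10, 1, 0.3)))
  all_low <- filter_scenario(cohort, "all")
  expect_equal(nrow(all_low), 68)
  no_adj <- filter_scenario(cohort, "no-adjuvant")
  expect_equal(nrow(no_adj), 54)   # 14 adjuvant-treated of 68 excluded
  excl <- attr(no_adj, "excluded")
  expect_equal(nrow(cohort), nrow(no_adj) + sum(excl))

  # zero recurrences after filtering is an explicit error
  spec0 <- cohort_generator_spec(n_patients = 60,
                                 outcome_coefficients = c("(Intercept)" = -20),
                                 seed = 2)
  gen0 <- generate_cohort(spec0)
  expect_error(run_scenario(gen0$cohort, gen0$features, B = 5, seed = 1),
               "outcome classes")
})
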