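test_that("logistic fit recovers closed-form limits", {
  coh <- tibble::tibble(
    outcome = factor(rep(c("event", "surveillance"), c(29, 37)),
                     levels = c("surveillance", "event")),
    x = c(rep(c(0, 1), c(20, 9)), rep(c(0, 1), c(17, 20)))
  )
  # intercept-only MLE is the log odds of the event fraction
  f0 <- fit_outcome_model(coh, character(0))
  expect_equal(unname(coef(f0$fit)), log(29 / 37), tolerance = 1e-4)
  # binary predictor: coefficient equals the 2x2 log odds ratio
  tab <- table(coh$x, coh$outcome)
  lor <- log(tab["1", "event"] * tab["0", "surveillance"] /
               (tab["1", "surveillance"] * tab["0", "event"]))
  expect_true(is.finite(lor))
  f1 <- fit_outcome_model(coh, "x")
  expect_equal(unname(coef(f1$fit)["x"]), lor, tolerance = 1e-6)
  expect_false(f1$separation)
})

test_that("perfect separation is flagged, single-class outcomes rejected", {
  coh <- tibble::tibble(
    outcome = factor(rep(c("surveillance", "event"), each = 10),
                     levels = c("surveillance", "event")),
    x = c(rnorm(10, -2), rnorm(10, 2))
  )
  f <- fit_outcome_model(coh, "x")
  expect_true(f$separation)
  coh$outcome <- factor(rep("event", 20), levels = c("surveillance", "event"))
  expect_error(fit_outcome_model(coh, "x"), "single class")
})

test_that("DeLong AUC handles perfect, tied and cross-checked cases", {
  r <- auc_delong(1:20, rep(c(0, 1), each = 10))
  expect_equal(r$auc, 1)
  expect_true(r$degenerate)
  expect_equal(r$ci_low, 1)
  r2 <- auc_delong(rep(1, 30), rep(c(0, 1), 15))
  expect_equal(r2$auc, 0.5)
  expect_error(auc_delong(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong AUC and variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    y <- rep(c(0, 1), c(37, 29))
    s <- rnorm(66) + y * runif(1, 0.3, 1.5)
    if (i == 3) s <- round(s) # introduce ties
    got <- auc_delong(s, y)
    ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    expect_equal(got$ci_low, ci[1], tolerance = 1e-8)
    expect_equal(got$ci_high, ci[3], tolerance = 1e-8)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  y <- rep(c(0, 1), c(20, 20))
  s <- rnorm(40) + y
  a0 <- auc_delong(s, y)$auc
  expect_equal(auc_delong(exp(s), y)$auc, a0, tolerance = 1e-12)
  expect_equal(auc_delong(qnorm(stats::plogis(s)), y)$auc, a0, tolerance = 1e-12)
})

test_that("backward elimination lowers AIC monotonically and respects ties", {
  dat <- simulate_signal_cohort(n = 400, seed = 12)
  fit <- backward_eliminate(dat, c("baseline_fvc_pct", "delta_p_250",
                                   "mean_hu_ratio", "mean_hu_exp",
                                   "skewness_exp", "kurtosis_exp"))
  trace <- attr(fit, "trace")
  expect_true(all(diff(trace$aic) < 0)) # each accepted step strictly lowers AIC
  expect_true(all(c("skewness_exp", "baseline_fvc_pct") %in%
                    attr(fit, "retained")))
  # a single informative predictor is kept when deletion raises AIC
  fit1 <- backward_eliminate(dat, "skewness_exp")
  expect_equal(attr(fit1, "retained"), "skewness_exp")
})

test_that("adding pure noise cannot beat the nested model beyond chance", {
  dat <- simulate_signal_cohort(n = 300, seed = 44)
  f_small <- fit_outcome_model(dat, "skewness_exp")
  f_big <- fit_outcome_model(dat, c("skewness_exp", "mean_hu_ratio",
                                    "kurtosis_exp"))
  dev_drop <- 2 * (as.numeric(logLik(f_big$fit)) - as.numeric(logLik(f_small$fit)))
  expect_gte(dev_drop, 0)           # nesting
  expect_lt(dev_drop, qchisq(0.999, df = 2) + 1e-9) # chi-square scale noise
})

test_that("the model suite fits three models and the sensitivity subset", {
  coh <- generate_cohort(cohort_spec(seed = 27, lobes = NULL))
  suite <- run_model_suite(coh)
  g <- glance(suite)
  expect_equal(nrow(g), 6)
  expect_setequal(unique(g$model), c("fvc", "ct", "parsimonious"))
  expect_true(all(g$auc >= 0 & g$auc <= 1))
  expect_true(all(g$auc_ci_low <= g$auc & g$auc <= g$auc_ci_high))
  td <- tidy(suite)
  expect_true(all(c("analysis", "model", "term", "estimate", "std.error") %in%
                    names(td)))
  # a cohort with zero transplants: sensitivity identical to primary
  coh2 <- coh
  coh2$event_type[coh2$event_type == "transplant"] <- "death"
  suite2 <- run_model_suite(coh2)
  expect_equal(glance(suite2)$aic[1:3], glance(suite2)$aic[4:6])
  expect_equal(glance(suite2)$auc[1:3], glance(suite2)$auc[4:6])
})
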