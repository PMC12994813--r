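test_that("Pearson correlation matches hand computation and affine invariance", {
  coh <- tibble::tibble(skewness_exp = c(1, 2, 3), baseline_fvc_pct = c(1, 2, 4),
                        delta_fvc_pct = c(2, 1, 3))
  r <- correlate_measures(coh, measures = "skewness_exp")
  expect_equal(r$r[r$target == "baseline_fvc_pct"], 0.98198, tolerance = 1e-4)
  # perfect linear association
  coh2 <- tibble::tibble(m = 1:20, t1 = 2 * (1:20) + 1)
  p <- correlate_measures(coh2, measures = "m", targets = "t1")
  expect_equal(p$r, 1, tolerance = 1e-12)
  expect_lt(p$p, 1e-12)
  # invariance under positive affine transforms of either variable
  set.seed(5)
  coh3 <- tibble::tibble(m = rnorm(50), t1 = rnorm(50))
  r0 <- correlate_measures(coh3, "m", "t1")$r
  coh3$m <- 3 * coh3$m - 7
  coh3$t1 <- 0.2 * coh3$t1 + 100
  expect_equal(correlate_measures(coh3, "m", "t1")$r, r0, tolerance = 1e-12)
  expect_error(correlate_measures(tibble::tibble(m = rep(1, 5), t1 = 1:5),
                                  "m", "t1"), "zero-variance")
})

test_that("Mann-Whitney exact branch equals the enumeration oracle", {
  # U = 0 with 3 vs 3: two-sided exact p = 2/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1); y <- sample(seq_len(50) + 100, n2)
    y <- sample(c(x * 0.5 + 25, y))[seq_len(n2)] # interleave values, keep no ties
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney_u(x, y)$p, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical groups give a p-value near one in both branches", {
  x <- c(1, 5, 9, 13)
  expect_gt(mann_whitney_u(x, rev(x) + 0.5)$p, 0.5)
  set.seed(2)
  big <- rnorm(40)
  expect_gt(mann_whitney_u(big, sample(big) + rnorm(40, 0, 1e-9))$p, 0.3)
})

test_that("the tie-corrected approximation handles heavily tied data", {
  x <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  y <- c(1, 2, 2, 2, 3, 3, 4, 4, 4)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal_approx")
  w <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-9)
})

test_that("subgroup comparison reports group summaries with the rank test", {
  coh <- generate_cohort(cohort_spec(seed = 6))
  tab <- compare_subgroups(coh)
  expect_equal(tab$measure,
               c("delta_p_250", "mean_hu_ratio", "mean_hu_exp", "skewness_exp",
                 "kurtosis_exp", "baseline_fvc_pct", "delta_fvc_pct"))
  expect_equal(tab$n_surveillance, rep(37, 7))
  expect_equal(tab$n_event, rep(29, 7))
  expect_true(all(tab$u >= 0 & tab$u <= 37 * 29))
  # cohort of identical patients: all SDs zero
  coh2 <- coh[rep(1, 12), ]
  coh2$outcome <- factor(rep(c("surveillance", "event"), 6),
                         levels = c("surveillance", "event"))
  tab2 <- compare_subgroups(coh2, measures = "skewness_exp")
  expect_equal(tab2$sd_surveillance, 0)
  expect_equal(tab2$sd_event, 0)
})

test_that("upper-vs-lower lobe paired t tests behave at the degenerate limits", {
  lm0 <- tibble::tibble(patient_id = rep(sprintf("P%02d", 1:6), each = 2),
                        lobe = rep(c("RUL", "RLL"), 6),
                        delta_p_250 = rep(5, 12))
  r0 <- lobe_contrasts(lm0, "delta_p_250", pairs = list(c("RUL", "RLL")))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  lm1 <- lm0
  lm1$delta_p_250[lm1$lobe == "RLL"] <- 9 # constant nonzero difference
  r1 <- lobe_contrasts(lm1, "delta_p_250", pairs = list(c("RUL", "RLL")))
  expect_true(r1$degenerate)
  expect_lt(r1$p, 1e-12)
})

test_that("paired t on generated cohorts matches t.test and finds the gradient", {
  coh <- generate_cohort(cohort_spec(seed = 19))
  lob <- cohort_lobe_metrics(coh)
  res <- lobe_contrasts(lob)
  expect_equal(nrow(res), 10) # 5 measures x 2 pairs
  expect_equal(res$df, rep(65, 10))
  # cross-check one cell against stats::t.test
  w <- tidyr::pivot_wider(lob[lob$lobe %in% c("RUL", "RLL"), c("patient_id", "lobe", "delta_p_250")],
                          names_from = "lobe", values_from = "delta_p_250")
  tt <- stats::t.test(w$RUL, w$RLL, paired = TRUE)
  cell <- res[res$measure == "delta_p_250" & res$lobe_a == "RUL", ]
  expect_equal(cell$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(cell$p, tt$p.value, tolerance = 1e-9)
  # basal-predominant gradient: all pairs highly significant at n = 66
  expect_true(all(res$p < 0.001))
})

test_that("lobe summary table has the fixed layout and round-trips", {
  coh <- generate_cohort(cohort_spec(seed = 23))
  lob <- cohort_lobe_metrics(coh)
  s <- summarize_lobes(lob)
  expect_equal(nrow(s), 5 * 5 * 2)
  expect_equal(levels(s$lobe), c("RUL", "ML", "RLL", "LUL", "LLL"))
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(s, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(back$mean, s$mean, tolerance = 1e-12)
})
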