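test_that("moments use population central moments with non-excess kurtosis", {
  # hand evaluation: {0,0,0,1} has m2 = 3/16, m3 = 3/32 -> skew = 2/sqrt(3)
  m <- hu_moments(c(0, 0, 0, 1))
  expect_equal(m$skewness, 2 / sqrt(3), tolerance = 1e-12)
  # symmetric two-point mass attains the kurtosis minimum of 1
  m2 <- hu_moments(rep(c(-1, 1), 10))
  expect_equal(m2$kurtosis, 1, tolerance = 1e-12)
  expect_equal(m2$skewness, 0, tolerance = 1e-12)
  expect_error(hu_moments(rep(5, 10)), "zero-variance")
  expect_error(hu_moments(c(1, 2, 3)), "at least 4")
})

test_that("skewness and kurtosis are invariant under positive affine maps", {
  set.seed(41)
  for (i in 1:10) {
    v <- rnorm(200, -700, 120)^1 + rexp(200, 1 / 50)
    a <- runif(1, 0.1, 10); b <- runif(1, -500, 500)
    m0 <- hu_moments(v); m1 <- hu_moments(a * v + b)
    expect_equal(m1$skewness, m0$skewness, tolerance = 1e-9)
    expect_equal(m1$kurtosis, m0$kurtosis, tolerance = 1e-9)
    # moment inequality on every sample
    expect_gte(m0$kurtosis, m0$skewness^2 + 1)
  }
})

test_that("percentile at threshold counts the fraction at or below", {
  expect_equal(percentile_at_threshold(rep(-800, 5), -250), 100)
  expect_equal(percentile_at_threshold(c(rep(-800, 3), rep(-100, 3)), -250), 50)
  expect_equal(percentile_at_threshold(c(-100, -50), -250), 0)
})

test_that("the percentile shift statistic matches counting oracles", {
  expect_equal(delta_p(rep(-800, 4), rep(-800, 4)), 0)
  expect_equal(delta_p(rep(-800, 10), rep(c(-800, -100), 5)), 50)
  # shifting expiration upward never decreases the shift statistic
  set.seed(7)
  insp <- rnorm(500, -750, 100)
  exp0 <- rnorm(500, -700, 120)
  for (c_shift in c(10, 50, 200)) {
    expect_gte(delta_p(insp, exp0 + c_shift), delta_p(insp, exp0))
    expect_lte(mean_hu_ratio(insp, exp0 + c_shift), mean_hu_ratio(insp, exp0))
  }
})

test_that("mean HU ratio divides expiratory by inspiratory mean and guards aeration", {
  v <- rnorm(100, -700, 50)
  expect_equal(mean_hu_ratio(v, v), 1)
  expect_equal(mean_hu_ratio(rep(-766.67, 3), rep(-575, 3)), 0.75, tolerance = 1e-3)
  expect_error(mean_hu_ratio(rep(0, 4), rep(-100, 4)), "not aerated")
  expect_error(mean_hu_ratio(rep(-49, 4), rep(-100, 4)), "not aerated")
})

test_that("sample extraction validates geometry and lobe completeness", {
  tp <- tiny_pair()
  s <- extract_samples(tp$insp, tp$mask, "insp")
  expect_equal(as.character(s$region), c("RUL", "ML", "RLL", "LUL", "LLL", "TOTAL"))
  expect_equal(s$n[6], sum(s$n[1:5]))
  # identity on a 2-voxel lobe
  expect_equal(sort(s$values[[1]]), c(-800, -600))
  expect_error(extract_samples(tp$insp, array(0L, dim(tp$mask)), "insp"),
               "no lung voxels")
  m2 <- tp$mask; m2[m2 == 3] <- 1
  expect_error(extract_samples(tp$insp, m2, "insp"), "RLL")
  expect_error(extract_samples(tp$insp, tp$mask[1:4, , , drop = FALSE], "insp"),
               "shapes differ")
  m3 <- tp$mask; m3[1] <- 7L
  expect_error(extract_samples(tp$insp, m3, "insp"), "unknown labels")
})

test_that("values are clamped to the analysis range on extraction", {
  tp <- tiny_pair()
  v <- tp$insp; v[1] <- -3000; v[2] <- 1500
  s <- extract_samples(v, tp$mask, "insp")
  expect_equal(min(s$values[[6]]), -1024)
  expect_equal(max(s$values[[6]]), 200)
})

test_that("compute_metrics reproduces per-region statistics deterministically", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), seed = 5)
  pair <- generate_phantom_pair(spec)
  m1 <- compute_metrics(pair$insp, pair$exp, pair$mask)
  m2 <- compute_metrics(pair$insp, pair$exp, pair$mask)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 6)
  expect_true(all(m1$kurtosis_exp >= 1))
  expect_true(all(abs(m1$delta_p_250) <= 100))
})

test_that("metrics recomputed from 1-HU histogram bins agree within binning error", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), seed = 9)
  pair <- generate_phantom_pair(spec)
  m <- compute_metrics(pair$insp, pair$exp, pair$mask)
  h <- histogram_export(pair$exp, pair$mask, "exp")
  for (reg in c("RUL", "TOTAL")) {
    hh <- h[h$region == reg, ]
    expect_equal(sum(hh$count), m$n_exp[m$region == reg])
    mids <- (hh$bin_left + hh$bin_right) / 2
    binned_mean <- sum(mids * hh$count) / sum(hh$count)
    expect_equal(binned_mean, m$mean_hu_exp[m$region == reg], tolerance = 0.5)
  }
})
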