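test_that("phantom generation is deterministic and honours the lobe partition", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), seed = 42)
  p1 <- generate_phantom_pair(spec)
  p2 <- generate_phantom_pair(spec)
  expect_identical(p1, p2)
  # every in-lung voxel has exactly one label, all five lobes populated
  counts <- table(p1$mask[p1$mask > 0])
  expect_equal(sort(as.integer(names(counts))), 1:5)
  expect_true(all(counts >= 8))
  expect_true(all(p1$insp >= -1024 & p1$insp <= 200))
  expect_true(all(p1$exp >= -1024 & p1$exp <= 200))
})

test_that("degenerate grids are rejected", {
  expect_error(phantom_spec(grid_shape = c(6, 6, 6)), "degenerate grid")
  expect_error(phantom_spec(grid_shape = c(20, 20)), "three positive")
})

test_that("zero collapse and zero shift gives identical phases up to noise", {
  lob <- lobe_params_default(c(RUL = 0, ML = 0, RLL = 0, LUL = 0, LLL = 0))
  lob$shift_aerated <- 0
  spec <- phantom_spec(grid_shape = c(30, 30, 30), lobes = lob,
                       exp_noise_sd = 0, seed = 1)
  pair <- generate_phantom_pair(spec)
  expect_equal(pair$insp, pair$exp)
  m <- compute_metrics(pair$insp, pair$exp, pair$mask)
  expect_true(all(abs(m$delta_p_250) < 1e-12))
  expect_true(all(abs(m$mean_hu_ratio - 1) < 1e-12))
})

test_that("expiratory mean shift follows the mixture closed form", {
  f <- 0.5
  lob <- lobe_params_default(c(RUL = f, ML = f, RLL = f, LUL = f, LLL = f))
  spec <- phantom_spec(grid_shape = c(44, 44, 44), lobes = lob,
                       exp_noise_sd = 0, seed = 3)
  pair <- generate_phantom_pair(spec)
  mi <- mean(pair$insp[pair$mask > 0])
  me <- mean(pair$exp[pair$mask > 0])
  expected_shift <- f * 400 + (1 - f) * 50
  # Monte-Carlo tolerance: a few HU on ~8e4 voxels
  expect_equal(me - mi, expected_shift, tolerance = 0.02)
})

test_that("analytic truth recovers Gaussian and two-point limits", {
  # single compartment (collapse 0), no clamp influence: Gaussian moments
  lob <- lobe_params_default(c(RUL = 0, ML = 0, RLL = 0, LUL = 0, LLL = 0))
  spec <- phantom_spec(grid_shape = c(20, 20, 20), lobes = lob,
                       exp_noise_sd = 0, seed = 1)
  tr <- phantom_truth(spec)
  # tolerance absorbs the (tiny) effect of the -1024 HU clamp at 3.5 sigma
  expect_equal(tr$skewness_exp, rep(0, 6), tolerance = 1e-3)
  expect_equal(tr$kurtosis_exp, rep(3, 6), tolerance = 1e-3)
  # degenerate two-point mixture at -800/-100, weights 0.5/0.5: kurtosis 1
  lob2 <- lobe_params_default(c(RUL = .5, ML = .5, RLL = .5, LUL = .5, LLL = .5))
  lob2$aerated_mean <- -800; lob2$collapsed_mean <- -100
  lob2$aerated_sd <- 0; lob2$collapsed_sd <- 0
  lob2$shift_aerated <- 0; lob2$shift_collapsed <- 0
  spec2 <- phantom_spec(grid_shape = c(20, 20, 20), lobes = lob2,
                        exp_noise_sd = 0, seed = 1)
  tr2 <- phantom_truth(spec2)
  expect_equal(tr2$kurtosis_exp, rep(1, 6), tolerance = 1e-12)
  expect_equal(tr2$skewness_exp, rep(0, 6), tolerance = 1e-12)
  expect_equal(tr2$mean_hu_exp, rep(-450, 6), tolerance = 1e-12)
})

test_that("clamped-normal raw moments match numerical integration", {
  cases <- list(c(-850, 50), c(-450, 80), c(-1000, 120), c(150, 60))
  for (cs in cases) {
    got <- hushift:::clamped_norm_raw(cs[1], cs[2], -1024, 200)
    for (k in 1:4) {
      want <- stats::integrate(function(x) {
        pmin(pmax(x, -1024), 200)^k * dnorm(x, cs[1], cs[2])
      }, cs[1] - 12 * cs[2], cs[1] + 12 * cs[2], rel.tol = 1e-12)$value
      expect_equal(got[k], want, tolerance = 1e-8)
    }
  }
})

test_that("empirical phantom metrics converge to analytic truth", {
  spec <- phantom_spec(grid_shape = c(52, 52, 52), seed = 17)
  tr <- phantom_truth(spec)
  pair <- generate_phantom_pair(spec)
  m <- compute_metrics(pair$insp, pair$exp, pair$mask)
  se_mean <- sqrt(tr$var_exp / tr$n_voxels)
  expect_true(all(abs(m$mean_hu_exp - tr$mean_hu_exp) < 4 * se_mean))
  expect_true(all(abs(m$mean_hu_ratio - tr$mean_hu_ratio) < 0.02))
  expect_true(all(abs(m$delta_p_250 - tr$delta_p_250) < 2))
  # lower lobes shift more and are less right-skewed than upper lobes
  g <- function(tbl, r, col) tbl[[col]][tbl$region == r]
  expect_gt(g(m, "RLL", "delta_p_250"), g(m, "RUL", "delta_p_250"))
  expect_lt(g(m, "RLL", "skewness_exp"), g(m, "RUL", "skewness_exp"))
})
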