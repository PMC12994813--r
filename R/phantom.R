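# Synthetic paired-phase attenuation phantoms with analytic ground truth.
#
# A phantom is an abstract partitioned box, not an anatomical lung: the
# downstream histogram measures consume unordered per-lobe value sets, so
# geometry beyond the lobe partition is irrelevant. Each lobe mixes two
# attenuation compartments: "aerated" tissue whose density rises only
# slightly in expiration, and "collapsing" tissue whose density rises
# strongly (the alveolar-collapse surrogate). The collapse fraction carries
# an apico-basal gradient: lower lobes collapse most, the middle lobe least.

#' Default per-lobe compartment parameters
#'
#' Aerated tissue sits near -850 HU and stiffens by ~+50 HU in expiration;
#' collapsing tissue sits near -450 HU in inspiration (ground-glass range)
#' and shifts by ~+400 HU toward soft-tissue attenuation on expiration.
#' Collapse fractions follow the basal-predominant pattern of fibrotic lung:
#' lower lobes three times the upper lobes, middle lobe lowest.
#'
#' @param collapse Named numeric of per-lobe collapse fractions; names must
#'   be the five lobe labels.
#' @return A tibble with one row per lobe and the compartment columns used
#'   by [phantom_spec()].
#' @export
lobe_params_default <- function(collapse = c(RUL = 0.10, ML = 0.07, RLL = 0.30,
                                             LUL = 0.10, LLL = 0.30)) {
  if (!setequal(names(collapse), LOBES)) {
    abort("`collapse` must be named with the five lobe labels", class = "hushift_error_spec")
  }
  tibble(
    lobe = LOBES,
    collapse_fraction = unname(collapse[LOBES]),
    aerated_mean = -850, aerated_sd = 50,
    collapsed_mean = -450, collapsed_sd = 80,
    shift_aerated = 50, shift_collapsed = 400
  )
}

#' Specification of a paired inspiration/expiration phantom
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param lobes Tibble of per-lobe compartment parameters, one row per lobe
#'   (see [lobe_params_default()] for the columns).
#' @param exp_noise_sd SD (HU) of the independent voxel noise added on top of
#'   the compartment shift when forming the expiratory volume.
#' @param clamp HU clamp range applied to generated volumes.
#' @param margin Background shell thickness in voxels (label 0).
#' @param seed Integer seed; fully determines the generated volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), lobes = lobe_params_default(),
                         exp_noise_sd = 20, clamp = c(-1024, 200), margin = 2,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers", class = "hushift_error_spec")
  }
  lobes <- as_tibble(lobes)
  if (!setequal(lobes$lobe, LOBES) || nrow(lobes) != 5L) {
    abort("`lobes` must have exactly one row per lobe", class = "hushift_error_spec")
  }
  lobes <- lobes[match(LOBES, lobes$lobe), ]
  with(lobes, {
    if (any(collapse_fraction < 0 | collapse_fraction > 1)) {
      abort("collapse fractions must lie in [0, 1]", class = "hushift_error_spec")
    }
    if (any(aerated_sd < 0 | collapsed_sd < 0)) {
      abort("compartment sds must be non-negative", class = "hushift_error_spec")
    }
    if (any(aerated_mean >= collapsed_mean)) {
      abort("aerated_mean must be below collapsed_mean", class = "hushift_error_spec")
    }
  })
  stopifnot_scalar_num(exp_noise_sd, "exp_noise_sd", lower = 0)
  stopifnot_scalar_num(margin, "margin", lower = 0)
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), lobes = lobes,
         exp_noise_sd = exp_noise_sd, clamp = clamp,
         margin = as.integer(margin), seed = as.integer(seed)),
    class = "phantom_spec"
  )
  counts <- table(factor(LOBES[lobe_mask(spec)], levels = LOBES))
  if (any(counts < 8)) {
    abort(paste0("degenerate grid: lobes with < 8 voxels: ",
                 paste(names(counts)[counts < 8], collapse = ", ")),
          class = "hushift_error_spec")
  }
  spec
}

# Deterministic lobe partition: axis 1 halves into right/left lung, axis 3
# (apex -> base) slabs into RUL/ML/RLL on the right and LUL/LLL on the left;
# a `margin`-voxel background shell surrounds the lung.
lobe_mask <- function(spec) {
  g <- spec$grid_shape
  m <- spec$margin
  mask <- array(0L, dim = g)
  xs <- seq_len(g[1]); zs <- seq_len(g[3])
  inside <- function(i, gmax) i > m & i <= gmax - m
  in_x <- inside(xs, g[1]); in_z <- inside(zs, g[3])
  ys <- inside(seq_len(g[2]), g[2])
  x_in <- xs[in_x]; z_in <- zs[in_z]
  right <- x_in <= stats::median(xs)
  zf <- (seq_along(z_in) - 0.5) / length(z_in) # apical fraction 0..1
  for (ix in seq_along(x_in)) {
    for (iz in seq_along(z_in)) {
      lab <- if (right[ix]) {
        if (zf[iz] < 0.35) 1L else if (zf[iz] < 0.55) 2L else 3L
      } else {
        if (zf[iz] < 0.45) 4L else 5L
      }
      mask[x_in[ix], ys, z_in[iz]] <- lab
    }
  }
  mask
}

#' Generate a paired inspiration/expiration phantom
#'
#' Each in-lung voxel is assigned to the aerated or collapsing compartment by
#' a Bernoulli draw on its lobe's collapse fraction; its inspiratory value is
#' drawn from the compartment's Gaussian, and its expiratory value is the
#' same draw plus the compartment's expiratory shift plus independent voxel
#' noise. Both volumes are clamped to the spec's HU range. Output is fully
#' determined by the spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_pair` with numeric arrays `insp`, `exp`
#'   and the integer array `mask`.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- lobe_mask(spec)
  insp <- array(NA_real_, dim = spec$grid_shape)
  expv <- array(NA_real_, dim = spec$grid_shape)
  with_seed(spec$seed, {
    for (i in seq_along(LOBES)) {
      p <- spec$lobes[i, ]
      idx <- which(mask == i)
      nv <- length(idx)
      collapsed <- runif(nv) < p$collapse_fraction
      mu <- ifelse(collapsed, p$collapsed_mean, p$aerated_mean)
      sdv <- ifelse(collapsed, p$collapsed_sd, p$aerated_sd)
      shift <- ifelse(collapsed, p$shift_collapsed, p$shift_aerated)
      raw <- rnorm(nv, mu, sdv)
      insp[idx] <- raw
      expv[idx] <- raw + shift + rnorm(nv, 0, spec$exp_noise_sd)
    }
  })
  lung <- mask > 0
  insp[lung] <- clamp_hu(insp[lung], spec$clamp)
  expv[lung] <- clamp_hu(expv[lung], spec$clamp)
  insp[!lung] <- spec$clamp[1]
  expv[!lung] <- spec$clamp[1]
  structure(list(insp = insp, exp = expv, mask = mask), class = "phantom_pair")
}

# Raw moments E[X^k], k = 1..4, of a clamped normal
# X = min(max(Y, a), b), Y ~ N(mu, sigma). Uses the truncated-normal moment
# recursion plus point masses at the clamp bounds; sigma = 0 degenerates to a
# (possibly clamped) point mass.
clamped_norm_raw <- function(mu, sigma, a, b) {
  if (sigma <= 0) {
    x <- min(max(mu, a), b)
    return(x^(1:4))
  }
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  pa <- pnorm(al); pb <- pnorm(be)
  z <- pb - pa
  if (z < 1e-300) { # all mass clamped to one bound
    x <- if (pa > 0.5) a else b
    return(x^(1:4))
  }
  phi_a <- dnorm(al); phi_b <- dnorm(be)
  L <- numeric(5) # L[k+1] = E[z^k | truncated]
  L[1] <- 1
  L[2] <- (phi_a - phi_b) / z
  for (k in 2:4) {
    L[k + 1] <- (k - 1) * L[k - 1] +
      (al^(k - 1) * phi_a - be^(k - 1) * phi_b) / z
  }
  raw_t <- vapply(1:4, function(k) {
    sum(vapply(0:k, function(j) choose(k, j) * mu^(k - j) * sigma^j * L[j + 1],
               numeric(1)))
  }, numeric(1))
  pa * a^(1:4) + (1 - pb) * b^(1:4) + z * raw_t
}

# Moments + threshold CDF of a clamped-Gaussian mixture given a component
# table (weight, mu, sigma). The CDF at an interior threshold is
# clamp-invariant because both clamp bounds stay on their own sides of it.
mixture_stats <- function(comp, clamp, threshold) {
  w <- comp$weight / sum(comp$weight)
  raw <- t(vapply(seq_along(w), function(i) {
    clamped_norm_raw(comp$mu[i], comp$sigma[i], clamp[1], clamp[2])
  }, numeric(4)))
  m <- colSums(w * raw)
  m1 <- m[1]
  m2c <- m[2] - m1^2
  m3c <- m[3] - 3 * m1 * m[2] + 2 * m1^3
  m4c <- m[4] - 4 * m1 * m[3] + 6 * m1^2 * m[2] - 3 * m1^4
  cdf <- sum(w * ifelse(comp$sigma > 0,
                        pnorm(threshold, comp$mu, pmax(comp$sigma, 1e-300)),
                        as.numeric(comp$mu <= threshold)))
  sh <- shape_from_central(m2c, m3c, m4c)
  list(mean = m1, var = m2c, skewness = unname(sh["skewness"]),
       kurtosis = unname(sh["kurtosis"]), cdf_at_threshold = cdf)
}

phase_components <- function(p, phase, exp_noise_sd) {
  if (phase == "insp") {
    tibble(weight = c(1 - p$collapse_fraction, p$collapse_fraction),
           mu = c(p$aerated_mean, p$collapsed_mean),
           sigma = c(p$aerated_sd, p$collapsed_sd))
  } else {
    tibble(weight = c(1 - p$collapse_fraction, p$collapse_fraction),
           mu = c(p$aerated_mean + p$shift_aerated,
                  p$collapsed_mean + p$shift_collapsed),
           sigma = sqrt(c(p$aerated_sd, p$collapsed_sd)^2 + exp_noise_sd^2))
  }
}

#' Analytic ground-truth histogram measures for a phantom specification
#'
#' Computes the exact population values of all five histogram measures for
#' each lobe and the total lung, from the closed-form moments of the clamped
#' two-compartment Gaussian mixtures the generator draws from (expiratory
#' components include the voxel-noise variance). The total lung is the
#' voxel-count-weighted mixture of the lobes. These are the values the
#' empirical measures of [generate_phantom_pair()] converge to as the voxel
#' count grows, which makes them an independent oracle for the metric code.
#'
#' @param spec A [phantom_spec()].
#' @param threshold Percentile-shift threshold in HU (default -250).
#' @return A tibble with one row per region and the five measure columns,
#'   plus `n_voxels`.
#' @export
phantom_truth <- function(spec, threshold = -250) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- lobe_mask(spec)
  counts <- tabulate(mask[mask > 0], nbins = 5L)
  per_lobe <- lapply(seq_along(LOBES), function(i) {
    p <- spec$lobes[i, ]
    list(insp = phase_components(p, "insp", spec$exp_noise_sd),
         exp = phase_components(p, "exp", spec$exp_noise_sd),
         n = counts[i])
  })
  total <- list(
    insp = bind_rows(lapply(seq_along(per_lobe), function(i) {
      mutate(per_lobe[[i]]$insp, weight = .data$weight * counts[i])
    })),
    exp = bind_rows(lapply(seq_along(per_lobe), function(i) {
      mutate(per_lobe[[i]]$exp, weight = .data$weight * counts[i])
    })),
    n = sum(counts)
  )
  all_regions <- c(per_lobe, list(total))
  rows <- lapply(seq_along(REGIONS), function(i) {
    r <- all_regions[[i]]
    si <- mixture_stats(r$insp, spec$clamp, threshold)
    se <- mixture_stats(r$exp, spec$clamp, threshold)
    tibble(
      region = REGIONS[i], n_voxels = r$n,
      mean_hu_exp = se$mean, skewness_exp = se$skewness,
      kurtosis_exp = se$kurtosis,
      mean_hu_ratio = se$mean / si$mean,
      delta_p_250 = 100 * (si$cdf_at_threshold - se$cdf_at_threshold),
      var_exp = se$var
    )
  })
  out <- bind_rows(rows)
  out$region <- factor(out$region, levels = REGIONS)
  out
}
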