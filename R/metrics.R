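#' Clamp attenuation values to the physiological analysis range
#'
#' CT reconstructions occasionally contain values far outside plausible lung
#' attenuation (metal streaks, padding). All histogram measures are computed
#' on values clamped to a fixed window that keeps soft-tissue-attenuation
#' collapsed parenchyma but drops reconstruction outliers.
#'
#' @param values Numeric vector of attenuation values (HU).
#' @param clamp Length-2 numeric, lower and upper clamp bounds in HU.
#' @return Numeric vector with values winsorised to `[clamp[1], clamp[2]]`.
#' @export
clamp_hu <- function(values, clamp = c(-1024, 200)) {
  check_values(values, "attenuation values")
  if (length(clamp) != 2L || clamp[1] >= clamp[2]) {
    abort("`clamp` must be an increasing length-2 numeric", class = "hushift_error_spec")
  }
  pmin(pmax(values, clamp[1]), clamp[2])
}

#' Mean, skewness and kurtosis of an attenuation sample
#'
#' Population (biased) central moments are used: skewness is
#' \eqn{m_3/m_2^{3/2}} and kurtosis is the non-excess \eqn{m_4/m_2^2}, so a
#' Gaussian sample has skewness 0 and kurtosis 3, and a platykurtic (broader)
#' distribution has kurtosis below 3. At the voxel counts of lobar CT samples
#' the small-sample correction is negligible; the convention is fixed so that
#' the kurtosis-below-3 reading of fibrotic broadening holds.
#'
#' @param values Numeric vector of attenuation values (HU), at least 4 values
#'   with positive variance.
#' @return A one-row tibble with columns `n`, `mean`, `skewness`, `kurtosis`.
#' @examples
#' hu_moments(rnorm(1000, -800, 50))
#' @export
hu_moments <- function(values) {
  check_values(values)
  n <- length(values)
  if (n < 4L) abort("need at least 4 values for moments", class = "hushift_error_input")
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 <= 0) abort("zero-variance sample: moments undefined", class = "hushift_error_input")
  sh <- shape_from_central(m2, mean(d^3), mean(d^4))
  tibble(n = n, mean = m, skewness = unname(sh["skewness"]),
         kurtosis = unname(sh["kurtosis"]))
}

#' Percentile of an attenuation sample at a threshold
#'
#' The percentile at which a threshold sits in the empirical attenuation
#' distribution: `100 * mean(values <= threshold)`. At -250 HU this splits
#' the lung into the fraction below (aerated through ground-glass) and above
#' (collapse-range and denser) attenuation.
#'
#' @param values Numeric vector of attenuation values (HU).
#' @param threshold Threshold in HU (default -250).
#' @return Percentile in `[0, 100]`.
#' @export
percentile_at_threshold <- function(values, threshold = -250) {
  check_values(values)
  stopifnot_scalar_num(threshold, "threshold")
  100 * mean(values <= threshold)
}

#' Inspiratory-expiratory percentile shift at a threshold
#'
#' The central statistic of the pipeline: the difference between the
#' percentile of `threshold` in the inspiratory and the expiratory
#' attenuation distribution. In expiration the lung is denser, the -250 HU
#' point sits at a lower percentile, and the difference is positive; larger
#' values indicate a larger fraction of parenchyma crossing the collapse
#' threshold between the two breathing states. A patient at the 93rd
#' percentile in inspiration and the 73rd in expiration scores 20.
#'
#' @param insp,exp Numeric vectors of attenuation values (HU) for the same
#'   region of the same patient in inspiration and expiration. The two
#'   vectors need not be the same length; no voxel registration is assumed.
#' @param threshold Threshold in HU (default -250).
#' @return Percentile-point difference in `[-100, 100]`.
#' @examples
#' delta_p(c(rep(-800, 93), rep(-100, 7)), c(rep(-800, 73), rep(-100, 27)))
#' @export
delta_p <- function(insp, exp, threshold = -250) {
  percentile_at_threshold(insp, threshold) - percentile_at_threshold(exp, threshold)
}

#' Expiratory/inspiratory mean attenuation ratio
#'
#' `mean(exp) / mean(insp)`. Both means are negative in aerated lung; the
#' ratio is 1 when nothing changes between breathing states and falls toward
#' 0 as the expiratory mean rises toward water attenuation. An inspiratory
#' mean at or above -50 HU is rejected: it indicates a non-aerated (or
#' mislabelled) sample and would make the ratio numerically unstable.
#'
#' @inheritParams delta_p
#' @return Dimensionless ratio.
#' @export
mean_hu_ratio <- function(insp, exp) {
  check_values(insp, "inspiratory sample")
  check_values(exp, "expiratory sample")
  mi <- mean(insp)
  if (mi >= -50) {
    abort(sprintf("inspiratory sample not aerated (mean %.1f HU >= -50 HU)", mi),
          class = "hushift_error_input")
  }
  mean(exp) / mi
}

#' Extract per-lobe attenuation samples from a volume and lobe mask
#'
#' Splits a masked HU volume into one sample per lobe plus the total lung
#' (union of all five lobes). Voxels labelled 0 are background and excluded.
#'
#' @param volume Numeric array of attenuation values (HU).
#' @param mask Integer array of the same shape; labels 1=RUL, 2=ML, 3=RLL,
#'   4=LUL, 5=LLL, 0=background.
#' @param phase `"insp"` or `"exp"`, carried through as a tag.
#' @param clamp HU clamp range applied to the extracted values.
#' @return A tibble with columns `region`, `phase`, `n`, `values`
#'   (list-column of numeric vectors); six rows (five lobes + `"TOTAL"`).
#' @export
extract_samples <- function(volume, mask, phase = c("insp", "exp"),
                            clamp = c(-1024, 200)) {
  phase <- match.arg(phase)
  if (!identical(dim(volume), dim(mask))) {
    abort(sprintf("volume %s and mask %s shapes differ",
                  paste(dim(volume), collapse = "x"),
                  paste(dim(mask), collapse = "x")),
          class = "hushift_error_geometry")
  }
  labs <- unique(as.integer(mask))
  bad <- setdiff(labs, 0:5)
  if (length(bad)) {
    abort(paste0("mask contains unknown labels: ", paste(sort(bad), collapse = ", ")),
          class = "hushift_error_input")
  }
  if (!any(mask > 0)) abort("no lung voxels in mask", class = "hushift_error_input")
  vals <- lapply(seq_along(LOBES), function(i) as.numeric(volume[mask == i]))
  empty <- LOBES[lengths(vals) == 0L]
  if (length(empty)) {
    abort(paste0("empty lobe(s) in mask: ", paste(empty, collapse = ", ")),
          class = "hushift_error_input")
  }
  vals <- c(vals, list(unlist(vals, use.names = FALSE)))
  vals <- lapply(vals, clamp_hu, clamp = clamp)
  tibble(region = factor(REGIONS, levels = REGIONS), phase = phase,
         n = lengths(vals), values = vals)
}

#' Compute all histogram measures for a paired inspiration/expiration scan
#'
#' For each lobe and the total lung, computes the expiratory mean HU,
#' expiratory skewness and (non-excess) kurtosis, the exp/insp mean-HU
#' ratio, and the percentile shift at `threshold`. The inspiratory and
#' expiratory volumes are analysed through their own masks (one per phase;
#' by default the same mask) as unordered value sets -- the method is
#' registration-free by construction.
#'
#' @param insp,exp Numeric arrays of attenuation values (HU) for inspiration
#'   and expiration.
#' @param mask Lobe-label array for the inspiratory volume.
#' @param mask_exp Lobe-label array for the expiratory volume; defaults to
#'   `mask`.
#' @param threshold Percentile-shift threshold in HU (default -250).
#' @param clamp HU clamp range.
#' @param patient_id Optional identifier carried into the output.
#' @return A tibble with one row per region and columns `patient_id`,
#'   `region`, `n_insp`, `n_exp`, `mean_hu_exp`, `skewness_exp`,
#'   `kurtosis_exp`, `mean_hu_ratio`, `delta_p_250`.
#' @export
compute_metrics <- function(insp, exp, mask, mask_exp = NULL, threshold = -250,
                            clamp = c(-1024, 200), patient_id = NA_character_) {
  mask_exp <- mask_exp %||% mask
  si <- extract_samples(insp, mask, "insp", clamp)
  se <- extract_samples(exp, mask_exp, "exp", clamp)
  rows <- lapply(seq_len(nrow(si)), function(i) {
    region <- as.character(si$region[i])
    vi <- si$values[[i]]
    ve <- se$values[[i]]
    mom <- tryCatch(hu_moments(ve), error = function(e) {
      abort(paste0(region, ": ", conditionMessage(e)), class = "hushift_error_input")
    })
    tibble(
      patient_id = patient_id, region = region,
      n_insp = length(vi), n_exp = length(ve),
      mean_hu_exp = mom$mean, skewness_exp = mom$skewness,
      kurtosis_exp = mom$kurtosis,
      mean_hu_ratio = mean_hu_ratio(vi, ve),
      delta_p_250 = delta_p(vi, ve, threshold)
    )
  })
  out <- bind_rows(rows)
  out$region <- factor(out$region, levels = REGIONS)
  out
}

#' Export 1-HU-bin attenuation histograms per region and phase
#'
#' Bins every regional sample into 1-HU-wide bins spanning the clamp range,
#' for plotting or archival. Bins are left-closed, `[edge, edge + 1)`, with
#' the final bin closed on both sides, so counts always sum to the sample
#' size.
#'
#' @inheritParams extract_samples
#' @return A tibble with columns `region`, `phase`, `bin_left`, `bin_right`,
#'   `count`.
#' @export
histogram_export <- function(volume, mask, phase = c("insp", "exp"),
                             clamp = c(-1024, 200)) {
  phase <- match.arg(phase)
  samples <- extract_samples(volume, mask, phase, clamp)
  edges <- seq(clamp[1], clamp[2])
  nb <- length(edges) - 1L
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    idx <- findInterval(samples$values[[i]], edges, rightmost.closed = TRUE)
    tibble(region = as.character(samples$region[i]), phase = phase,
           bin_left = edges[-length(edges)], bin_right = edges[-1],
           count = tabulate(idx, nbins = nb))
  })
  out <- bind_rows(rows)
  out$region <- factor(out$region, levels = REGIONS)
  out
}
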