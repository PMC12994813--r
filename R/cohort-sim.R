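# Synthetic IPF cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# outcome subgroups (clinical surveillance vs death/transplantation within
# three years) whose total-lung and lobe-wise histogram measures follow the
# published subgroup means/SDs, plus irregular FVC% visit schedules that
# satisfy the pipeline's inclusion criteria (baseline PFT within +/-50 days
# of the CT, at least one follow-up at >= 6 months).

#' Default subgroup distributions of the total-lung measures
#'
#' Published subgroup means and SDs of the five histogram measures, baseline
#' FVC% and one-year delta FVC% for surveillance (n = 37) vs
#' death/transplantation (n = 29) patients. `delta_fvc_pct` doubles as the
#' mean one-year FVC% decline slope of the visit-series model.
#'
#' @return A tibble with columns `measure`, `mean_surv`, `sd_surv`,
#'   `mean_event`, `sd_event`.
#' @export
cohort_measure_defaults <- function() {
  tibble(
    measure = c("delta_p_250", "mean_hu_ratio", "mean_hu_exp",
                "skewness_exp", "kurtosis_exp", "baseline_fvc_pct",
                "delta_fvc_pct"),
    mean_surv  = c(8.09, 0.75, -575, 0.99, 3.62, 75.84, -4.43),
    sd_surv    = c(5.88, 0.09,   94, 0.46, 1.25, 17.1,   6.62),
    mean_event = c(13.9, 0.69, -495, 0.55, 2.67, 64.41, -3.48),
    sd_event   = c(8.02, 0.10,   88, 0.37, 0.48, 14.49, 13.38)
  )
}

#' Default subgroup distributions of the lobe-wise measures
#'
#' Published lobe-wise subgroup means/SDs of the five measures, encoding the
#' apico-basal gradient (lower lobes denser, less skewed, more shifted).
#'
#' @return A tibble with columns `measure`, `lobe`, `mean_surv`, `sd_surv`,
#'   `mean_event`, `sd_event`.
#' @export
lobe_measure_defaults <- function() {
  lob <- rep(LOBES, times = 5)
  tibble(
    measure = rep(c("delta_p_250", "mean_hu_ratio", "mean_hu_exp",
                    "skewness_exp", "kurtosis_exp"), each = 5),
    lobe = lob,
    mean_surv = c(5.60, 4.01, 14.74, 5.60, 13.57,
                  0.77, 0.81, 0.68, 0.77, 0.69,
                  -607, -641, -491, -595, -502,
                  1.41, 1.52, 0.57, 1.23, 0.66,
                  5.05, 5.65, 2.87, 4.48, 3.24),
    sd_surv = c(4.74, 4.07, 10.39, 5.00, 12.06,
                0.09, 0.07, 0.11, 0.09, 0.13,
                94, 94, 114, 98, 132,
                0.54, 0.63, 0.54, 0.53, 0.61,
                1.89, 2.21, 0.80, 1.81, 1.27),
    mean_event = c(11.41, 6.91, 26.36, 9.25, 21.46,
                   0.70, 0.76, 0.58, 0.71, 0.62,
                   -526, -560, -376, -534, -420,
                   0.86, 0.98, 0.04, 0.80, 0.22,
                   3.44, 3.50, 2.39, 3.29, 2.51),
    sd_event = c(8.55, 4.33, 12.48, 6.78, 13.20,
                 0.11, 0.09, 0.12, 0.10, 0.12,
                 104, 72, 88, 97, 108,
                 0.55, 0.34, 0.37, 0.44, 0.45,
                 1.11, 0.93, 0.46, 0.81, 0.55)
  )
}

# --- transformed marginals -------------------------------------------------
#
# Range-constrained measures are generated as monotone transforms of a
# latent Gaussian: mean_hu_ratio through a logistic map onto (0, 1), the
# percentile shift onto (-100, 100), and kurtosis as 1 + lognormal so the
# kurtosis > 1 bound always holds. Latent parameters are moment-matched so
# the natural-scale mean and SD equal the targets exactly (a parameter-level
# transform would bias the mean through Jensen's inequality).

transform_for <- function(measure) {
  switch(measure,
    mean_hu_ratio = list(type = "logit", lo = 0, hi = 1),
    delta_p_250 = list(type = "logit", lo = -100, hi = 100),
    kurtosis_exp = list(type = "logk"),
    list(type = "identity")
  )
}

apply_transform <- function(tr, w) {
  switch(tr$type,
    identity = w,
    logit = tr$lo + (tr$hi - tr$lo) * stats::plogis(w),
    logk = 1 + exp(w)
  )
}

# Latent (mu, sigma) such that g(N(mu, sigma)) has mean m and sd s.
match_moments <- function(tr, m, s) {
  if (tr$type == "identity") return(c(mu = m, sigma = s))
  if (tr$type == "logk") {
    if (m <= 1) abort("kurtosis mean must exceed 1", class = "hushift_error_spec")
    s2 <- log(1 + s^2 / (m - 1)^2)
    return(c(mu = log(m - 1) - s2 / 2, sigma = sqrt(s2)))
  }
  g <- function(w) apply_transform(tr, w)
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    e1 <- stats::integrate(function(z) g(mu + sigma * z) * dnorm(z),
                           -Inf, Inf, rel.tol = 1e-10)$value
    e2 <- stats::integrate(function(z) g(mu + sigma * z)^2 * dnorm(z),
                           -Inf, Inf, rel.tol = 1e-10)$value
    sdv <- sqrt(max(e2 - e1^2, 0))
    (e1 - m)^2 / s^2 + (sdv - s)^2 / s^2
  }
  p0 <- stats::qlogis((m - tr$lo) / (tr$hi - tr$lo))
  s0 <- s * (tr$hi - tr$lo)^-1 / max(((m - tr$lo) / (tr$hi - tr$lo)) *
                                       (1 - (m - tr$lo) / (tr$hi - tr$lo)), 1e-3)
  fit <- stats::optim(c(p0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Severity-factor signs: positive loadings for measures that increase with
# disease severity, negative otherwise. Correlation magnitude between any
# two generated measures is rho; its sign follows the loadings.
severity_sign <- function(measure) {
  if (measure %in% c("delta_p_250", "mean_hu_exp")) 1 else -1
}

#' Specification of a synthetic two-subgroup cohort
#'
#' @param n_surveillance,n_event Subgroup sizes (defaults 37 and 29).
#' @param measures Total-lung subgroup distributions
#'   ([cohort_measure_defaults()] layout).
#' @param lobes Lobe-wise subgroup distributions ([lobe_measure_defaults()]
#'   layout), or `NULL` to skip lobe metrics.
#' @param rho Exchangeable correlation magnitude between measures on the
#'   latent scale, in `[0, 1)`.
#' @param visit_interval_mean,visit_interval_sd PFT follow-up spacing model
#'   (days).
#' @param visit_noise_sd Measurement noise SD of a single FVC% reading.
#' @param followup_horizon_days Last scheduled PFT day (must allow a visit at
#'   or beyond `min_followup_days`).
#' @param min_followup_days Inclusion criterion: at least one follow-up this
#'   long after the CT (default 183, i.e. six months).
#' @param baseline_offset_mean,baseline_offset_sd Distribution of the
#'   baseline PFT day relative to the CT (days; truncated to +/-50).
#' @param event_days_mean,event_days_sd Time from CT to death/transplant in
#'   the event subgroup (days; truncated to the 3-year window).
#' @param transplant_fraction Fraction of events that are transplants
#'   (default 6/29).
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_surveillance = 37, n_event = 29,
                        measures = cohort_measure_defaults(),
                        lobes = lobe_measure_defaults(),
                        rho = 0.5,
                        visit_interval_mean = 120, visit_interval_sd = 30,
                        visit_noise_sd = 3,
                        followup_horizon_days = 750,
                        min_followup_days = 183,
                        baseline_offset_mean = -4, baseline_offset_sd = 18,
                        event_days_mean = 604, event_days_sd = 294,
                        transplant_fraction = 6 / 29,
                        seed = 1L) {
  stopifnot_scalar_num(n_surveillance, "n_surveillance", lower = 1)
  stopifnot_scalar_num(n_event, "n_event", lower = 1)
  stopifnot_scalar_num(rho, "rho", lower = 0, upper = 1 - 1e-9)
  stopifnot_scalar_num(transplant_fraction, "transplant_fraction", 0, 1)
  measures <- as_tibble(measures)
  if (any(measures$sd_surv <= 0 | measures$sd_event <= 0)) {
    abort("measure sds must be positive", class = "hushift_error_spec")
  }
  if (followup_horizon_days < min_followup_days) {
    abort("infeasible schedule: horizon ends before the minimum follow-up delay",
          class = "hushift_error_spec")
  }
  structure(
    list(n_surveillance = as.integer(n_surveillance),
         n_event = as.integer(n_event),
         measures = measures,
         lobes = if (!is.null(lobes)) as_tibble(lobes),
         rho = rho,
         visit_interval_mean = visit_interval_mean,
         visit_interval_sd = visit_interval_sd,
         visit_noise_sd = visit_noise_sd,
         followup_horizon_days = followup_horizon_days,
         min_followup_days = min_followup_days,
         baseline_offset_mean = baseline_offset_mean,
         baseline_offset_sd = baseline_offset_sd,
         event_days_mean = event_days_mean,
         event_days_sd = event_days_sd,
         transplant_fraction = transplant_fraction,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Variable plan: one row per generated variable (total-lung + lobe-wise),
# with moment-matched latent parameters per subgroup.
cohort_variable_plan <- function(spec) {
  tot <- mutate(spec$measures, lobe = NA_character_,
                var = .data$measure)
  plan <- tot
  if (!is.null(spec$lobes)) {
    lob <- mutate(spec$lobes, var = paste0(.data$measure, "_", .data$lobe))
    plan <- bind_rows(plan, lob)
  }
  plan$sign <- vapply(plan$measure, severity_sign, numeric(1))
  lat <- lapply(seq_len(nrow(plan)), function(i) {
    tr <- transform_for(plan$measure[i])
    list(tr = tr,
         surv = match_moments(tr, plan$mean_surv[i], plan$sd_surv[i]),
         event = match_moments(tr, plan$mean_event[i], plan$sd_event[i]))
  })
  plan$latent <- lat
  plan
}

#' Generate a synthetic cohort
#'
#' Draws one record per patient: subgroup label, correlated total-lung and
#' lobe-wise histogram measures, an irregular FVC% visit series, and outcome
#' fields (event type, days to event, last contact). Within a patient, all
#' measures share a single latent severity factor, giving exchangeable
#' correlation `rho` on the latent scale with physiological signs.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: identifiers, `outcome`
#'   (`"surveillance"`/`"event"`), `event_type`, dates, the total-lung
#'   measure columns, and list-columns `lobe_metrics` (tibble per patient)
#'   and `pft` (visit tibble per patient). Use [cohort_pft()],
#'   [cohort_events()] and [cohort_lobe_metrics()] to unnest.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- cohort_variable_plan(spec)
  n <- spec$n_surveillance + spec$n_event
  group <- rep(c("surveillance", "event"), c(spec$n_surveillance, spec$n_event))
  with_seed(spec$seed, {
    ct_date <- as.Date("2017-01-01") + sample.int(900, n, replace = TRUE)
    u <- rnorm(n) # latent severity factor
    vals <- matrix(NA_real_, n, nrow(plan),
                   dimnames = list(NULL, plan$var))
    for (j in seq_len(nrow(plan))) {
      z <- plan$sign[j] * sqrt(spec$rho) * u + sqrt(1 - spec$rho) * rnorm(n)
      lat <- plan$latent[[j]]
      par <- rbind(lat$surv, lat$event)[ifelse(group == "surveillance", 1, 2), ]
      vals[, j] <- apply_transform(lat$tr, par[, "mu"] + par[, "sigma"] * z)
    }
    # FVC series: linear decline (slope = drawn delta FVC%/year) + noise.
    level <- vals[, "baseline_fvc_pct"]
    slope <- vals[, "delta_fvc_pct"]
    pft <- vector("list", n)
    for (i in seq_len(n)) {
      off <- round(min(50, max(-50, rnorm(1, spec$baseline_offset_mean,
                                          spec$baseline_offset_sd))))
      t <- off
      repeat {
        gap <- max(30, round(rnorm(1, spec$visit_interval_mean,
                                   spec$visit_interval_sd)))
        nxt <- t[length(t)] + gap
        if (nxt > spec$followup_horizon_days) break
        t <- c(t, nxt)
      }
      if (max(t) < spec$min_followup_days) {
        t <- c(t, spec$min_followup_days) # schedule guarantee
      }
      fvc <- pmax(5, level[i] + slope[i] * t / 365 +
                    rnorm(length(t), 0, spec$visit_noise_sd))
      pft[[i]] <- tibble(date = ct_date[i] + t, fvc_pct = fvc)
    }
    is_event <- group == "event"
    d2e <- ifelse(is_event,
                  round(pmin(1095, pmax(30, rnorm(n, spec$event_days_mean,
                                                  spec$event_days_sd)))),
                  NA_real_)
    etype <- ifelse(is_event,
                    ifelse(runif(n) < spec$transplant_fraction,
                           "transplant", "death"),
                    "none")
    last_contact <- ct_date + ifelse(is_event, d2e,
                                     1095 + sample.int(300, n, replace = TRUE))
  })
  lobe_metrics <- if (!is.null(spec$lobes)) {
    lob_plan <- plan[!is.na(plan$lobe), ]
    lapply(seq_len(n), function(i) {
      wide <- tibble(lobe = factor(LOBES, levels = LOBES))
      for (m in unique(lob_plan$measure)) {
        wide[[m]] <- vals[i, paste0(m, "_", LOBES)]
      }
      wide
    })
  } else {
    rep(list(NULL), n)
  }
  out <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    outcome = factor(group, levels = c("surveillance", "event")),
    event_type = etype,
    ct_date = ct_date,
    event_date = ct_date + ifelse(is.na(d2e), NA_real_, d2e),
    last_contact_date = last_contact,
    days_to_event = d2e
  )
  for (m in plan$var[is.na(plan$lobe)]) out[[m]] <- vals[, m]
  out$lobe_metrics <- lobe_metrics
  out$pft <- pft
  out
}

#' Unnest the PFT visit series of a generated cohort
#' @param cohort Output of [generate_cohort()].
#' @return Long tibble `patient_id`, `date`, `fvc_pct`.
#' @export
cohort_pft <- function(cohort) {
  tidyr::unnest(select(cohort, "patient_id", "pft"), "pft")
}

#' Event table of a generated cohort
#' @param cohort Output of [generate_cohort()].
#' @return Tibble `patient_id`, `ct_date`, `event_type`, `event_date`,
#'   `last_contact_date`.
#' @export
cohort_events <- function(cohort) {
  select(cohort, "patient_id", "ct_date", "event_type", "event_date",
         "last_contact_date")
}

#' Long lobe-wise metric table of a generated cohort
#' @param cohort Output of [generate_cohort()].
#' @return Tibble `patient_id`, `outcome`, `lobe`, one column per measure.
#' @export
cohort_lobe_metrics <- function(cohort) {
  tidyr::unnest(select(cohort, "patient_id", "outcome", "lobe_metrics"),
                "lobe_metrics")
}

#' Simulate a cohort with signal in chosen predictors only
#'
#' Model-validation generator: predictors are independent standard Gaussians
#' (on standardized scales) and the event indicator follows a logistic model
#' with the supplied coefficients, so any predictor with coefficient zero is
#' pure noise. Used to study variable-selection behaviour at known truth.
#'
#' @param n Number of patients.
#' @param beta Named coefficients on the standardized predictors; names must
#'   be a subset of the predictor set.
#' @param intercept Logistic intercept.
#' @param predictors Predictor column names to generate.
#' @param seed Integer seed.
#' @return A tibble with an `outcome` factor and the predictor columns.
#' @export
simulate_signal_cohort <- function(n = 500,
                                   beta = c(skewness_exp = -0.8,
                                            baseline_fvc_pct = -0.5),
                                   intercept = -0.3,
                                   predictors = c("baseline_fvc_pct",
                                                  HU_MEASURES),
                                   seed = 1L) {
  if (!all(names(beta) %in% predictors)) {
    abort("names(beta) must be a subset of `predictors`", class = "hushift_error_spec")
  }
  with_seed(seed, {
    x <- matrix(rnorm(n * length(predictors)), n,
                dimnames = list(NULL, predictors))
    eta <- intercept + drop(x[, names(beta), drop = FALSE] %*% beta)
    y <- rbinom(n, 1, stats::plogis(eta))
  })
  out <- as_tibble(x)
  out$outcome <- factor(ifelse(y == 1, "event", "surveillance"),
                        levels = c("surveillance", "event"))
  out$patient_id <- sprintf("S%04d", seq_len(n))
  out
}
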