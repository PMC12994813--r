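# Clinical record assembly: PFT pairing, one-year FVC% interpolation,
# three-year outcome assignment, and cohort-table construction with an
# explicit inclusion/exclusion ledger.

#' Select the baseline pulmonary function test for a CT date
#'
#' Picks the visit with the shortest delay to the CT scan; the pairing is
#' only accepted when that delay is within `window` days (inclusion
#' criterion). Ties between an earlier and a later visit at the same
#' absolute delay are broken toward the earlier visit.
#'
#' @param pft Data frame with columns `date` (Date) and `fvc_pct`.
#' @param ct_date CT scan date.
#' @param window Maximal |delay| in days (default 50).
#' @return One-row tibble `date`, `fvc_pct`, `offset_days`.
#' @export
select_baseline_pft <- function(pft, ct_date, window = 50) {
  pft <- as_tibble(pft)
  if (nrow(pft) == 0L) abort("empty PFT series", class = "hushift_error_input")
  off <- as.numeric(as.Date(pft$date) - as.Date(ct_date))
  ord <- order(abs(off), off) # tie -> earlier visit
  best <- ord[1]
  if (abs(off[best]) > window) {
    abort(sprintf("no PFT within %d days of CT (nearest at %+d days)",
                  window, as.integer(off[best])),
          class = "hushift_error_no_baseline")
  }
  tibble(date = as.Date(pft$date[best]), fvc_pct = pft$fvc_pct[best],
         offset_days = off[best])
}

#' Interpolate FVC% to exactly one year after the CT scan
#'
#' Fits least-squares polynomials in time (days since CT) of degree 1 up to
#' `max_degree`, capped at `n_visits - 2` so at least one residual degree of
#' freedom remains, selects the degree with the lowest Gaussian AIC (ties,
#' including the all-perfect-fit case on noiseless data, resolve to the
#' lowest degree), and evaluates the selected fit at day 365. Evaluation
#' beyond the last visit is permitted but reported as extrapolation.
#'
#' @param pft Data frame with columns `date` and `fvc_pct`; at least two
#'   visits.
#' @param ct_date CT scan date.
#' @param max_degree Highest polynomial degree considered (default 4).
#' @param at_days Evaluation time in days after the CT (default 365).
#' @return One-row tibble `fvc_pct_1yr`, `degree`, `n_visits`,
#'   `extrapolated`.
#' @export
interpolate_fvc_1yr <- function(pft, ct_date, max_degree = 4, at_days = 365) {
  pft <- as_tibble(pft)
  if (nrow(pft) < 2L) {
    abort("need at least 2 PFT visits for interpolation", class = "hushift_error_input")
  }
  t <- as.numeric(as.Date(pft$date) - as.Date(ct_date))
  if (anyDuplicated(t)) abort("duplicate PFT dates", class = "hushift_error_input")
  y <- pft$fvc_pct
  degs <- seq_len(max(1L, min(max_degree, length(t) - 2L)))
  fits <- lapply(degs, function(d) lm(y ~ poly(t, d, raw = FALSE)))
  aics <- vapply(fits, AIC, numeric(1)) # -Inf on perfect fits; first (lowest
  best <- which.min(aics)               # degree) wins ties
  fit <- fits[[best]]
  pred <- unname(predict(fit, newdata = data.frame(t = at_days)))
  if (!is.finite(pred)) abort("non-finite interpolated FVC%", class = "hushift_error_input")
  tibble(fvc_pct_1yr = pred, degree = degs[best], n_visits = length(t),
         extrapolated = at_days > max(t))
}

#' Assign the three-year outcome subgroup
#'
#' Death or transplantation within the observation window puts a patient in
#' the event subgroup; a patient is in clinical surveillance only when
#' follow-up demonstrably covers the whole window (last contact, or an event
#' beyond the window, at `window` days or later). Anything else is lost to
#' follow-up and must be excluded rather than classified.
#'
#' @param ct_date CT scan date.
#' @param event_type `"death"`, `"transplant"` or `"none"`.
#' @param event_date Event date or `NA`.
#' @param last_contact_date Date of last contact.
#' @param window Observation window in days (default 1095, i.e. 3 years).
#' @return One-row tibble `outcome` (`"event"`, `"surveillance"` or
#'   `"lost_to_followup"`), `event_type`, `days_to_event`.
#' @export
assign_outcome <- function(ct_date, event_type = "none", event_date = NA,
                           last_contact_date = NA, window = 1095) {
  ct_date <- as.Date(ct_date)
  has_event <- !is.na(event_type) && event_type %in% c("death", "transplant")
  if (has_event) {
    d2e <- as.numeric(as.Date(event_date) - ct_date)
    if (!is.finite(d2e)) abort("event without a valid event date", class = "hushift_error_input")
    if (d2e < 0) abort("event precedes the CT date", class = "hushift_error_input")
    if (d2e <= window) {
      return(tibble(outcome = "event", event_type = event_type,
                    days_to_event = d2e))
    }
    # survived the window; event afterwards proves complete follow-up
    return(tibble(outcome = "surveillance", event_type = "none",
                  days_to_event = NA_real_))
  }
  followup <- as.numeric(as.Date(last_contact_date) - ct_date)
  if (is.finite(followup) && followup >= window) {
    return(tibble(outcome = "surveillance", event_type = "none",
                  days_to_event = NA_real_))
  }
  tibble(outcome = "lost_to_followup", event_type = "none",
         days_to_event = NA_real_)
}

#' Assemble the analysis cohort from clinical tables
#'
#' Joins per-patient PFT series, event records and (optionally) total-lung
#' histogram metrics into one analysis row per patient: baseline FVC%,
#' one-year interpolated FVC%, their difference (`delta_fvc_pct`), and the
#' outcome subgroup. Patients failing an inclusion criterion (no baseline
#' PFT within the pairing window, insufficient follow-up PFTs, lost to
#' follow-up) are dropped and accounted for in the exclusion ledger, so
#' every input patient appears exactly once in the cohort or the ledger.
#'
#' @param pft Long data frame `patient_id`, `date`, `fvc_pct`.
#' @param events Data frame `patient_id`, `ct_date`, `event_type`,
#'   `event_date`, `last_contact_date`.
#' @param metrics Optional data frame of histogram metrics with `patient_id`
#'   and measure columns; rows with a `region` column are filtered to
#'   `"TOTAL"`.
#' @param config An [analysis_config()] supplying the pairing window,
#'   follow-up minimum and observation window.
#' @return A tibble of included patients; the exclusion ledger (tibble
#'   `patient_id`, `reason`) is attached as attribute `"excluded"` and
#'   readable with [excluded_patients()].
#' @export
build_cohort <- function(pft, events, metrics = NULL,
                         config = analysis_config()) {
  pft <- as_tibble(pft); events <- as_tibble(events)
  need <- c("patient_id", "ct_date", "event_type", "event_date",
            "last_contact_date")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    abort(paste0("events table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "hushift_error_schema")
  }
  included <- list(); excluded <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    pid <- ev$patient_id
    series <- filter(pft, .data$patient_id == pid)
    res <- tryCatch({
      base <- select_baseline_pft(series, ev$ct_date,
                                  window = config$pft_pairing_window_days)
      t <- as.numeric(as.Date(series$date) - as.Date(ev$ct_date))
      if (max(t) < config$min_followup_days) {
        abort("no follow-up PFT beyond the minimum delay",
              class = "hushift_error_no_followup")
      }
      interp <- interpolate_fvc_1yr(series, ev$ct_date)
      out <- assign_outcome(ev$ct_date, ev$event_type, ev$event_date,
                            ev$last_contact_date,
                            window = config$observation_window_days)
      if (out$outcome == "lost_to_followup") {
        abort("lost to follow-up before the observation window closed",
              class = "hushift_error_lost")
      }
      tibble(
        patient_id = pid, ct_date = as.Date(ev$ct_date),
        baseline_fvc_pct = base$fvc_pct,
        baseline_pft_offset_days = base$offset_days,
        fvc_pct_1yr = interp$fvc_pct_1yr,
        delta_fvc_pct = interp$fvc_pct_1yr - base$fvc_pct,
        interp_degree = interp$degree,
        outcome = out$outcome, event_type = out$event_type,
        days_to_event = out$days_to_event
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        tibble(patient_id = pid, reason = conditionMessage(res))
    } else {
      included[[length(included) + 1L]] <- res
    }
  }
  cohort <- bind_rows(included)
  if (nrow(cohort)) {
    cohort$outcome <- factor(cohort$outcome, levels = c("surveillance", "event"))
    if (!is.null(metrics)) {
      metrics <- as_tibble(metrics)
      if ("region" %in% names(metrics)) {
        metrics <- filter(metrics, .data$region == "TOTAL")
        metrics <- select(metrics, -"region")
      }
      cohort <- left_join(cohort, metrics, by = "patient_id")
    }
  }
  exc <- bind_rows(excluded)
  if (!nrow(exc)) exc <- tibble(patient_id = character(), reason = character())
  attr(cohort, "excluded") <- exc
  cohort
}

#' Exclusion ledger of a cohort built with [build_cohort()]
#' @param cohort Output of [build_cohort()].
#' @return Tibble `patient_id`, `reason` (empty when nobody was excluded).
#' @export
excluded_patients <- function(cohort) {
  attr(cohort, "excluded") %||% tibble(patient_id = character(),
                                       reason = character())
}
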