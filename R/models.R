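# Prognostic logistic models: maximum-likelihood fits, DeLong AUC
# confidence intervals, AIC-guided backward elimination, and the three-model
# comparison suite (FVC%-only, CT-measures, parsimonious) with its
# transplant-excluded sensitivity rerun. Predictors enter untransformed and
# unstandardized; reported AUCs are apparent (in-sample), matching the
# design being emulated.

event_indicator <- function(cohort, outcome_col = "outcome",
                            event_level = "event") {
  v <- cohort[[outcome_col]]
  if (is.null(v)) {
    abort(sprintf("cohort lacks outcome column `%s`", outcome_col),
          class = "hushift_error_schema")
  }
  y <- as.integer(as.character(v) == event_level)
  if (length(unique(y)) < 2L) {
    abort("outcome has a single class; logistic fit undefined",
          class = "hushift_error_input")
  }
  y
}

#' AUC with DeLong standard error and 95% confidence interval
#'
#' The AUC is the Mann-Whitney two-sample estimator with midrank tie
#' handling: the probability that a random event patient scores above a
#' random non-event patient (ties count half). Its variance is estimated
#' from the DeLong structural components (per-subject placement values) and
#' the 95% CI is Wald on the AUC scale, truncated to `[0, 1]`. A zero
#' variance (e.g. perfect ranking) yields a degenerate zero-width interval,
#' flagged rather than hidden.
#'
#' @param scores Numeric risk scores (higher = more event-like).
#' @param labels Event indicator: logical, 0/1, or a factor whose
#'   `event_level` marks events.
#' @param event_level Label counted as an event when `labels` is not
#'   numeric/logical (default `"event"`).
#' @return One-row tibble `auc`, `se`, `ci_low`, `ci_high`, `n_event`,
#'   `n_control`, `degenerate`.
#' @export
auc_delong <- function(scores, labels, event_level = "event") {
  check_values(scores, "scores")
  y <- if (is.numeric(labels) || is.logical(labels)) {
    as.integer(labels)
  } else {
    as.integer(as.character(labels) == event_level)
  }
  if (length(y) != length(scores)) {
    abort("scores and labels differ in length", class = "hushift_error_input")
  }
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  if (m == 0L || n == 0L) {
    abort("both classes must be present for an AUC", class = "hushift_error_input")
  }
  # Placement values via midranks: V10[i] = mean_j psi(x_i, y_j).
  r_all <- rank(c(xs, ys))
  v10 <- (r_all[seq_len(m)] - rank(xs)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(ys)) / m
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
  tibble(auc = auc, se = se, ci_low = ci[1], ci_high = ci[2],
         n_event = m, n_control = n, degenerate = se == 0)
}

#' Fit a logistic prognostic model
#'
#' Maximum-likelihood logistic regression of the event indicator on the
#' given predictors (iteratively reweighted least squares, at most 100
#' iterations, convergence tolerance 1e-8), with standard errors from the
#' observed information. Complete or quasi-complete separation -- diverging
#' coefficients pinning fitted probabilities to 0/1 -- is detected and
#' flagged on the result rather than silently returned. The apparent AUC of
#' the fitted probabilities with its DeLong CI is attached.
#'
#' @param cohort Data frame with the outcome and predictor columns.
#' @param predictors Character vector of predictor column names; `character(0)`
#'   fits the intercept-only model.
#' @param outcome_col,event_level Outcome column and event label.
#' @return An object of class `hushift_logit` (supports [generics::tidy()],
#'   [generics::glance()], `print()`, `autoplot()`).
#' @export
fit_outcome_model <- function(cohort, predictors, outcome_col = "outcome",
                              event_level = "event") {
  cohort <- as_tibble(cohort)
  y <- event_indicator(cohort, outcome_col, event_level)
  if (length(y) < 10L) {
    abort("need at least 10 records for a logistic fit", class = "hushift_error_input")
  }
  miss <- setdiff(predictors, names(cohort))
  if (length(miss)) {
    abort(paste0("cohort lacks predictor(s): ", paste(miss, collapse = ", ")),
          class = "hushift_error_schema")
  }
  dat <- cohort[, predictors, drop = FALSE]
  dat$.y <- y
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = ".y")
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  separation <- !fit$converged || max(abs(predict(fit, type = "link"))) > 20
  structure(
    list(fit = fit, predictors = predictors, n = length(y),
         n_event = sum(y), separation = separation,
         auc = auc_delong(fitted(fit), y)),
    class = "hushift_logit"
  )
}

#' @export
print.hushift_logit <- function(x, ...) {
  cat("Logistic prognostic model (", x$n, " patients, ", x$n_event,
      " events)\n", sep = "")
  cat("Predictors:",
      if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  if (x$separation) cat("WARNING: separation detected; estimates diverge\n")
  print(summary(x$fit)$coefficients)
  cat(sprintf("AIC %.2f | AUC %.3f (95%% CI %.3f-%.3f, DeLong)\n",
              AIC(x$fit), x$auc$auc, x$auc$ci_low, x$auc$ci_high))
  invisible(x)
}

#' AIC-guided backward elimination
#'
#' Greedy backward search from the full predictor set: at each step the AIC
#' of every single-predictor deletion is evaluated and the deletion with the
#' lowest AIC is applied if it strictly lowers the current AIC; the search
#' stops otherwise. Ties between deletions (within `1e-8` of AIC) are broken
#' by dropping the predictor with the largest Wald p-value. Elimination may
#' run all the way down to the intercept-only model.
#'
#' @inheritParams fit_outcome_model
#' @param predictors Full starting predictor set.
#' @return The final `hushift_logit`, with attributes `retained` (character)
#'   and `trace` (tibble `step`, `dropped`, `aic`).
#' @export
backward_eliminate <- function(cohort, predictors, outcome_col = "outcome",
                               event_level = "event") {
  current <- predictors
  fit <- fit_outcome_model(cohort, current, outcome_col, event_level)
  trace <- tibble(step = 0L, dropped = NA_character_, aic = AIC(fit$fit))
  step <- 0L
  while (length(current) > 0L) {
    cand <- lapply(current, function(p) {
      fit_outcome_model(cohort, setdiff(current, p), outcome_col, event_level)
    })
    aics <- vapply(cand, function(f) AIC(f$fit), numeric(1))
    best_aic <- min(aics)
    if (best_aic >= AIC(fit$fit)) break
    tied <- which(aics <= best_aic + 1e-8)
    drop_idx <- if (length(tied) > 1L) {
      wald <- summary(fit$fit)$coefficients
      pvals <- vapply(current[tied], function(p) {
        if (p %in% rownames(wald)) wald[p, 4] else 1
      }, numeric(1))
      tied[which.max(pvals)]
    } else {
      tied
    }
    step <- step + 1L
    trace <- bind_rows(trace, tibble(step = step, dropped = current[drop_idx],
                                     aic = aics[drop_idx]))
    fit <- cand[[drop_idx]]
    current <- setdiff(current, current[drop_idx])
  }
  attr(fit, "retained") <- current
  attr(fit, "trace") <- trace
  fit
}

#' Fit the three prognostic models with sensitivity rerun
#'
#' Fits (1) the FVC%-only reference model, (2) the CT model on the five
#' histogram measures, and (3) the parsimonious model obtained by backward
#' elimination from FVC% plus all five measures; then refits all three on
#' the transplant-excluded subset (sensitivity analysis). Requires an
#' `event_type` column so transplants can be filtered without refitting
#' machinery.
#'
#' @param cohort Data frame with `outcome`, `event_type`, `baseline_fvc_pct`
#'   and the five measure columns.
#' @param ct_measures CT predictor set (default the five measures).
#' @param fvc Baseline FVC% column name.
#' @return An object of class `hushift_model_suite`: lists `models` and
#'   `sensitivity` of `hushift_logit` objects named `fvc`, `ct`,
#'   `parsimonious`, plus the retained parsimonious predictors.
#' @export
run_model_suite <- function(cohort, ct_measures = HU_MEASURES,
                            fvc = "baseline_fvc_pct") {
  cohort <- as_tibble(cohort)
  if (is.null(cohort$event_type)) {
    abort("cohort lacks `event_type` (needed for the sensitivity subset)",
          class = "hushift_error_schema")
  }
  fit_three <- function(dat) {
    pars <- backward_eliminate(dat, c(fvc, ct_measures))
    list(fvc = fit_outcome_model(dat, fvc),
         ct = fit_outcome_model(dat, ct_measures),
         parsimonious = pars)
  }
  primary <- fit_three(cohort)
  sens_cohort <- filter(cohort, .data$event_type != "transplant")
  sensitivity <- fit_three(sens_cohort)
  structure(
    list(models = primary, sensitivity = sensitivity,
         retained = attr(primary$parsimonious, "retained"),
         n = nrow(cohort), n_sensitivity = nrow(sens_cohort)),
    class = "hushift_model_suite"
  )
}

#' @export
print.hushift_model_suite <- function(x, ...) {
  cat("Prognostic model suite:", x$n, "patients (sensitivity subset:",
      x$n_sensitivity, ")\n")
  cat("Parsimonious predictors:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n\n")
  print(glance(x))
  invisible(x)
}
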