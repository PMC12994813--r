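# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of a logistic prognostic model
#'
#' @param x A `hushift_logit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy hushift_logit
#' @export
tidy.hushift_logit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row summary of a logistic prognostic model
#'
#' @param x A `hushift_logit`.
#' @param ... Unused.
#' @return Tibble `n`, `n_event`, `df`, `logLik`, `aic`, `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `separation`.
#' @method glance hushift_logit
#' @export
glance.hushift_logit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event,
         df = length(coef(x$fit)),
         logLik = as.numeric(logLik(x$fit)), aic = AIC(x$fit),
         auc = x$auc$auc, auc_ci_low = x$auc$ci_low,
         auc_ci_high = x$auc$ci_high, separation = x$separation)
}

#' Tidy coefficient table of a model suite
#'
#' @param x A `hushift_model_suite`.
#' @param ... Unused.
#' @return Tibble `analysis` (`"primary"`/`"sensitivity"`), `model`, then
#'   the [tidy.hushift_logit()] columns.
#' @method tidy hushift_model_suite
#' @export
tidy.hushift_model_suite <- function(x, ...) {
  block <- function(models, label) {
    bind_rows(lapply(names(models), function(nm) {
      mutate(tidy(models[[nm]]), model = nm, analysis = label)
    }))
  }
  out <- bind_rows(block(x$models, "primary"),
                   block(x$sensitivity, "sensitivity"))
  select(out, "analysis", "model", "term", "estimate", "std.error",
         "statistic", "p.value")
}

#' Per-model summary of a model suite
#'
#' @param x A `hushift_model_suite`.
#' @param ... Unused.
#' @return Tibble with one row per model and analysis: fit and AUC summary.
#' @method glance hushift_model_suite
#' @export
glance.hushift_model_suite <- function(x, ...) {
  block <- function(models, label) {
    bind_rows(lapply(names(models), function(nm) {
      mutate(glance(models[[nm]]), model = nm, analysis = label)
    }))
  }
  out <- bind_rows(block(x$models, "primary"),
                   block(x$sensitivity, "sensitivity"))
  select(out, "analysis", "model", "n", "n_event", "aic", "auc",
         "auc_ci_low", "auc_ci_high", "separation")
}
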