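# Descriptive statistics: Pearson correlations, Mann-Whitney U subgroup
# comparisons, and upper-vs-lower-lobe paired t tests. Two-sided tests
# throughout; no multiple-testing correction is applied across measures (the
# handful of measures is reported as-is -- interpret small p-values with
# that in mind).

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums. For groups of at most `exact_max`
#' observations each with no ties, the p-value is exact (two-sided by
#' doubling the smaller tail of the exact U distribution, capped at 1);
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest per-group size for the exact branch (default 8).
#' @return One-row tibble `n_x`, `n_y`, `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  check_values(x, "group x"); check_values(y, "group y")
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- min(1, 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2)))
    method <- "exact"
  } else {
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- u - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(n_x = n1, n_y = n2, u = u, p = p, method = method)
}

#' Pearson correlations between histogram measures and FVC% endpoints
#'
#' Product-moment correlation of each measure against each target, with the
#' two-tailed p-value from the t transform `r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. Complete cases per pair.
#'
#' @param cohort Data frame with the measure and target columns.
#' @param measures Measure columns (default the five histogram measures).
#' @param targets Target columns (default baseline and delta FVC%).
#' @return Tibble `measure`, `target`, `n`, `r`, `p`.
#' @export
correlate_measures <- function(cohort,
                               measures = HU_MEASURES,
                               targets = c("baseline_fvc_pct", "delta_fvc_pct")) {
  cohort <- as_tibble(cohort)
  grid <- expand.grid(measure = measures, target = targets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cohort[[grid$measure[i]]]; y <- cohort[[grid$target[i]]]
    if (is.null(x) || is.null(y)) {
      abort(sprintf("cohort lacks column `%s`",
                    if (is.null(x)) grid$measure[i] else grid$target[i]),
            class = "hushift_error_schema")
    }
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) abort("need n >= 3 for correlation", class = "hushift_error_input")
    if (sd(x) == 0 || sd(y) == 0) {
      abort("zero-variance variable in correlation", class = "hushift_error_input")
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble(measure = grid$measure[i], target = grid$target[i],
           n = length(x), r = unname(ct$estimate), p = ct$p.value)
  })
  bind_rows(rows)
}

#' Subgroup comparison of measures (means, SDs and Mann-Whitney U)
#'
#' For each measure: per-subgroup mean, SD and n, plus the two-sided
#' Mann-Whitney U test between the subgroups. Means and SDs are reported
#' alongside the rank test deliberately, matching the conventional
#' presentation of such cohort tables.
#'
#' @param cohort Data frame with an outcome column and the measure columns.
#' @param measures Columns to compare (default the five measures plus
#'   baseline and delta FVC%).
#' @param group_col Name of the grouping column (default `"outcome"`); it
#'   must have exactly two levels present.
#' @return Tibble, one row per measure, with `mean_*`, `sd_*`, `n_*` for
#'   both groups and `u`, `p`, `method`.
#' @export
compare_subgroups <- function(cohort,
                              measures = c(HU_MEASURES, "baseline_fvc_pct",
                                           "delta_fvc_pct"),
                              group_col = "outcome") {
  cohort <- as_tibble(cohort)
  g <- factor(cohort[[group_col]])
  if (is.null(cohort[[group_col]]) || nlevels(droplevels(g)) != 2L) {
    abort(sprintf("`%s` must have exactly two groups", group_col),
          class = "hushift_error_schema")
  }
  g <- droplevels(g)
  lv <- levels(g)
  rows <- lapply(measures, function(m) {
    v <- cohort[[m]]
    if (is.null(v)) {
      abort(sprintf("cohort lacks column `%s`", m), class = "hushift_error_schema")
    }
    a <- v[g == lv[1] & is.finite(v)]
    b <- v[g == lv[2] & is.finite(v)]
    mw <- mann_whitney_u(a, b)
    out <- tibble(measure = m,
                  mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                  mean_b = mean(b), sd_b = sd(b), n_b = length(b),
                  u = mw$u, p = mw$p, method = mw$method)
    names(out) <- sub("_a$", paste0("_", lv[1]), names(out))
    names(out) <- sub("_b$", paste0("_", lv[2]), names(out))
    out
  })
  bind_rows(rows)
}

#' Paired t tests between upper and lower lobes
#'
#' One-sample t test on within-patient differences (first minus second lobe
#' of each pair) for each measure, two-sided. Patients missing either lobe
#' value are dropped from that pair. When all differences are identical the
#' t statistic is degenerate: an all-zero difference returns t = 0, p = 1;
#' a constant nonzero difference is reported with `p = 0` and
#' `degenerate = TRUE` (the evidence is unbounded, not measurable).
#'
#' @param lobe_metrics Long data frame `patient_id`, `lobe`, measure columns
#'   (e.g. from [cohort_lobe_metrics()]).
#' @param measures Measure columns to test (default the five measures).
#' @param pairs List of length-2 lobe vectors (default RUL-RLL and LUL-LLL).
#' @return Tibble `measure`, `lobe_a`, `lobe_b`, `n`, `mean_diff`, `t`,
#'   `df`, `p`, `degenerate`.
#' @export
lobe_contrasts <- function(lobe_metrics, measures = HU_MEASURES,
                           pairs = list(c("RUL", "RLL"), c("LUL", "LLL"))) {
  lobe_metrics <- as_tibble(lobe_metrics)
  rows <- list()
  for (m in measures) {
    for (pr in pairs) {
      wide <- tidyr::pivot_wider(
        select(filter(lobe_metrics, .data$lobe %in% pr),
               "patient_id", "lobe", all_of(m)),
        names_from = "lobe", values_from = all_of(m))
      d <- wide[[pr[1]]] - wide[[pr[2]]]
      d <- d[is.finite(d)]
      if (length(d) < 2L) abort("need >= 2 complete pairs", class = "hushift_error_input")
      sdd <- sd(d)
      if (sdd == 0) {
        res <- tibble(measure = m, lobe_a = pr[1], lobe_b = pr[2],
                      n = length(d), mean_diff = mean(d),
                      t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                      df = length(d) - 1,
                      p = if (mean(d) == 0) 1 else 0,
                      degenerate = mean(d) != 0)
      } else {
        tt <- mean(d) / (sdd / sqrt(length(d)))
        res <- tibble(measure = m, lobe_a = pr[1], lobe_b = pr[2],
                      n = length(d), mean_diff = mean(d), t = tt,
                      df = length(d) - 1,
                      p = 2 * pt(-abs(tt), df = length(d) - 1),
                      degenerate = FALSE)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  bind_rows(rows)
}

#' Lobe-wise subgroup summary table
#'
#' Mean and SD of every measure for every lobe within every subgroup, in a
#' fixed measure-by-lobe order (the lobe-table layout of the analysis
#' report).
#'
#' @param lobe_metrics Long data frame `patient_id`, `outcome`, `lobe`,
#'   measure columns.
#' @param measures Measure columns (default the five measures).
#' @param group_col Grouping column (default `"outcome"`).
#' @return Tibble `measure`, `lobe`, group column, `n`, `mean`, `sd`.
#' @export
summarize_lobes <- function(lobe_metrics, measures = HU_MEASURES,
                            group_col = "outcome") {
  lobe_metrics <- as_tibble(lobe_metrics)
  long <- tidyr::pivot_longer(lobe_metrics, all_of(measures),
                              names_to = "measure", values_to = "value")
  out <- summarise(
    group_by(long, .data$measure, .data$lobe, .data[[group_col]]),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    sd = sd(.data$value[is.finite(.data$value)]),
    .groups = "drop"
  )
  out$measure <- factor(out$measure, levels = measures)
  out$lobe <- factor(out$lobe, levels = LOBES)
  arrange(out, .data$measure, .data$lobe)
}
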