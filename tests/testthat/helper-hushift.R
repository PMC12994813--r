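# Shared fixtures and independent oracles used across test files.

# Tiny paired volumes with a full five-lobe mask (2 voxels per lobe by
# default), built by hand so expected values are enumerable.
tiny_pair <- function(values_per_lobe = 2) {
  n <- 5 * values_per_lobe
  dims <- c(n, 1, 1)
  mask <- array(rep(1:5, each = values_per_lobe), dim = dims)
  insp <- array(rep(c(-800, -600), length.out = n), dim = dims)
  expv <- insp + 100
  list(insp = insp, exp = expv, mask = mask)
}

# Brute-force two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# group assignments of the pooled sample (midranks throughout).
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Stratified bootstrap SE of the AUC (resampling within outcome classes).
auc_boot_se <- function(scores, y, B = 2000) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  auc_of <- function(a, b) {
    r <- rank(c(a, b))
    (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
      (length(a) * length(b))
  }
  stats::sd(replicate(B, {
    auc_of(sample(xs, replace = TRUE), sample(ys, replace = TRUE))
  }))
}

# Exhaustive all-subsets minimum-AIC search over logistic models.
best_subset_aic <- function(cohort, predictors) {
  subsets <- unlist(lapply(0:length(predictors), function(k) {
    utils::combn(predictors, k, simplify = FALSE)
  }), recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    f <- fit_outcome_model(cohort, s)
    stats::AIC(f$fit)
  }, numeric(1))
  list(aic = min(aics), subset = subsets[[which.min(aics)]])
}
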