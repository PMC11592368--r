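# Independent brute-force SampEn pair counter (vectorized over full distance
# matrices) used as the oracle against the production kernel. Deliberately a
# different algorithm: materializes all pairwise Chebyshev distances.
sampen_counts_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  idx <- seq_len(nt)
  D <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    D <- pmax(D, abs(outer(x[idx + k], x[idx + k], "-")))
  }
  match_m <- D <= r
  match_m1 <- match_m & (abs(outer(x[idx + m], x[idx + m], "-")) <= r)
  ut <- upper.tri(match_m)
  c(A = as.numeric(sum(match_m1[ut])), B = as.numeric(sum(match_m[ut])))
}

# ICC(2,k) via an explicit two-way ANOVA fit (aov), independent of the
# closed-form mean squares used in the package.
icc2k_oracle <- function(ratings) {
  unit <- interaction(ratings$subject, ratings$item, drop = TRUE)
  rater <- factor(ratings$rater)
  fit <- stats::aov(score ~ unit + rater, data = cbind(ratings, unit = unit))
  ms <- summary(fit)[[1]][, "Mean Sq"]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  n <- nlevels(unit)
  (ms["unit"] - ms["Residuals"]) /
    (ms["unit"] + (ms["rater"] - ms["Residuals"]) / n)
}

# Epoch a synthetic cohort's EEG without the filtering stage and return the
# tidy MSE table for the given task (the statistical-calibration path).
cohort_mse_table <- function(co, task = "metacontrol",
                             params = mse_params(scales = 1:15)) {
  spec <- co$spec
  win <- if (task == "metacontrol") spec$epoch_ms_metacontrol else
    spec$epoch_ms_aut
  rows <- lapply(co$profiles$subject, function(sid) {
    ep <- epoch_baseline(co$eeg_for(sid, task), win, c(-500, 0))
    mse_table(ep, params, subject = sid, task = task)
  })
  do.call(rbind, rows)
}

# Profile (ground-truth) group lookup for a cohort.
cohort_groups <- function(co) {
  stats::setNames(co$profiles$profile, co$profiles$subject)
}
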