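# Independent oracles and fixture builders used across the suite.

# Brute-force band powers: explicit double loop over bins and samples with
# plain sin/cos sums — no fft(). Mirrors the declared normalization contract
# (Hann window, energy normalization, half-open bands) so that band_powers()
# can be checked against an implementation that shares no code with it.
brute_band_powers <- function(segment, fs = 4) {
  n <- length(segment)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  xw <- (segment - mean(segment)) * w
  lf <- 0
  hf <- 0
  for (k in seq_len(n %/% 2)) {
    re <- 0
    im <- 0
    for (j in seq_len(n)) {
      ang <- 2 * pi * k * (j - 1) / n
      re <- re + xw[j] * cos(ang)
      im <- im - xw[j] * sin(ang)
    }
    p <- 2 * (re^2 + im^2) / (n * sum(w^2))
    f <- k * fs / n
    if (f > 0.04 && f <= 0.15 + 1e-12) lf <- lf + p
    if (f > 0.15 && f <= 0.40 + 1e-12) hf <- hf + p
  }
  c(lf = lf, hf = hf)
}

# Double-loop leave-one-out oracle: independent fold bookkeeping,
# prediction and confusion-matrix aggregation.
loocv_oracle <- function(data, threshold = 0) {
  n <- nrow(data)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_logistic(data[-i, , drop = FALSE])
    score[i] <- logit_score(data[i, , drop = FALSE], fit)
  }
  pred <- ifelse(score > threshold, "healthy", "MDD")
  tp <- 0; fn <- 0; tn <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (data$label[i] == "MDD") {
      if (pred[i] == "MDD") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == "healthy") tn <- tn + 1 else fp <- fp + 1
    }
  }
  list(score = score, predicted = pred,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

# Fraction of true beats recovered within tol_s by the detected series.
recovery_rate <- function(detected, truth, tol_s) {
  mean(vapply(truth, function(b) min(abs(detected - b)) <= tol_s,
              logical(1)))
}

# A small synthetic cohort with group separation on all nine variables.
make_separated_cohort <- function(n_mdd, n_healthy, seed) {
  ord <- canonical_features()
  gp <- group_params(
    mdd_mean = setNames(c(85, 88, 82, 56, 29, 63, 3.5, 6.6, 4.6), ord),
    mdd_sd = setNames(c(4, 4, 4, 10, 6, 10, 0.7, 1, 0.9), ord),
    healthy_mean = setNames(c(74, 78, 70, 160, 80, 150, 1.5, 4.5, 2), ord),
    healthy_sd = setNames(c(4, 4, 4, 30, 18, 30, 0.7, 1, 0.8), ord))
  simulate_feature_cohort(gp, n_mdd, n_healthy, seed = seed)
}

# Cohort features without group structure, for harnesses that relabel rows.
make_featureonly_cohort <- function(n, seed) {
  ord <- canonical_features()
  mu <- setNames(c(75, 78, 72, 200, 150, 210, 3, 5, 4), ord)
  sdv <- setNames(c(8, 8, 8, 60, 50, 60, 1, 1.5, 1.2), ord)
  gp <- group_params(mu, sdv, mu, sdv)
  coh <- simulate_feature_cohort(gp, ceiling(n / 2), floor(n / 2),
                                 seed = seed)
  attr(coh, "mu") <- mu
  attr(coh, "sd") <- sdv
  coh
}
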