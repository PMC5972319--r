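mdd_mean_vector <- function() {
  setNames(c(84.7, 87.9, 82.2, 56.4, 29.4, 62.8, 3.5, 6.6, 4.6),
           canonical_features())
}

test_that("phase features average window centers into the right phase", {
  hrv <- tibble::tibble(window_center_s = seq(15, 305, by = 2),
                        hr_bpm = 75, lf_ms2 = 100, hf_ms2 = 100, lfhf = 1)
  f <- phase_features(hrv)
  expect_equal(unlist(f), setNames(c(75, 75, 75, 100, 100, 100, 1, 1, 1),
                                   canonical_features()))

  # center attribution over the 320-s protocol: 43 / 50 / 53 windows
  ph <- cut(hrv$window_center_s, c(0, 100, 200, 320), right = FALSE)
  expect_equal(as.integer(table(ph)), c(43, 50, 53))
  # recover the counts through the feature means themselves
  hrv2 <- hrv
  hrv2$hf_ms2 <- as.integer(ph)          # 1/2/3 by phase
  f2 <- phase_features(hrv2)
  expect_equal(unname(unlist(f2[c("hf_before", "hf_during", "hf_after")])),
               c(1, 2, 3))

  # a step change at the task onset moves only the during/after means
  hrv3 <- hrv
  hrv3$hf_ms2 <- ifelse(hrv$window_center_s < 100, 300, 120)
  f3 <- phase_features(hrv3)
  expect_gt(f3$hf_before, f3$hf_during)

  # an empty phase is a named error
  expect_error(phase_features(hrv[hrv$window_center_s >= 100, ]),
               "before")
})

test_that("the frozen model scores are exact", {
  m <- reference_model()
  zero <- setNames(rep(0, 9), canonical_features())
  expect_identical(logit_score(zero, m), 605.15)

  # independent dot-product oracle over the published coefficients
  coefs <- c(0.23, 6.43, -9.7, -4.97, 4.73, -3.59, -36.78, 30.81, -87.24)
  x <- mdd_mean_vector()
  oracle <- sum(coefs * unname(x)) + 605.15
  expect_equal(logit_score(x, m), oracle, tolerance = 1e-12)
  expect_equal(oracle, -300.898, tolerance = 1e-9)

  # linearity: score of a mean equals mean of scores
  y <- x * 1.3 + 2
  expect_equal(logit_score((x + y) / 2, m),
               mean(c(logit_score(x, m), logit_score(y, m))),
               tolerance = 1e-9)

  # feature order is enforced, never silently fixed
  shuffled <- tibble::as_tibble(as.list(x))[, c(2:9, 1)]
  expect_error(logit_score(shuffled, m), "order")
})

test_that("classification follows the healthy-high orientation with MDD ties", {
  expect_equal(classify(605.15), "healthy")
  expect_equal(classify(-300.898), "MDD")
  expect_equal(classify(0), "MDD")                  # tie -> positive class
  expect_equal(classify(c(-1, 1), threshold = 0), c("MDD", "healthy"))
  expect_equal(classify(5, threshold = 10), "MDD")
})

test_that("model JSON round-trips coefficients bit-exactly", {
  m <- reference_model()
  expect_identical(m$A[3, 3], -87.24)
  expect_identical(m$A[1, 1], 0.23)
  expect_identical(m$constant, 605.15)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(m2$A, m$A)
  expect_identical(m2$constant, m$constant)
  expect_identical(m2$feature_order, m$feature_order)
  broken <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"A\": [[1,2],[3,4]]", broken)
  expect_error(read_model_json(broken), "malformed|missing")
})

test_that("ridge logistic fit is stable, deterministic and matches glm", {
  coh <- make_separated_cohort(8, 12, seed = 71)
  fit <- fit_logistic(coh)
  expect_true(all(is.finite(tidy(fit)$estimate)))
  # separable data: ridge keeps coefficients finite, training is perfect
  train_pred <- classify(logit_score(coh, fit))
  expect_equal(train_pred, coh$label)

  # permuting rows leaves the fit unchanged
  set.seed(72)
  perm <- sample(nrow(coh))
  fit2 <- fit_logistic(coh[perm, ])
  expect_equal(tidy(fit2)$estimate, tidy(fit)$estimate, tolerance = 1e-6)

  # non-separable relabeled cohort: agreement with glm's unpenalized MLE
  coh2 <- make_featureonly_cohort(400, seed = 73)
  mu <- attr(coh2, "mu"); sdv <- attr(coh2, "sd")
  beta <- 1.5 * rep(c(1, -1), length.out = 9) / sdv
  truth <- logit_model(matrix(beta, 3, 3, byrow = TRUE),
                       constant = -sum(beta * mu))
  set.seed(74)
  coh2$label <- ifelse(runif(400) < plogis(logit_score(coh2, truth)),
                       "healthy", "MDD")
  fit3 <- fit_logistic(coh2)
  g <- stats::glm(I(label == "healthy") ~ ., family = stats::binomial,
                  data = cbind(coh2[canonical_features()],
                               label = coh2$label))
  expect_equal(unname(tidy(fit3)$estimate),
               unname(coef(g)[c("(Intercept)", canonical_features())]),
               tolerance = 1e-5)
  expect_true(glance(fit3)$converged)

  one_class <- coh[coh$label == "MDD", ]
  expect_error(fit_logistic(one_class), "both classes")
  bad <- coh
  bad$hf_before[1] <- NA_real_
  expect_error(fit_logistic(bad), "finite")
})

test_that("leave-one-out evaluation matches the double-loop oracle", {
  # trivially separable toy: 2 vs 2 on one feature
  ord <- canonical_features()
  toy <- tibble::as_tibble(setNames(as.list(rep(1, 9)), ord))[rep(1, 4), ]
  toy$hr_before <- c(60, 61, 100, 101)
  toy$label <- c("MDD", "MDD", "healthy", "healthy")
  toy$subject_id <- letters[1:4]
  res <- loocv_evaluate(toy)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$n, 4)
  expect_equal(sum(res$confusion), 4)

  for (sizes in list(c(4, 6), c(5, 7))) {
    coh <- make_separated_cohort(sizes[1], sizes[2], seed = sum(sizes))
    res <- loocv_evaluate(coh)
    oracle <- loocv_oracle(coh)
    expect_equal(tidy(res)$score, oracle$score, tolerance = 1e-12)
    expect_identical(tidy(res)$predicted, oracle$predicted)
    expect_equal(res$sensitivity, oracle$sensitivity)
    expect_equal(res$specificity, oracle$specificity)
    # exactly n folds, each subject predicted once
    expect_equal(nrow(tidy(res)), nrow(coh))
    expect_false(any(is.na(tidy(res)$score)))
  }
  expect_error(loocv_evaluate(make_separated_cohort(1, 9, seed = 3)),
               "at least 2")
})

test_that("score responds monotonically to each coefficient's sign", {
  m <- reference_model()
  x <- mdd_mean_vector()
  base <- logit_score(x, m)
  coefs <- pulsescreen:::model_coefficients(m)
  for (j in seq_along(coefs)) {
    up <- x
    up[j] <- up[j] + 1
    delta <- logit_score(up, m) - base
    if (coefs[j] > 0) expect_gt(delta, 0) else expect_lt(delta, 0)
  }
})
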