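#' Define the recording phases around the mental task
#'
#' The screening protocol records 320 s in three contiguous phases: rest
#' before the task, the mental task itself, and rest after. Boundaries are
#' configurable; the default is the 100/100/120-s protocol. Phases are
#' half-open `[b_j, b_{j+1})` except the last, which is closed at the end of
#' the recording.
#'
#' @param boundaries Numeric vector of 4 increasing phase boundaries in
#'   seconds (default `c(0, 100, 200, 320)`).
#' @return An object of class `phase_definition`.
#' @export
phase_definition <- function(boundaries = c(0, 100, 200, 320)) {
  if (length(boundaries) != 4L || any(diff(boundaries) <= 0)) {
    abort("`boundaries` must be 4 strictly increasing times (s)")
  }
  structure(list(boundaries = as.numeric(boundaries),
                 phases = c("before", "during", "after")),
            class = "phase_definition")
}

phase_of <- function(times, phases) {
  b <- phases$boundaries
  idx <- findInterval(times, b, rightmost.closed = TRUE)
  idx[idx < 1L | idx > 3L] <- NA_integer_
  phases$phases[idx]
}

#' Phase-averaged screening features from an HRV series
#'
#' Averages HR, HF and LF/HF over the spectral windows whose *center* falls
#' in each phase (each window is attributed to exactly one phase), yielding
#' the nine screening variables in canonical order.
#'
#' @param hrv An `hrv_series` tibble from [sliding_hrv()].
#' @param phases A [phase_definition()].
#' @return A one-row tibble with the nine canonical feature columns.
#' @export
phase_features <- function(hrv, phases = phase_definition()) {
  if (!is.data.frame(hrv) ||
      !all(c("window_center_s", "hr_bpm", "hf_ms2", "lfhf") %in% names(hrv))) {
    abort("`hrv` must be an hrv_series tibble")
  }
  ph <- phase_of(hrv$window_center_s, phases)
  for (p in phases$phases) {
    if (!any(ph %in% p)) {
      abort(sprintf("phase '%s' contains no spectral window centers", p))
    }
  }
  means <- function(v) vapply(phases$phases,
                              function(p) mean(v[ph %in% p]), numeric(1))
  hr <- unname(means(hrv$hr_bpm))
  hf <- unname(means(hrv$hf_ms2))
  lh <- unname(means(hrv$lfhf))
  out <- tibble(hr_before = hr[1], hr_during = hr[2], hr_after = hr[3],
                hf_before = hf[1], hf_during = hf[2], hf_after = hf[3],
                lfhf_before = lh[1], lfhf_during = lh[2], lfhf_after = lh[3])
  out
}

#' Construct a linear logit screening model
#'
#' The screening score is the exact linear form
#' `sum_ij A[i, j] * X[j, i] + constant`, where `i` indexes the measure
#' (1 HR, 2 HF, 3 LF/HF) and `j` the phase (1 before, 2 during, 3 after).
#' Higher scores indicate the healthy group (`orientation = "healthy_high"`).
#'
#' @param A 3x3 numeric coefficient matrix, rows = measures (HR, HF, LF/HF),
#'   columns = phases (before, during, after).
#' @param constant Scalar intercept.
#' @param feature_order Character vector naming the flat feature order the
#'   model expects (default canonical).
#' @param orientation Score orientation tag; only `"healthy_high"` is
#'   defined.
#' @return An object of class `logit_model`.
#' @export
logit_model <- function(A, constant,
                        feature_order = canonical_features(),
                        orientation = "healthy_high") {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3L, 3L)) || !all(is.finite(A))) {
    abort("`A` must be a finite 3x3 matrix")
  }
  stop_not_scalar_number(constant, "constant")
  if (!identical(orientation, "healthy_high")) {
    abort("unknown orientation tag")
  }
  if (length(feature_order) != 9L) abort("feature_order must have 9 names")
  dimnames(A) <- list(c("hr", "hf", "lfhf"), c("before", "during", "after"))
  structure(list(A = A, constant = constant,
                 feature_order = as.character(feature_order),
                 orientation = orientation),
            class = "logit_model")
}

# Flat coefficient vector in the model's feature order (measure-major).
model_coefficients <- function(model) {
  setNames(as.numeric(t(model$A)), model$feature_order)
}

#' The frozen published screening model
#'
#' The reference coefficient matrix and constant of the fingertip-pulse
#' screening score, exactly as published (trained on a clinical cohort of 6
#' depressed and 14 healthy participants). Loaded from the JSON fixture
#' shipped with the package; coefficients round-trip bit-exactly.
#'
#' @return A `logit_model`.
#' @export
reference_model <- function() {
  read_model_json(system.file("extdata", "reference_screening_model.json",
                              package = "pulsescreen", mustWork = TRUE))
}

features_matrix <- function(features, feature_order) {
  if (is.numeric(features) && !is.null(names(features))) {
    features <- as_tibble(as.list(features))
  }
  if (!is.data.frame(features)) {
    abort("`features` must be a data frame or named numeric vector")
  }
  cols <- names(features)[vapply(features, is.numeric, logical(1))]
  feat_cols <- cols[cols %in% feature_order]
  if (!identical(feat_cols, feature_order)) {
    abort(paste("feature columns do not match the model's feature order",
                "(names and order must agree exactly; no silent reordering)"))
  }
  as.matrix(features[, feature_order])
}

#' Logit screening score of feature vectors
#'
#' @param features One or more feature rows (tibble with the canonical nine
#'   columns, e.g. from [phase_features()] or a cohort table) or a named
#'   numeric vector. Column order must match the model's `feature_order`
#'   exactly.
#' @param model A [logit_model()] (default: the frozen [reference_model()]).
#' @return Numeric vector of scores, one per row.
#' @export
logit_score <- function(features, model = reference_model()) {
  if (!inherits(model, "logit_model")) abort("`model` must be a logit_model")
  X <- features_matrix(features, model$feature_order)
  if (any(!is.finite(X))) abort("features must be finite")
  drop(X %*% model_coefficients(model)) + model$constant
}

#' Classify a logit score into screening labels
#'
#' Scores above the threshold are labeled healthy (the published model's
#' orientation); scores at or below the threshold — ties included — are
#' labeled MDD, the positive screening class.
#'
#' @param score Numeric vector of logit scores.
#' @param threshold Decision threshold (default 0, probability one half).
#' @return Character vector of `"healthy"` / `"MDD"`.
#' @export
classify <- function(score, threshold = 0) {
  ifelse(score > threshold, "healthy", "MDD")
}

check_cohort <- function(data, require_both = TRUE) {
  ord <- canonical_feature_order()
  missing <- setdiff(c("label", ord), names(data))
  if (length(missing)) {
    abort(paste0("cohort is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(data$label %in% c("MDD", "healthy"))) {
    abort("labels must be 'MDD' or 'healthy'")
  }
  X <- as.matrix(data[, ord])
  if (any(!is.finite(X))) abort("cohort features must be finite")
  if (require_both && length(unique(data$label)) < 2L) {
    abort("both classes must be present")
  }
  invisible(data)
}

#' Fit the screening model by ridge-stabilised logistic regression
#'
#' Maximizes the binomial log-likelihood with a small ridge penalty
#' `lambda * sum(slope^2)` (intercept unpenalized) by Newton iterations with
#' step-halving. The default `lambda = 1e-8` only stabilizes the otherwise
#' divergent fit on separable cohorts. Labels are coded healthy = 1, so
#' fitted scores share the published model's healthy-high orientation.
#' The fit is deterministic given the data.
#'
#' @param data Cohort tibble with `label` and the nine canonical features.
#' @param lambda Ridge penalty on the slopes (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the penalized log-likelihood change.
#' @return A `logit_fit` (inherits `logit_model`) with convergence
#'   diagnostics; see [glance.logit_fit()].
#' @export
fit_logistic <- function(data, lambda = 1e-8, max_iter = 100, tol = 1e-8) {
  check_cohort(data)
  if (nrow(data) < 3L) abort("need at least 3 subjects to fit")
  ord <- canonical_feature_order()
  X <- cbind(`(constant)` = 1, as.matrix(data[, ord]))
  y <- as.numeric(data$label == "healthy")
  p_dim <- ncol(X)
  D <- diag(c(0, rep(1, p_dim - 1L)))      # intercept unpenalized
  beta <- numeric(p_dim)
  softplus <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - softplus(eta)) - lambda * sum(b[-1]^2)
  }
  ll <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(X, y - p)) - 2 * lambda * (D %*% beta)
    H <- crossprod(X, X * w) + 2 * lambda * D
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H + diag(1e-10, p_dim), grad))
    # step halving: never accept a move that lowers the penalized likelihood
    s <- 1
    repeat {
      cand <- beta + s * drop(step)
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    delta <- abs(ll_new - ll)
    beta <- cand
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  A <- matrix(beta[-1], nrow = 3, byrow = TRUE)
  out <- logit_model(A, constant = beta[1])
  out$converged <- converged
  out$iterations <- iter
  out$loglik <- ll + lambda * sum(beta[-1]^2)
  out$penalized_loglik <- ll
  out$lambda <- lambda
  out$n <- nrow(data)
  class(out) <- c("logit_fit", class(out))
  out
}

#' Leave-one-out cross-validated screening evaluation
#'
#' Each subject is held out once; the model is refit on the remaining
#' subjects and the held-out subject is scored and classified. Aggregates
#' the confusion matrix, sensitivity (MDD = positive class) and specificity.
#' A fold whose training set loses an entire class is flagged and skipped
#' with a warning.
#'
#' @param data Cohort tibble (n >= 4, both classes with >= 2 subjects).
#' @param threshold Classification threshold on the logit score.
#' @inheritParams fit_logistic
#' @return An object of class `screening_result` with per-subject scores,
#'   the confusion matrix, sensitivity and specificity.
#' @export
loocv_evaluate <- function(data, threshold = 0, lambda = 1e-8,
                           max_iter = 100, tol = 1e-8) {
  check_cohort(data)
  n <- nrow(data)
  if (n < 4L) abort("need at least 4 subjects")
  if (any(table(data$label) < 2L)) {
    abort("both classes need at least 2 subjects for leave-one-out folds")
  }
  score <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(train$label)) < 2L) {
      warn(sprintf("fold %d lost an entire class; prediction skipped", i))
      flagged[i] <- TRUE
      next
    }
    fit <- fit_logistic(train, lambda = lambda, max_iter = max_iter,
                        tol = tol)
    score[i] <- logit_score(data[i, , drop = FALSE], fit)
  }
  predicted <- ifelse(flagged, NA_character_, classify(score, threshold))
  subjects <- tibble(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id
                 else sprintf("s%03d", seq_len(n)),
    label = data$label, score = score, predicted = predicted,
    flagged = flagged)
  new_screening_result(subjects, threshold)
}

new_screening_result <- function(subjects, threshold) {
  ok <- !is.na(subjects$predicted)
  tp <- sum(ok & subjects$label == "MDD" & subjects$predicted == "MDD")
  fn <- sum(ok & subjects$label == "MDD" & subjects$predicted == "healthy")
  tn <- sum(ok & subjects$label == "healthy" & subjects$predicted == "healthy")
  fp <- sum(ok & subjects$label == "healthy" & subjects$predicted == "MDD")
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c("MDD", "healthy"),
                                      predicted = c("MDD", "healthy")))
  structure(list(subjects = subjects, confusion = confusion,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold, n = nrow(subjects)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening result (n = %d, threshold = %g)\n", x$n,
              x$threshold))
  print(x$confusion)
  cat(sprintf("sensitivity = %.3f, specificity = %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.logit_model <- function(x, ...) {
  cat("Logit screening model (rows: HR, HF, LF/HF; cols: before/during/after)\n")
  print(x$A)
  cat(sprintf("constant = %g; orientation = %s\n", x$constant, x$orientation))
  invisible(x)
}

#' Tidy a logit screening model
#'
#' @param x A `logit_model` or `logit_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (constant first, then the
#'   nine coefficients in canonical feature order).
#' @method tidy logit_model
#' @export
tidy.logit_model <- function(x, ...) {
  tibble(term = c("(constant)", x$feature_order),
         estimate = c(x$constant, unname(model_coefficients(x))))
}

#' One-row fit summary of a trained screening model
#'
#' @param x A `logit_fit` from [fit_logistic()].
#' @param ... Unused.
#' @return A one-row tibble with log-likelihood, penalty, iteration count,
#'   convergence flag and sample size.
#' @method glance logit_fit
#' @export
glance.logit_fit <- function(x, ...) {
  tibble(loglik = x$loglik, lambda = x$lambda, iterations = x$iterations,
         converged = x$converged, n = x$n)
}

#' Per-subject table of a screening evaluation
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return Tibble with subject id, true label, logit score, predicted label
#'   and fold flag.
#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) x$subjects

#' One-row summary of a screening evaluation
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return Tibble with sensitivity, specificity, accuracy, threshold, n.
#' @method glance screening_result
#' @export
glance.screening_result <- function(x, ...) {
  ok <- !is.na(x$subjects$predicted)
  tibble(sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = mean(x$subjects$predicted[ok] == x$subjects$label[ok]),
         threshold = x$threshold, n = x$n)
}
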