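#' Default diagnostic feature set
#'
#' The declarative list of EEG features entering the logistic diagnostic
#' model by default: the eyes-open frontal/central beta2 and occipital beta3
#' powers, the eyes-closed beta2/alpha/beta3 regional powers, and the
#' right-left temporal asymmetries that separate the groups.
#'
#' @return Tibble with columns `eye_state`, `feature_type`, `region`, `band`.
#' @export
default_model_features <- function() {
  tibble::tribble(
    ~eye_state, ~feature_type, ~region, ~band,
    "EO", "power", "PFC", "beta2",
    "EO", "power", "RMFC", "beta2",
    "EO", "power", "LMFC", "beta2",
    "EO", "power", "CC", "beta2",
    "EO", "power", "MOC", "beta3",
    "EO", "asymmetry", "RT-LT", "alpha",
    "EO", "asymmetry", "RT-LT", "beta1",
    "EO", "asymmetry", "RT-LT", "beta2",
    "EO", "asymmetry", "RT-LT", "beta3",
    "EC", "power", "PFC", "beta3",
    "EC", "power", "RMFC", "beta2",
    "EC", "power", "RT", "alpha",
    "EC", "power", "RT", "beta3",
    "EC", "power", "MOC", "beta3",
    "EC", "power", "RMOC", "beta3",
    "EC", "power", "LMOC", "beta3",
    "EC", "asymmetry", "RT-LT", "theta",
    "EC", "asymmetry", "RT-LT", "alpha"
  )
}

#' Build the model design matrix from a cohort feature table
#'
#' Pivots the tidy feature table to one row per subject and one column per
#' selected feature (named `state.type.region.band`), aligned with the
#' metadata table.
#'
#' @param features Cohort feature tibble.
#' @param meta Metadata tibble (`subject_id`, `group`).
#' @param select Feature selection tibble, see [default_model_features()].
#' @return List with `x` (matrix), `y` (1 = MDD, 0 = HC), `subject_id`.
#' @export
feature_matrix <- function(features, meta, select = default_model_features()) {
  sel <- dplyr::inner_join(features, select,
    by = c("eye_state", "feature_type", "region", "band")
  )
  sel$feature <- paste(sel$eye_state, sel$feature_type, sel$region, sel$band,
    sep = "."
  )
  wide <- tidyr::pivot_wider(
    sel[, c("subject_id", "feature", "value")],
    names_from = "feature", values_from = "value"
  )
  wide <- dplyr::inner_join(meta[, c("subject_id", "group")], wide,
    by = "subject_id"
  )
  x <- as.matrix(wide[, -(1:2)])
  rownames(x) <- wide$subject_id
  list(x = x, y = as.integer(wide$group == "MDD"), subject_id = wide$subject_id)
}

# Ridge-stabilized IRLS used when the unpenalized fit separates.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- solve(XtW %*% X + pen, XtW %*% z)
    ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(t(X * w) %*% X + pen)
  list(coef = drop(beta), se = sqrt(diag(cov)))
}

#' Fit an unpenalized binary logistic regression
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) on raw, unstandardized
#' features plus an intercept; standard errors from the inverse observed
#' information and two-sided Wald p-values. If the fit shows complete or
#' quasi-separation (non-convergence or diverging coefficients), the model is
#' refit with a small ridge penalty (`lambda = 1e-4`) and flagged.
#'
#' @param x Numeric feature matrix (subjects x features), no constant column.
#' @param y Binary outcome (1 = positive class).
#' @return List with `coefficients` (tibble: `term`, `B`, `SE`, `p`),
#'   `separable` flag, `converged`, and the fitted probabilities.
#' @export
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (nrow(x) <= ncol(x) + 1) stop("need n > p + 1 observations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) {
    drop_idx <- qx$pivot[seq(qx$rank + 1, ncol(x) + 1)] - 1
    stop("singular design; collinear column(s): ",
      paste(colnames(x)[drop_idx], collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm(y ~ x,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  separable <- !fit$converged || max(abs(stats::coef(fit)), na.rm = TRUE) > 50 ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separable) {
    rf <- ridge_logistic(x, y)
    B <- rf$coef
    SE <- rf$se
    fitted <- stats::plogis(drop(cbind(1, x) %*% B))
    converged <- TRUE
  } else {
    sm <- summary(fit)
    B <- stats::coef(fit)
    SE <- sm$coefficients[, "Std. Error"]
    fitted <- fit$fitted.values
    converged <- fit$converged
  }
  zval <- B / SE
  terms <- c("(Intercept)", colnames(x))
  list(
    coefficients = tibble::tibble(
      term = terms, B = unname(B), SE = unname(SE),
      p = unname(2 * stats::pnorm(-abs(zval)))
    ),
    separable = separable, converged = converged, fitted = fitted
  )
}

#' ROC curve of a score against binary labels
#'
#' Thresholds are the unique score values plus an `Inf` sentinel; a case is
#' predicted positive when its score is greater than or equal to the
#' threshold. AUC is the trapezoidal integral of the (1 - specificity,
#' sensitivity) curve, identical to the Mann-Whitney U statistic divided by
#' the number of positive-negative pairs.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (1 = positive).
#' @return Object of class `roc_result`: `thresholds` (descending),
#'   `sensitivity`, `specificity`, `auc`, `youden_cutoff`, `youden_sens`,
#'   `youden_spec`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  out <- structure(
    list(
      thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "roc_result"
  )
  yj <- youden_cutoff(out)
  out$youden_cutoff <- yj$threshold
  out$youden_sens <- yj$sens
  out$youden_spec <- yj$spec
  out
}

#' Youden-index optimal cut-off
#'
#' The threshold maximizing J = sensitivity + specificity - 1. Ties are
#' broken by the lowest threshold, favouring sensitivity. The `Inf` sentinel
#' is never returned as a cut-off when a finite threshold ties with it.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return List with `threshold`, `sens`, `spec`, `j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(roc$thresholds[best])]
  list(
    threshold = roc$thresholds[pick], sens = roc$sensitivity[pick],
    spec = roc$specificity[pick], j = j[pick]
  )
}

#' Percentile bootstrap confidence interval for an AUC
#'
#' Resamples subjects with replacement within each class (so every bootstrap
#' sample keeps both classes) and returns the 2.5/97.5 percentiles of the
#' bootstrap AUC distribution.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive), at least 5 per class.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
auc_confidence_interval <- function(scores, labels, n_boot = 2000, seed = 1) {
  labels <- as.numeric(labels)
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == 0)
  if (length(idx_pos) < 5 || length(idx_neg) < 5) {
    stop("bootstrap CI requires at least 5 subjects per class")
  }
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(seed))
  aucs <- vapply(seq_len(n_boot), function(b) {
    ip <- sample(idx_pos, replace = TRUE)
    ineg <- sample(idx_neg, replace = TRUE)
    fast_auc(c(scores[ip], scores[ineg]), c(rep(1, length(ip)), rep(0, length(ineg))))
  }, numeric(1))
  unname(stats::quantile(aucs, c(0.025, 0.975), type = 7))
}

# Rank-based AUC (Mann-Whitney), used in bootstrap loops where building the
# full curve would be wasteful. Identical to roc_curve()$auc.
fast_auc <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validated diagnostic performance
#'
#' Stratified k-fold split with a fixed seed; per fold the logistic model is
#' fit on the training subjects, the held-out subjects are scored, the fold
#' AUC is the trapezoidal ROC integral, and fold sensitivity/specificity are
#' evaluated on the held-out subjects at the Youden cut-off derived from the
#' training scores (test-derived cut-offs would leak). Sensitivity and
#' specificity at the fixed 0.5 probability cut-off are reported alongside.
#'
#' @param x Feature matrix (subjects x features).
#' @param y Binary labels (1 = positive); each class count must be >= k.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with `mean_auc`, `mean_sens`, `mean_spec`, `mean_sens_05`,
#'   `mean_spec_05`, `folds` (per-fold tibble), `oof_scores` (out-of-fold
#'   score per subject), `seed`.
#' @export
cross_validated_performance <- function(x, y, k = 10, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (min(table(y)) < k) stop("each class must have at least k subjects")
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  oof <- numeric(n)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop("stratification violated: a fold contains a single class")
    }
    fit <- fit_logistic(x[tr, , drop = FALSE], y[tr])
    cut <- youden_cutoff(roc_curve(fit$fitted, y[tr]))$threshold
    sc <- stats::plogis(drop(cbind(1, x[te, , drop = FALSE]) %*%
      fit$coefficients$B))
    oof[te] <<- sc
    tibble::tibble(
      fold = f,
      auc = fast_auc(sc, y[te]),
      sens = sum(sc >= cut & y[te] == 1) / sum(y[te] == 1),
      spec = sum(sc < cut & y[te] == 0) / sum(y[te] == 0),
      sens_05 = sum(sc >= 0.5 & y[te] == 1) / sum(y[te] == 1),
      spec_05 = sum(sc < 0.5 & y[te] == 0) / sum(y[te] == 0)
    )
  })
  folds <- dplyr::bind_rows(rows)
  list(
    mean_auc = mean(folds$auc), mean_sens = mean(folds$sens),
    mean_spec = mean(folds$spec), mean_sens_05 = mean(folds$sens_05),
    mean_spec_05 = mean(folds$spec_05), folds = folds, oof_scores = oof,
    seed = as.integer(seed)
  )
}

#' Fit and evaluate the full diagnostic model
#'
#' Combines the full-cohort logistic fit (coefficient table), stratified
#' k-fold cross-validated performance, a percentile-bootstrap 95% CI for the
#' AUC of the pooled out-of-fold scores, and the pooled ROC with its Youden
#' cut-off.
#'
#' @param features Cohort feature tibble.
#' @param meta Metadata tibble.
#' @param select Feature selection ([default_model_features()]).
#' @param k Folds for cross-validation.
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param seed Integer seed (CV split and bootstrap).
#' @return List (`model_report`): `coefficients`, `cv_mean_auc`,
#'   `cv_sensitivity`, `cv_specificity`, `auc_ci_95`, `roc`, `separable`,
#'   `features` (the selection), `seed`.
#' @export
fit_diagnostic_model <- function(features, meta, select = default_model_features(),
                                 k = 10, n_boot = 1000, seed = 1) {
  fm <- feature_matrix(features, meta, select)
  full <- fit_logistic(fm$x, fm$y)
  cv <- cross_validated_performance(fm$x, fm$y, k = k, seed = seed)
  roc <- roc_curve(cv$oof_scores, fm$y)
  ci <- if (n_boot >= 1) {
    auc_confidence_interval(cv$oof_scores, fm$y, n_boot = n_boot, seed = seed)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      coefficients = full$coefficients, separable = full$separable,
      cv_mean_auc = cv$mean_auc, cv_sensitivity = cv$mean_sens,
      cv_specificity = cv$mean_spec,
      cv_sensitivity_05 = cv$mean_sens_05, cv_specificity_05 = cv$mean_spec_05,
      auc_ci_95 = ci, roc = roc, folds = cv$folds,
      features = select, seed = as.integer(seed)
    ),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %d features | CV AUC %.4f (95%% CI %.4f-%.4f) | sens %.3f spec %.3f (Youden)\n",
    nrow(x$features), x$cv_mean_auc, x$auc_ci_95[1], x$auc_ci_95[2],
    x$cv_sensitivity, x$cv_specificity
  ))
  invisible(x)
}
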