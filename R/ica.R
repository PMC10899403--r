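# Compact FastICA (symmetric orthogonalization, logcosh contrast) with
# deterministic seeding. Used only for ocular artifact removal; the rotation
# is unidentifiable on near-Gaussian data, in which case the detector below
# simply finds nothing to remove.

fast_ica <- function(X, n_comp = ncol(X), seed = 1, max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # PCA whitening
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- eg$values[keep]
  d[d < 1e-12] <- 1e-12
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(d), n_comp) # whitener
  Z <- Xc %*% K # n x k, identity covariance
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp, n_comp)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  failed <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W) # n x k source estimates
    G <- tanh(WX)
    gprime <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - diag(gprime, n_comp) %*% W
    if (!all(is.finite(W1))) {
      failed <- TRUE
      break
    }
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  S <- Z %*% t(W) # n x k sources
  # Xc = S %*% t(A): exact inverse of the whiten + rotate transform
  A <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d), n_comp) %*% t(W)
  unmix <- K %*% t(W) # channels x k: S = Xc %*% unmix
  list(
    S = S, A = A, unmix = unmix, mean = mu,
    converged = converged, failed = failed, n_iter = it
  )
}

#' Remove ocular artifacts by ICA
#'
#' Decomposes the recording with FastICA (deterministic for a fixed seed) and
#' zeroes components identified as ocular by a dual criterion: the component
#' time course correlates (|r| > `cor_threshold`) with the mean of the
#' frontopolar channels Fp1/Fp2, or the component's mixing weights are
#' frontopolar-dominated (both |weight(Fp1)| and |weight(Fp2)| exceed
#' `frontal_ratio` times the median absolute weight).
#'
#' On near-Gaussian background activity the symmetric FastICA rotation has no
#' unique optimum, so the iteration cap may be reached without formal
#' convergence; the final iterate is still a valid orthogonal unmixing and is
#' used, with `converged = FALSE` recorded in the report. Only a numerical
#' failure (non-finite update) triggers a pass-through, with a logged
#' warning, never silently.
#'
#' @param rec An [eeg_recording()] containing Fp1 and Fp2; at least 30 s long.
#' @param seed Integer seed for the ICA initialization.
#' @param cor_threshold,frontal_ratio Detection thresholds (see above).
#' @return A list with `recording` (cleaned) and `report` (removed component
#'   indices, per-component criteria values, convergence flag).
#' @export
remove_ocular_ica <- function(rec, seed = 1, cor_threshold = 0.7, frontal_ratio = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$channels) < 2) stop("ICA requires at least 2 channels")
  if (recording_duration(rec) < 30) {
    stop("recording must be at least 30 s for a stable ICA decomposition")
  }
  fp <- match(c("Fp1", "Fp2"), rec$channels)
  if (anyNA(fp)) stop("ocular removal requires Fp1 and Fp2 in the montage")
  fit <- fast_ica(rec$samples, seed = seed)
  if (fit$failed) {
    warning("ICA failed numerically; recording passed through unchanged")
    rec <- add_provenance(rec, "remove_ocular_ica", list(
      seed = seed, converged = FALSE, failed = TRUE, removed = integer()
    ))
    return(list(recording = rec, report = list(
      removed = integer(), converged = FALSE, failed = TRUE,
      cor_eog = numeric(), frontal_dominance = numeric()
    )))
  }
  eog_ref <- rowMeans(rec$samples[, fp, drop = FALSE])
  k <- ncol(fit$S)
  cor_eog <- vapply(seq_len(k), function(i) {
    suppressWarnings(stats::cor(fit$S[, i], eog_ref))
  }, numeric(1))
  cor_eog[is.na(cor_eog)] <- 0
  dominance <- vapply(seq_len(k), function(i) {
    w <- abs(fit$A[, i])
    min(w[fp]) / max(stats::median(w), 1e-12)
  }, numeric(1))
  removed <- which(abs(cor_eog) > cor_threshold | dominance > frontal_ratio)
  if (length(removed)) {
    S2 <- fit$S
    S2[, removed] <- 0
    rec$samples <- sweep(S2 %*% t(fit$A), 2, fit$mean, `+`)
    colnames(rec$samples) <- rec$channels
  }
  rec <- add_provenance(rec, "remove_ocular_ica", list(
    seed = seed, converged = fit$converged, removed = removed,
    cor_threshold = cor_threshold, frontal_ratio = frontal_ratio
  ))
  list(recording = rec, report = list(
    removed = removed, converged = fit$converged, failed = FALSE,
    cor_eog = cor_eog, frontal_dominance = dominance, n_iter = fit$n_iter
  ))
}
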