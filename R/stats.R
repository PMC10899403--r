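#' Two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] exposing the Welch (default) and
#' pooled-variance variants with a documented degenerate-case convention:
#' when both samples have zero variance and equal means, `t = 0, p = 1`.
#'
#' @param x,y Numeric samples (each n >= 2, finite).
#' @param variant `"welch"` or `"pooled"`.
#' @return List with `t`, `p`, `df`, `variant`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2, variant = variant))
    }
    stop("both samples constant with different means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(
    t = unname(ht$statistic), p = ht$p.value,
    df = unname(ht$parameter), variant = variant
  )
}

#' Cohen's d from raw samples
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' (n-1)-weighted pooled standard deviation.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  d_from_summaries(
    mean(x), stats::sd(x), length(x),
    mean(y), stats::sd(y), length(y)
  )
}

#' Cohen's d from printed summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of the first sample.
#' @param m2,s2,n2 Mean, SD and size of the second sample.
#' @return Scalar d = (m1 - m2) / s_pooled.
#' @export
d_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero: d undefined")
  (m1 - m2) / sqrt(sp2)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @return List with `chisq`, `p`, `df`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(abs(counts - round(counts)) < 1e-9))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: a table margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]), order-preserving with
#' the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Pearson correlation requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance: r undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Group contrast table for a cohort feature set
#'
#' One row per (eye state, feature): group means and SDs, the two-sample t
#' statistic, the raw two-sided p, the FDR-adjusted p and Cohen's d under the
#' control-minus-patient sign convention (`d > 0` when the control mean is
#' larger). FDR families are formed per eye state separately for the 60
#' power features and the 15 asymmetry features.
#'
#' @param features Feature tibble as returned by [subject_features()] rows
#'   bound over subjects.
#' @param meta Metadata tibble with `subject_id` and `group`.
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @return Tibble with columns `eye_state`, `feature_type`, `region`, `band`,
#'   `mean_hc`, `sd_hc`, `n_hc`, `mean_mdd`, `sd_mdd`, `n_mdd`, `t`, `p_raw`,
#'   `p_fdr`, `cohen_d`.
#' @export
group_contrast_table <- function(features, meta, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  df <- dplyr::inner_join(features, meta[, c("subject_id", "group")],
    by = "subject_id"
  )
  if (length(unique(df$group)) < 2) stop("both groups must be present")
  grp_n <- table(meta$group)
  rows <- df |>
    dplyr::group_by(.data$eye_state, .data$feature_type, .data$region, .data$band) |>
    dplyr::group_map(function(d, key) {
      hc <- d$value[d$group == "HC"]
      mdd <- d$value[d$group == "MDD"]
      if (length(hc) < 0.5 * grp_n[["HC"]] || length(mdd) < 0.5 * grp_n[["MDD"]]) {
        warning(sprintf(
          "feature %s/%s/%s/%s missing for more than half of a group; row skipped",
          key$eye_state, key$feature_type, key$region, key$band
        ))
        return(NULL)
      }
      tt <- two_sample_t(hc, mdd, variant)
      cbind(key, tibble::tibble(
        mean_hc = mean(hc), sd_hc = stats::sd(hc), n_hc = length(hc),
        mean_mdd = mean(mdd), sd_mdd = stats::sd(mdd), n_mdd = length(mdd),
        t = tt$t, p_raw = tt$p, cohen_d = cohens_d(hc, mdd)
      ))
    }) |>
    dplyr::bind_rows() |>
    tibble::as_tibble()
  rows |>
    dplyr::group_by(.data$eye_state, .data$feature_type) |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p_raw)) |>
    dplyr::ungroup() |>
    dplyr::relocate("p_fdr", .after = "p_raw")
}

#' Correlate EEG features with a clinical severity score
#'
#' Pearson correlation of each feature with a clinical scale, within one
#' group (by default the patient group, whose severity scores are defined).
#'
#' @param features Cohort feature tibble.
#' @param meta Metadata tibble with `subject_id`, `group` and the scale column.
#' @param scale Clinical scale column name (`"hdrs17"` or `"hama"`).
#' @param group Group whose subjects enter the correlation.
#' @return Tibble with `eye_state`, `feature_type`, `region`, `band`, `r`,
#'   `p`, `n`.
#' @export
correlate_clinical <- function(features, meta, scale = "hdrs17", group = "MDD") {
  stopifnot(scale %in% names(meta))
  sub <- meta[meta$group == group & is.finite(meta[[scale]]), ]
  df <- dplyr::inner_join(features, sub[, c("subject_id", scale)],
    by = "subject_id"
  )
  df |>
    dplyr::group_by(.data$eye_state, .data$feature_type, .data$region, .data$band) |>
    dplyr::group_map(function(d, key) {
      ct <- pearson_r(d$value, d[[scale]])
      cbind(key, tibble::tibble(r = ct$r, p = ct$p, n = ct$n))
    }) |>
    dplyr::bind_rows() |>
    tibble::as_tibble()
}
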