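#' Completeness filter for label-free intensities
#'
#' Retains a feature only if it is quantified in strictly more than
#' `min_fraction` of the samples. With the default 0.5 on a 35-sample
#' cohort the smallest passing count is 18, i.e. the usual "> 50% data
#' completeness" rule for LFQ proteomics.
#'
#' @param m a [feature_matrix()].
#' @param min_fraction completeness threshold in (0, 1); comparison is
#'   strict (`>`).
#' @return The filtered `feature_matrix`, feature order preserved.
#' @export
filter_completeness <- function(m, min_fraction = 0.5) {
  stopifnot(inherits(m, "feature_matrix"))
  if (nrow(m$values) == 0 || ncol(m$values) == 0) {
    stop("cannot filter an empty matrix", call. = FALSE)
  }
  stopifnot(min_fraction > 0, min_fraction < 1)
  frac <- rowMeans(!is.na(m$values))
  m$values <- m$values[frac > min_fraction, , drop = FALSE]
  m
}

#' Minimum retained count under the completeness rule
#'
#' Convenience: the smallest number of non-missing samples (out of
#' `n_samples`) that survives [filter_completeness()] at `min_fraction`.
#'
#' @param n_samples cohort size.
#' @param min_fraction completeness threshold (strict `>`).
#' @return Integer count.
#' @examples
#' min_complete_count(35, 0.5) # 18
#' @export
min_complete_count <- function(n_samples, min_fraction = 0.5) {
  as.integer(floor(n_samples * min_fraction) + 1L)
}

#' Quality-status filter for targeted metabolomics
#'
#' Retains a metabolite only if at least `min_valid_fraction` of its cells
#' carry the status `valid` (concentration within the calibrated range).
#' The default 2/3 is inclusive: 6 valid cells out of 9 pass.
#'
#' @param m a metabolite [feature_matrix()].
#' @param q the congruent [quality_matrix()].
#' @param min_valid_fraction inclusive threshold in (0, 1].
#' @return The filtered `feature_matrix`.
#' @export
filter_metabolite_validity <- function(m, q, min_valid_fraction = 2 / 3) {
  stopifnot(inherits(m, "feature_matrix"), inherits(q, "quality_matrix"))
  if (!identical(dim(m$values), dim(q$statuses)) ||
      !identical(rownames(m$values), rownames(q$statuses)) ||
      !identical(colnames(m$values), colnames(q$statuses))) {
    stop("feature matrix and quality matrix are not congruent", call. = FALSE)
  }
  frac_valid <- rowMeans(q$statuses == "valid")
  m$values <- m$values[frac_valid >= min_valid_fraction, , drop = FALSE]
  m
}

#' Flag low-quality samples
#'
#' Operationalises the usual visual QC criterion — samples with an unusual
#' number of missing values and/or shifted median intensity — as robust
#' z-rules: a sample is flagged when its missing fraction exceeds the
#' cohort median by more than `k` MADs, or when its median intensity
#' deviates from the cohort median-of-medians by more than `k` MADs (MAD
#' scaled by 1.4826 for normal consistency).
#'
#' @param m a [feature_matrix()] with at least 4 samples.
#' @param k robust-z multiplier (default 3).
#' @return A tibble of class `qc_report` with one row per sample:
#'   `sample_id`, `missing_fraction`, `median_intensity`, `flagged`,
#'   `flag_reason`.
#' @export
qc_flag_samples <- function(m, k = 3) {
  stopifnot(inherits(m, "feature_matrix"))
  if (ncol(m$values) < 4) {
    stop("sample QC needs at least 4 samples for robust statistics",
         call. = FALSE)
  }
  miss <- colMeans(is.na(m$values))
  med <- apply(m$values, 2, stats::median, na.rm = TRUE)
  miss_cut <- stats::median(miss) + k * stats::mad(miss)
  med_centre <- stats::median(med)
  med_cut <- k * stats::mad(med)
  high_missing <- miss > miss_cut
  shifted_median <- abs(med - med_centre) > med_cut
  reason <- dplyr::case_when(
    high_missing & shifted_median ~ "high_missingness; median_intensity_shift",
    high_missing ~ "high_missingness",
    shifted_median ~ "median_intensity_shift",
    .default = ""
  )
  out <- tibble::tibble(
    sample_id = colnames(m$values),
    missing_fraction = unname(miss),
    median_intensity = unname(med),
    flagged = unname(high_missing | shifted_median),
    flag_reason = unname(reason)
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Coefficient of variation, in percent
#'
#' Population (1/N) standard deviation over the mean, times 100:
#' \deqn{CV = \sqrt{\tfrac{1}{N}\sum_i (x_i - \mu)^2} \cdot 100 / \mu.}
#' Missing entries are dropped before N is counted.
#'
#' @param x numeric vector; needs at least 2 non-missing values and a
#'   non-zero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(1, 2, 3)) # 40.82483
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("CV needs at least 2 non-missing values", call. = FALSE)
  mu <- mean(x)
  if (mu == 0) stop("CV undefined for zero mean", call. = FALSE)
  sqrt(mean((x - mu)^2)) * 100 / mu
}
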