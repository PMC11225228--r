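#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-feature model fits
#'
#' @param x a `feature_fit` from [fit_feature_models()].
#' @param ... ignored.
#' @return Tibble with one row per (feature, coefficient): `feature_id`,
#'   `term`, `estimate`, plus per-feature `sigma2` and `df.residual`.
#' @export
tidy.feature_fit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "term",
                        values_to = "estimate") |>
    dplyr::left_join(
      tibble::tibble(
        feature_id = rownames(x$coefficients),
        sigma2 = x$sigma2, df.residual = x$df_residual
      ),
      by = "feature_id"
    )
}

#' @rdname tidy.feature_fit
#' @export
glance.feature_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$coefficients),
    n_samples = x$n_samples,
    n_coefficients = length(x$design_colnames),
    n_estimable = sum(!is.na(x$pattern_id)),
    n_zero_df = sum(!is.na(x$pattern_id) & x$df_residual == 0)
  )
}

#' Tidy moderation hyperparameters
#'
#' @param x a `moderation_params` from [estimate_moderation()].
#' @param ... ignored.
#' @return One-row tibble: `d0`, `s0_sq`, `n_used`.
#' @export
tidy.moderation_params <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_used = x$n_used)
}

#' Summarise a differential result
#'
#' @param x a `diff_result` from [moderated_t()].
#' @param alpha significance threshold (defaults to the one recorded on
#'   the result).
#' @param ... ignored.
#' @return One-row tibble: feature counts, significant counts before and
#'   after adjustment, and the moderation prior used.
#' @export
glance.diff_result <- function(x, alpha = attr(x, "alpha") %||% 0.05, ...) {
  mod <- attr(x, "moderation")
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(x$ok),
    n_signif_raw = sum(x$p.value < alpha, na.rm = TRUE),
    n_signif_adj = sum(x$adj.p.value < alpha, na.rm = TRUE),
    alpha = alpha,
    d0 = mod$d0 %||% NA_real_,
    s0_sq = mod$s0_sq %||% NA_real_
  )
}

#' Tidy an overlap summary
#'
#' @param x an `overlap_summary` from [overlap_sets()].
#' @param ... ignored.
#' @return Tibble of intersection patterns with counts plus the
#'   percent-largest statistic.
#' @export
tidy.overlap_summary <- function(x, ...) {
  dplyr::mutate(x$counts, n_union = x$n_union,
                percent_largest = x$percent_largest)
}
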