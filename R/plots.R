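#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sample QC plot
#'
#' Missing-value fraction against median intensity, flagged samples
#' highlighted.
#'
#' @param object a `qc_report` from [qc_flag_samples()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$median_intensity, y = .data$missing_fraction,
    colour = .data$flagged
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "median intensity", y = "missing-value fraction",
                  colour = "flagged", title = "Sample quality control") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result
#'
#' @param object a `diff_result` from [moderated_t()].
#' @param alpha significance threshold on adjusted p-values.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.diff_result <- function(object, alpha = attr(object, "alpha") %||% 0.05,
                                 ...) {
  df <- dplyr::filter(object, .data$ok) |>
    dplyr::mutate(signif = !is.na(.data$adj.p.value) & .data$adj.p.value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$logFC, y = -log10(.data$p.value), colour = .data$signif
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("adj. p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Heatmap of normalised enrichment scores
#'
#' @param object an `enrichment_result` with a `patient_id` column.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  if (!"patient_id" %in% names(object)) object$patient_id <- "all"
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$patient_id, y = .data$set_name, fill = .data$norm
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalised\nscore") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-enzyme imbalance scores
#'
#' @param object an `imbalance_result` from [score_imbalance()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.imbalance_result <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$imbalance)) |>
    dplyr::arrange(.data$imbalance) |>
    dplyr::mutate(enzyme = factor(.data$enzyme, levels = .data$enzyme))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$imbalance, y = .data$enzyme, fill = .data$imbalance > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "imbalance (downstream - upstream)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of t-value concordance between two analyses
#'
#' @param res1,res2 `diff_result` tibbles for the same contrast under two
#'   methods.
#' @param labels axis labels.
#' @return A ggplot.
#' @export
plot_concordance <- function(res1, res2, labels = c("method 1", "method 2")) {
  merged <- dplyr::inner_join(
    dplyr::select(res1, "feature_id", t1 = "t"),
    dplyr::select(res2, "feature_id", t2 = "t"),
    by = "feature_id"
  ) |> tidyr::drop_na()
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$t1, y = .data$t2)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "firebrick") +
    ggplot2::labs(x = paste("t,", labels[1]), y = paste("t,", labels[2])) +
    ggplot2::theme_minimal()
}
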