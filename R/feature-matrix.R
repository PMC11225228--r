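#' Feature-by-sample abundance matrix
#'
#' The central container for quantitative omics data: a numeric matrix with
#' features (proteins, peptides or metabolites) in rows and samples in
#' columns. Missing measurements are carried explicitly as `NA` — never as
#' zero — so downstream models can distinguish "not detected" from "low".
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); `NA` marks a missing measurement.
#' @param feature_kind one of `"protein"`, `"peptide"`, `"metabolite"`.
#' @param is_log logical; `TRUE` once intensities have been log-transformed.
#'
#' @return An object of class `feature_matrix`.
#' @examples
#' m <- feature_matrix(matrix(2^(1:4), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("s1", "s2"))))
#' log_transform(m)
#' @export
feature_matrix <- function(values, feature_kind = c("protein", "peptide", "metabolite"),
                           is_log = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0)) {
    stop("`values` must have feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (nrow(values) > 0) check_unique_ids(rownames(values), "feature")
  if (ncol(values) > 0) check_unique_ids(colnames(values), "sample")
  if (is_log && any(!is.finite(values[!is.na(values)]))) {
    stop("log-scale matrix contains non-finite values", call. = FALSE)
  }
  structure(
    list(values = values, feature_kind = feature_kind, is_log = is_log),
    class = "feature_matrix"
  )
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) {
    stop(sprintf("%s ids must be non-empty", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s ids: %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d %ss x %d samples (%s scale, %.1f%% missing)\n",
    nrow(x$values), x$feature_kind, ncol(x$values),
    if (x$is_log) "log" else "raw", 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @rdname feature_matrix
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' @param x a `feature_matrix`.
#' @param ... ignored.
#' @describeIn feature_matrix long-format tibble with one row per
#'   (feature, sample) cell; missing cells keep an `NA` value.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value") |>
    dplyr::mutate(feature_kind = x$feature_kind, is_log = x$is_log)
}

#' Per-cell quality status matrix
#'
#' Companion to a metabolite [feature_matrix()]: one categorical status per
#' cell, as emitted by targeted-metabolomics quantification software
#' (concentration within the calibrated range, below/above its limits, or
#' not measured).
#'
#' @param statuses character matrix, same dimnames discipline as
#'   [feature_matrix()]; entries drawn from `valid`, `below_limit`,
#'   `above_limit`, `missing`.
#' @return An object of class `quality_matrix`.
#' @export
quality_matrix <- function(statuses) {
  if (!is.matrix(statuses) || !is.character(statuses)) {
    stop("`statuses` must be a character matrix", call. = FALSE)
  }
  if (is.null(rownames(statuses)) || is.null(colnames(statuses))) {
    stop("`statuses` must carry feature/sample ids as dimnames", call. = FALSE)
  }
  allowed <- c("valid", "below_limit", "above_limit", "missing")
  bad <- setdiff(unique(as.vector(statuses)), allowed)
  if (length(bad) > 0 || anyNA(statuses)) {
    stop("statuses must be one of ", paste(allowed, collapse = ", "),
         "; found: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_unique_ids(rownames(statuses), "feature")
  check_unique_ids(colnames(statuses), "sample")
  structure(list(statuses = statuses), class = "quality_matrix")
}

#' @export
dim.quality_matrix <- function(x) dim(x$statuses)

#' Sample annotation table
#'
#' Validates the per-sample metadata used throughout the workflow: subject
#' (the blocking unit for paired designs), tissue condition (e.g. `TT`
#' tumour vs `NAT` adjacent normal), extraction method, and matrix type.
#'
#' @param data data frame with columns `sample_id`, `subject_id`,
#'   `condition`, `method`, `matrix_type`.
#' @return A validated tibble (class `sample_annotation`).
#' @export
sample_annotation <- function(data) {
  need <- c("sample_id", "subject_id", "condition", "method", "matrix_type")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_unique_ids(as.character(data$sample_id), "sample")
  out <- tibble::as_tibble(data)[need]
  class(out) <- c("sample_annotation", class(out))
  out
}

# every sample column of m must have exactly one annotation row
check_annotation_covers <- function(m, ann) {
  miss <- setdiff(sample_ids(m), ann$sample_id)
  if (length(miss) > 0) {
    stop("samples without annotation: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-transform an intensity matrix
#'
#' Element-wise log of all non-missing entries. Raw label-free intensities
#' span orders of magnitude and are log2-transformed before linear
#' modelling; the missing-value mask is untouched.
#'
#' @param m a raw-scale [feature_matrix()] with all non-missing values > 0.
#' @param base logarithm base; default 2 so that model coefficients read as
#'   log2 fold changes.
#' @return The transformed `feature_matrix` with `is_log = TRUE`.
#' @export
log_transform <- function(m, base = 2) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$is_log) stop("matrix is already log-scaled", call. = FALSE)
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-positive value at feature '%s', sample '%s' cannot be log-transformed",
      rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]]
    ), call. = FALSE)
  }
  m$values <- log(m$values, base = base)
  m$is_log <- TRUE
  m
}
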