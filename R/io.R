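#' Read a feature-by-sample matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature ids. Empty cells and the token `NA` are read
#' as missing; anything else must parse as a number.
#'
#' @param path file path.
#' @param feature_kind `"protein"`, `"peptide"` or `"metabolite"`.
#' @return A [feature_matrix()] with `is_log = FALSE`.
#' @export
read_feature_matrix <- function(path, feature_kind = "protein") {
  parsed <- read_tsv_cells(path)
  vals <- suppressWarnings(array(as.numeric(parsed$cells), dim = dim(parsed$cells)))
  bad <- which(is.na(vals) & !parsed$missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric cell '%s' at feature '%s' (row %d), sample '%s'",
      parsed$cells[bad[1, 1], bad[1, 2]],
      parsed$feature_ids[bad[1, 1]], bad[1, 1] + 1L,
      parsed$sample_ids[bad[1, 2]]
    ), call. = FALSE)
  }
  dimnames(vals) <- list(parsed$feature_ids, parsed$sample_ids)
  feature_matrix(vals, feature_kind = feature_kind, is_log = FALSE)
}

# shared low-level TSV grid reader with ragged-row / duplicate-id errors
read_tsv_cells <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  sample_ids <- header[-1]
  check_unique_ids(sample_ids, "sample")
  n <- length(fields) - 1L
  widths <- lengths(fields[-1])
  # a line ending in a tab loses its trailing empty field in strsplit
  short_ok <- widths == ncol_expected - 1L & endsWith(lines[-1], "\t")
  ragged <- which(widths != ncol_expected & !short_ok)
  if (length(ragged) > 0) {
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 ragged[1] + 1L, widths[ragged[1]], ncol_expected), call. = FALSE)
  }
  cells <- matrix("", nrow = n, ncol = ncol_expected - 1L)
  feat <- character(n)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    length(row) <- ncol_expected
    row[is.na(row)] <- ""
    feat[i] <- row[1]
    cells[i, ] <- row[-1]
  }
  check_unique_ids(feat, "feature")
  list(
    feature_ids = feat, sample_ids = sample_ids, cells = cells,
    missing = cells == "" | cells == "NA"
  )
}

#' Write a feature matrix to TSV
#'
#' Inverse of [read_feature_matrix()]: missing cells are written as `NA` so
#' that a write/read round trip preserves values and mask exactly.
#'
#' @param m a [feature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  df <- tibble::as_tibble(m$values, rownames = "feature_id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read a per-cell quality status matrix from TSV
#'
#' Same layout as [read_feature_matrix()] but cells hold the categorical
#' quality statuses reported by targeted quantification software.
#'
#' @inheritParams read_feature_matrix
#' @return A [quality_matrix()].
#' @export
read_quality_matrix <- function(path) {
  parsed <- read_tsv_cells(path)
  cells <- parsed$cells
  cells[parsed$missing] <- "missing"
  dimnames(cells) <- list(parsed$feature_ids, parsed$sample_ids)
  quality_matrix(cells)
}

#' @rdname read_quality_matrix
#' @param q a [quality_matrix()].
#' @export
write_quality_matrix <- function(q, path) {
  stopifnot(inherits(q, "quality_matrix"))
  df <- tibble::as_tibble(q$statuses, rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `condition`,
#'   `method`, `matrix_type`.
#' @return A validated [sample_annotation()] tibble.
#' @export
read_sample_annotation <- function(path) {
  sample_annotation(readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  )))
}

#' Analysis configuration
#'
#' Bundles the workflow thresholds in one validated object. Defaults mirror
#' the filtering and testing rules used throughout the package: strict
#' \eqn{>} 50\% completeness for proteins, at least 2/3 valid cells for
#' metabolites, alpha = 0.05, robust-z multiplier 3 for sample QC, and 1000
#' permutations for enrichment nulls.
#'
#' @param completeness_fraction proteins must exceed this fraction of
#'   non-missing samples (strict).
#' @param metabolite_valid_fraction metabolites must reach this fraction of
#'   `valid` quality cells (inclusive).
#' @param alpha significance level for adjusted p-values.
#' @param n_permutations permutation count B for enrichment nulls.
#' @param seed integer random seed recorded in output manifests.
#' @param qc_k robust-z multiplier for sample QC flagging.
#' @param distance_penalty,max_depth,min_branch_length imbalance-scoring
#'   parameters, see [imbalance_config()].
#' @param paths named list of file paths, passed through untouched.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(completeness_fraction = 0.5,
                            metabolite_valid_fraction = 2 / 3,
                            alpha = 0.05,
                            n_permutations = 1000,
                            seed = 1L,
                            qc_k = 3,
                            distance_penalty = 8,
                            max_depth = 5L,
                            min_branch_length = 1L,
                            paths = list()) {
  stopifnot(
    completeness_fraction > 0, completeness_fraction < 1,
    metabolite_valid_fraction > 0, metabolite_valid_fraction < 1,
    alpha > 0, alpha < 1,
    n_permutations >= 100,
    qc_k > 0
  )
  structure(
    list(
      completeness_fraction = completeness_fraction,
      metabolite_valid_fraction = metabolite_valid_fraction,
      alpha = alpha,
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      qc_k = qc_k,
      imbalance = imbalance_config(distance_penalty, max_depth, min_branch_length),
      paths = paths
    ),
    class = "analysis_config"
  )
}

#' @rdname analysis_config
#' @param path YAML file whose top-level keys match the arguments of
#'   `analysis_config()`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(analysis_config)), "...")
  do.call(analysis_config, vals[intersect(names(vals), known)])
}

#' Write a JSON run manifest
#'
#' Records inputs, configuration and seed next to a result directory so a
#' run can be reproduced.
#'
#' @param path output JSON path.
#' @param config an [analysis_config()].
#' @param inputs named list/character of input descriptions.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = list()) {
  stopifnot(inherits(config, "analysis_config"))
  cfg <- config[setdiff(names(config), "paths")]
  cfg$imbalance <- unclass(cfg$imbalance)
  manifest <- list(
    package = "duomics",
    version = as.character(utils::packageVersion("duomics")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = cfg,
    inputs = inputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
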