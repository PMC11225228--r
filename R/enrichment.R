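#' Z-score per-patient fold changes across patients
#'
#' Standardises each feature's per-patient log2 fold changes across the
#' patient axis: `(value - mean) / sd` with the sample (n-1) standard
#' deviation. Features with zero variance become missing and are flagged
#' in `attr(, "constant_features")`.
#'
#' @param fc tibble with columns `feature_id`, `patient_id`, `log2fc`
#'   (extra columns such as `feature_type` are preserved).
#' @return Tibble of the same shape with `log2fc` replaced by `z`.
#' @export
zscore_across_patients <- function(fc) {
  stopifnot(all(c("feature_id", "patient_id", "log2fc") %in% names(fc)))
  n_pat <- dplyr::n_distinct(fc$patient_id)
  if (n_pat < 2) stop("z-scoring needs at least 2 patients", call. = FALSE)
  out <- tibble::as_tibble(fc) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(
      .mu = mean(.data$log2fc, na.rm = TRUE),
      .sd = stats::sd(.data$log2fc, na.rm = TRUE),
      z = dplyr::if_else(.data$.sd > 0, (.data$log2fc - .data$.mu) / .data$.sd,
                         NA_real_)
    ) |>
    dplyr::ungroup()
  constant <- unique(out$feature_id[!is.na(out$log2fc) & is.na(out$z)])
  out <- dplyr::select(out, -"log2fc", -".mu", -".sd")
  attr(out, "constant_features") <- constant
  out
}

#' Per-patient log2 fold changes from a paired cohort
#'
#' For each subject with both conditions measured, the per-feature
#' difference `TT - NAT` of log2 values (restricted to one method's
#' samples if `method` is given).
#'
#' @param m a log-scale [feature_matrix()].
#' @param annotation a [sample_annotation()] covering its samples.
#' @param method optional method label to subset on.
#' @param conditions character(2): (numerator, denominator) conditions.
#' @return Tibble: `feature_id`, `patient_id`, `log2fc`.
#' @export
patient_fold_changes <- function(m, annotation, method = NULL,
                                 conditions = c("TT", "NAT")) {
  stopifnot(inherits(m, "feature_matrix"), m$is_log)
  check_annotation_covers(m, annotation)
  ann <- annotation[match(sample_ids(m), annotation$sample_id), ]
  if (!is.null(method)) ann <- dplyr::filter(ann, .data$method == !!method)
  rows <- purrr::map(unique(ann$subject_id), function(s) {
    s1 <- ann$sample_id[ann$subject_id == s & ann$condition == conditions[1]]
    s2 <- ann$sample_id[ann$subject_id == s & ann$condition == conditions[2]]
    if (length(s1) != 1 || length(s2) != 1) return(NULL)
    tibble::tibble(
      feature_id = feature_ids(m), patient_id = s,
      log2fc = m$values[, s1] - m$values[, s2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Permutation-normalised weighted-mean set enrichment
#'
#' For each set, the raw score is the (weight-1) sum of its measured
#' members' values. An empirical null is built by permuting the value
#' vector over all measured features B times and re-scoring the same
#' membership positions; the normalised score is the number of null
#' standard deviations the raw score sits from the null mean. Features
#' are sorted by id before permutation so results do not depend on input
#' row order.
#'
#' @param values named numeric vector (feature id -> value), or a tibble
#'   with `feature_id` and `value`. NAs are dropped.
#' @param sets set-collection tibble (`set_name`, `member`) or named list.
#' @param B permutation count (>= 100).
#' @param seed integer seed.
#' @param min_size sets with fewer measured members are skipped.
#' @return Tibble of class `enrichment_result`: `set_name`, `n_members`,
#'   `raw`, `null_mean`, `null_sd`, `norm`, `degenerate`. Skipped sets are
#'   recorded in `attr(, "skipped_sets")`.
#' @export
wmean_enrichment <- function(values, sets, B = 1000, seed = 1L, min_size = 2) {
  if (inherits(values, "data.frame")) {
    values <- stats::setNames(values$value, values$feature_id)
  }
  if (is.null(names(values))) stop("`values` must be named by feature id",
                                   call. = FALSE)
  if (B < 100) stop("need at least 100 permutations", call. = FALSE)
  values <- values[!is.na(values)]
  values <- values[order(names(values))]  # canonical feature order
  if (inherits(sets, "data.frame")) {
    sets <- split(sets$member, sets$set_name)
  }
  members <- purrr::map(sets, function(m) {
    which(names(values) %in% m)
  })
  sizes <- lengths(members)
  skipped <- names(members)[sizes < min_size]
  members <- members[sizes >= min_size]
  if (length(members) == 0) {
    stop("no set has at least ", min_size, " measured members", call. = FALSE)
  }
  # indicator matrix (sets x features): raw scores and all permutations
  # come from one matrix product each
  ind <- matrix(0, nrow = length(members), ncol = length(values),
                dimnames = list(names(members), NULL))
  for (i in seq_along(members)) ind[i, members[[i]]] <- 1
  raw <- drop(ind %*% values)
  local_rng(seed)
  perms <- replicate(B, values[sample.int(length(values))])
  null_scores <- ind %*% perms
  null_mean <- rowMeans(null_scores)
  null_sd <- apply(null_scores, 1, stats::sd)
  out <- tibble::tibble(
    set_name = names(members),
    n_members = lengths(members),
    raw = unname(raw),
    null_mean = unname(null_mean),
    null_sd = unname(null_sd),
    # a zero-sd null from constant member values scores 0 (no signal);
    # a whole-universe set has no null at all and stays undefined
    norm = ifelse(null_sd > 0, (raw - null_mean) / null_sd,
                  ifelse(lengths(members) < length(values), 0, NA_real_)),
    degenerate = null_sd == 0
  )
  attr(out, "skipped_sets") <- skipped
  attr(out, "B") <- B
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Per-patient enrichment matrix
#'
#' Runs [wmean_enrichment()] on each patient's z-scored values and binds
#' the results into one tidy set x patient table.
#'
#' @param z tibble with `feature_id`, `patient_id`, `z` (from
#'   [zscore_across_patients()]).
#' @inheritParams wmean_enrichment
#' @return `enrichment_result` tibble with an extra `patient_id` column.
#' @export
enrich_per_patient <- function(z, sets, B = 1000, seed = 1L, min_size = 2) {
  stopifnot(all(c("feature_id", "patient_id", "z") %in% names(z)))
  pats <- unique(z$patient_id)
  out <- purrr::imap(
    stats::setNames(pats, pats),
    function(p, nm) {
      sub <- dplyr::filter(z, .data$patient_id == p)
      res <- wmean_enrichment(
        stats::setNames(sub$z, sub$feature_id), sets,
        B = B, seed = seed, min_size = min_size
      )
      res$patient_id <- nm
      res
    }
  ) |> dplyr::bind_rows()
  attr(out, "B") <- B
  attr(out, "seed") <- as.integer(seed)
  class(out) <- unique(c("enrichment_result", class(out)))
  out
}

#' Enrichment in the three data configurations
#'
#' Computes per-patient hallmark enrichment (1) from proteomic z-scores
#' with the gene-only sets, (2) from the concatenated protein +
#' metabolite z-scores with the mixed gene/metabolite ontology, and (3)
#' as the element-wise mean of separate protein and metabolite normalised
#' scores (a set measured in only one modality keeps that modality's
#' score).
#'
#' @param prot_z,metab_z z-scored fold-change tibbles (`feature_id`,
#'   `patient_id`, `z`); `metab_z` may be `NULL`.
#' @param sets gene-only set collection.
#' @param mixed_sets mixed ontology from [transfer_hallmarks()]; defaults
#'   to `sets` when no metabolites are supplied.
#' @inheritParams wmean_enrichment
#' @return Named list of three `enrichment_result` tibbles:
#'   `proteins_only`, `integrated`, `averaged`.
#' @export
run_configurations <- function(prot_z, metab_z, sets, mixed_sets = NULL,
                               B = 1000, seed = 1L, min_size = 2) {
  if (is.null(mixed_sets)) mixed_sets <- sets
  cfg1 <- enrich_per_patient(prot_z, sets, B = B, seed = seed,
                             min_size = min_size)
  if (is.null(metab_z) || nrow(metab_z) == 0) {
    return(list(proteins_only = cfg1, integrated = cfg1, averaged = cfg1))
  }
  both_z <- dplyr::bind_rows(
    dplyr::select(prot_z, "feature_id", "patient_id", "z"),
    dplyr::select(metab_z, "feature_id", "patient_id", "z")
  )
  cfg2 <- enrich_per_patient(both_z, mixed_sets, B = B, seed = seed,
                             min_size = min_size)
  met_sets <- if (inherits(mixed_sets, "data.frame") &&
                  "member_type" %in% names(mixed_sets)) {
    dplyr::filter(mixed_sets, .data$member_type == "metabolite")
  } else {
    mixed_sets
  }
  cfg_met <- tryCatch(
    enrich_per_patient(metab_z, met_sets, B = B, seed = seed,
                       min_size = min_size),
    error = function(e) NULL
  )
  key <- c("set_name", "patient_id")
  cfg3 <- if (is.null(cfg_met)) {
    cfg1
  } else {
    dplyr::full_join(
      dplyr::select(cfg1, dplyr::all_of(key), norm_prot = "norm"),
      dplyr::select(cfg_met, dplyr::all_of(key), norm_met = "norm"),
      by = key
    ) |>
      dplyr::mutate(
        norm = dplyr::case_when(
          is.na(.data$norm_met) ~ .data$norm_prot,
          is.na(.data$norm_prot) ~ .data$norm_met,
          .default = (.data$norm_prot + .data$norm_met) / 2
        )
      )
  }
  class(cfg3) <- unique(c("enrichment_result", class(cfg3)))
  attr(cfg3, "B") <- B
  attr(cfg3, "seed") <- as.integer(seed)
  list(proteins_only = cfg1, integrated = cfg2, averaged = cfg3)
}

#' Compare enrichment scores between two methods
#'
#' Pearson correlation of normalised enrichment scores over shared sets,
#' per patient and pooled over all set x patient pairs.
#'
#' @param e1,e2 `enrichment_result` tibbles with a `patient_id` column
#'   (or without, for a single profile).
#' @return List: `per_patient` tibble (`patient_id`, `n_sets`, `r`),
#'   `pooled_r`.
#' @export
compare_methods <- function(e1, e2) {
  if (!"patient_id" %in% names(e1)) e1$patient_id <- "all"
  if (!"patient_id" %in% names(e2)) e2$patient_id <- "all"
  key <- c("set_name", "patient_id")
  merged <- dplyr::inner_join(
    dplyr::select(e1, dplyr::all_of(key), norm1 = "norm"),
    dplyr::select(e2, dplyr::all_of(key), norm2 = "norm"),
    by = key
  ) |> tidyr::drop_na()
  if (dplyr::n_distinct(merged$set_name) < 3) {
    stop("need at least 3 shared sets", call. = FALSE)
  }
  per_patient <- merged |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_sets = dplyr::n(),
      r = stats::cor(.data$norm1, .data$norm2),
      .groups = "drop"
    )
  list(
    per_patient = per_patient,
    pooled_r = stats::cor(merged$norm1, merged$norm2)
  )
}

#' Paired test for a difference between correlation vectors
#'
#' Paired Student t-test on per-patient correlation coefficients obtained
#' under two methods; df = n - 1. When the two vectors are identical the
#' difference has zero variance and the convention `t = 0`, `p = 1` is
#' returned.
#'
#' @param r_method1,r_method2 paired numeric vectors (n >= 2).
#' @return One-row tibble: `t`, `df`, `p.value`, `mean_difference`.
#' @export
test_correlation_difference <- function(r_method1, r_method2) {
  if (length(r_method1) != length(r_method2)) {
    stop("correlation vectors must be paired", call. = FALSE)
  }
  d <- r_method1 - r_method2
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    t_stat <- 0
    p <- 1
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  tibble::tibble(t = t_stat, df = n - 1, p.value = p, mean_difference = mean(d))
}
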