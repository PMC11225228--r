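#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Missing p-values stay missing and do not count
#' toward the number of tests m.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  obs <- !is.na(p)
  out[obs] <- stats::p.adjust(p[obs], method = "BH")
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test in the Mann-Whitney convention
#' (`W = rank-sum of a - n_a(n_a+1)/2`), with average ranks for ties and a
#' normal approximation using tie-corrected variance and a 0.5 continuity
#' correction. Used to compare fold-change magnitudes between feature
#' sets; no multiplicity adjustment is applied.
#'
#' @param a,b numeric vectors (non-empty; NAs dropped).
#' @return One-row tibble: `W`, `p.value`, `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(
    W = unname(ht$statistic), p.value = ht$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' Overlap summary across methods
#'
#' Given per-method feature sets (detected, or significant at the chosen
#' alpha), tabulates shared and unique memberships and reports the size of
#' the largest disjoint intersection cell relative to the union — the
#' headline "percent shared" statistic of UpSet-style comparisons.
#'
#' @param sets named list of character vectors (one per method), or a
#'   named list of `diff_result` tibbles (then filtered at
#'   `adj.p.value < alpha`).
#' @param alpha significance cutoff applied when `sets` holds
#'   `diff_result`s.
#' @return A list of class `overlap_summary`: `membership` (tibble of
#'   feature x method flags), `counts` (tibble per intersection pattern),
#'   `n_union`, `percent_largest`.
#' @export
overlap_sets <- function(sets, alpha = 0.05) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  ids <- purrr::map(sets, function(s) {
    if (inherits(s, "diff_result")) {
      s$feature_id[!is.na(s$adj.p.value) & s$adj.p.value < alpha]
    } else {
      as.character(s)
    }
  })
  universe <- sort(unique(unlist(ids)))
  membership <- tibble::tibble(feature_id = universe)
  for (nm in names(ids)) membership[[nm]] <- universe %in% ids[[nm]]
  if (length(universe) > 0) {
    pattern <- apply(as.matrix(membership[names(ids)]), 1, function(z) {
      paste(names(ids)[z], collapse = "&")
    })
    counts <- dplyr::count(tibble::tibble(pattern = pattern), .data$pattern,
                           name = "n")
  } else {
    counts <- tibble::tibble(pattern = character(), n = integer())
  }
  # largest disjoint intersection cell (UpSet convention), not input set
  largest <- if (nrow(counts) > 0) max(counts$n) else 0L
  structure(
    list(
      membership = membership,
      counts = counts,
      set_sizes = lengths(ids),
      n_union = length(universe),
      percent_largest = if (length(universe) > 0) 100 * largest / length(universe) else NA_real_
    ),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d features in union; largest set = %.1f%% of union\n",
              x$n_union, x$percent_largest))
  print(x$counts)
  invisible(x)
}

#' Concordance of t-values between two analyses
#'
#' Correlates matched moderated t-statistics from two differential
#' analyses (e.g. the same contrast computed from two extraction methods)
#' on the intersection of their features.
#'
#' @param res1,res2 `diff_result` tibbles.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `method`, `n`, `estimate`, `p.value`.
#' @export
concordance_t <- function(res1, res2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  merged <- dplyr::inner_join(
    dplyr::select(res1, "feature_id", t1 = "t"),
    dplyr::select(res2, "feature_id", t2 = "t"),
    by = "feature_id"
  ) |>
    tidyr::drop_na()
  if (nrow(merged) < 4) stop("need at least 4 shared features", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(merged$t1, merged$t2, method = method))
  tibble::tibble(
    method = method, n = nrow(merged),
    estimate = unname(ct$estimate), p.value = ct$p.value
  )
}

#' Random-split heterogeneity test
#'
#' Negative-control analysis: within one method's samples, randomly split
#' the cohort into two balanced halves (balanced within tissue condition;
#' an odd group leaves one sample out at random), then test
#' `group1 - group2` with tissue condition as a covariate. Under
#' homogeneity no features should reach significance.
#'
#' @param m a log-scale [feature_matrix()].
#' @param annotation a [sample_annotation()] covering its samples.
#' @param seed integer seed controlling the split.
#' @param alpha significance level.
#' @return A `diff_result` tibble; the split is recorded in
#'   `attr(, "split")` and any left-out sample in `attr(, "left_out")`.
#' @export
random_split_test <- function(m, annotation, seed = 1L, alpha = 0.05) {
  check_annotation_covers(m, annotation)
  ann <- annotation[match(sample_ids(m), annotation$sample_id), ]
  if (nrow(ann) < 4) stop("need at least 4 samples", call. = FALSE)
  rng <- local_rng(seed)
  left_out <- character(0)
  grp <- rep(NA_character_, nrow(ann))
  for (cond in unique(ann$condition)) {
    idx <- sample(which(ann$condition == cond))
    if (length(idx) %% 2 == 1) {
      left_out <- c(left_out, ann$sample_id[idx[1]])
      idx <- idx[-1]
    }
    half <- length(idx) / 2
    grp[idx[seq_len(half)]] <- "random_group1"
    grp[idx[half + seq_len(half)]] <- "random_group2"
  }
  keep <- !is.na(grp)
  ann2 <- ann[keep, ]
  ann2$split_group <- grp[keep]
  m2 <- m
  m2$values <- m2$values[, keep, drop = FALSE]
  design <- make_design(ann2, terms = "split_group", block = "condition")
  fit <- fit_feature_models(m2, design)
  res <- moderated_t(fit, c(random_group1 = 1, random_group2 = -1),
                     alpha = alpha)
  attr(res, "split") <- stats::setNames(ann2$split_group, ann2$sample_id)
  attr(res, "left_out") <- left_out
  res
}

#' Hypergeometric over-representation test
#'
#' For each annotation set, tests whether significant features are
#' over-represented relative to the measured universe (upper-tail
#' hypergeometric, i.e. one-sided Fisher), with BH adjustment across sets.
#'
#' @param signif character vector of significant feature ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all measured feature ids.
#' @param sets named list of character vectors, or a set collection tibble
#'   from [read_gmt()].
#' @return Tibble: `set_name`, `set_size` (within universe), `overlap`,
#'   `expected`, `p.value`, `adj.p.value`.
#' @export
ora_hypergeometric <- function(signif, universe, sets) {
  universe <- unique(as.character(universe))
  signif <- unique(as.character(signif))
  extra <- setdiff(signif, universe)
  if (length(extra) > 0) {
    stop("significant ids outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  if (inherits(sets, "data.frame")) {
    sets <- split(sets$member, sets$set_name)
  }
  n_univ <- length(universe)
  n_sig <- length(signif)
  rows <- purrr::imap(sets, function(members, nm) {
    in_univ <- intersect(unique(members), universe)
    k <- length(intersect(in_univ, signif))
    m_set <- length(in_univ)
    p <- stats::phyper(k - 1, m_set, n_univ - m_set, n_sig, lower.tail = FALSE)
    tibble::tibble(
      set_name = nm, set_size = m_set, overlap = k,
      expected = n_sig * m_set / n_univ, p.value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$adj.p.value <- bh_adjust(out$p.value)
  out
}

# seed the caller's RNG scope; global RNG state is restored on exit
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
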