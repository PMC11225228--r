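#' Imbalance-scoring parameters
#'
#' @param distance_penalty geometric distance penalty p (> 1); a
#'   metabolite d reaction steps away contributes with weight
#'   `p^-(d-1)`, so direct reactants/products weigh 1. Default 8.
#' @param max_depth maximum reaction-step distance explored (default 5).
#' @param min_branch_length minimum number of measured metabolites
#'   required on each side of a reaction for it to be scored (default 1
#'   upstream and 1 downstream).
#' @return List of class `imbalance_config`.
#' @export
imbalance_config <- function(distance_penalty = 8, max_depth = 5L,
                             min_branch_length = 1L) {
  stopifnot(distance_penalty > 1, max_depth >= min_branch_length,
            min_branch_length >= 1)
  structure(
    list(distance_penalty = distance_penalty,
         max_depth = as.integer(max_depth),
         min_branch_length = as.integer(min_branch_length)),
    class = "imbalance_config"
  )
}

#' Distance-weighted metabolite signatures per enzyme reaction
#'
#' Breadth-first traversal from each reaction an enzyme catalyses:
#' upstream walks against the edge direction through reactant edges
#' (the reaction's substrates, then the substrates of the reactions that
#' produce them, ...), downstream walks along product edges. Each
#' metabolite keeps its minimal reaction-step distance d (cycles are
#' handled by minimality), up to `max_depth`, and gets the weight
#' `distance_penalty^-(d-1)`.
#'
#' @param net a [reaction_network()].
#' @param config an [imbalance_config()].
#' @return Tibble of class `signature_weights`: `enzyme`, `reaction_id`,
#'   `side` (`upstream`/`downstream`), `metabolite`, `distance`, `weight`.
#' @export
build_signatures <- function(net, config = imbalance_config()) {
  stopifnot(inherits(net, "reaction_network"),
            inherits(config, "imbalance_config"))
  e <- net$edges
  # reaction -> its substrate / product metabolites
  reactants_of <- split(e$source[e$edge_role == "reactant"],
                        e$reaction_id[e$edge_role == "reactant"])
  products_of <- split(e$target[e$edge_role == "product"],
                       e$reaction_id[e$edge_role == "product"])
  # metabolite -> reactions producing / consuming it
  producing <- split(e$reaction_id[e$edge_role == "product"],
                     e$target[e$edge_role == "product"])
  consuming <- split(e$reaction_id[e$edge_role == "reactant"],
                     e$source[e$edge_role == "reactant"])
  enzyme_of <- c(
    stats::setNames(e$target[e$edge_role == "reactant"],
                    e$reaction_id[e$edge_role == "reactant"]),
    stats::setNames(e$source[e$edge_role == "product"],
                    e$reaction_id[e$edge_role == "product"])
  )
  enzyme_of <- enzyme_of[!duplicated(names(enzyme_of))]

  walk <- function(rxn, side) {
    # frontier of metabolites at distance d; step to the next reactions
    dist <- list()
    frontier <- if (side == "upstream") reactants_of[[rxn]] else products_of[[rxn]]
    frontier <- unique(frontier)
    d <- 1L
    while (length(frontier) > 0 && d <= config$max_depth) {
      new <- setdiff(frontier, names(dist))
      for (m in new) dist[[m]] <- d
      if (d == config$max_depth) break
      next_rxns <- unique(unlist(
        if (side == "upstream") producing[new] else consuming[new]
      ))
      frontier <- unique(unlist(
        if (side == "upstream") reactants_of[next_rxns] else products_of[next_rxns]
      ))
      d <- d + 1L
    }
    if (length(dist) == 0) return(NULL)
    d_vec <- unname(unlist(dist))
    tibble::tibble(
      metabolite = names(dist),
      distance = d_vec,
      weight = config$distance_penalty^-(d_vec - 1)
    )
  }

  rxns <- unique(e$reaction_id)
  rows <- purrr::map(rxns, function(r) {
    purrr::map(c("upstream", "downstream"), function(s) {
      w <- walk(r, s)
      if (is.null(w)) return(NULL)
      w$enzyme <- enzyme_of[[r]]
      w$reaction_id <- r
      w$side <- s
      w
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- dplyr::select(rows, "enzyme", "reaction_id", "side", "metabolite",
                       "distance", "weight")
  class(out) <- c("signature_weights", class(out))
  attr(out, "config") <- config
  out
}

#' Enzyme-centred metabolic imbalance scores
#'
#' Per reaction, each side's score is the weighted mean of the measured
#' metabolites' differential t-values (weights from
#' [build_signatures()]); the reaction's imbalance is downstream minus
#' upstream, sign-inverted for reactions flagged `reverse`. Reactions
#' missing a measured metabolite on either side (below
#' `min_branch_length`) are skipped, and an enzyme's score is the mean
#' over its scored reactions. Extreme scores flag metabolic bottlenecks:
#' enzymes whose substrates and products change in opposite directions.
#'
#' @param signatures a [build_signatures()] result.
#' @param metabolite_t named numeric vector (metabolite id -> t-value) or
#'   tibble with `feature_id` and `t`.
#' @param net the [reaction_network()] (source of reverse flags).
#' @return Tibble of class `imbalance_result`: `enzyme`, `upstream`,
#'   `downstream`, `imbalance`, `n_reactions`. Enzymes with no scorable
#'   reaction carry `NA` and are listed in `attr(, "unscored")`.
#' @export
score_imbalance <- function(signatures, metabolite_t, net) {
  stopifnot(inherits(signatures, "signature_weights"),
            inherits(net, "reaction_network"))
  if (inherits(metabolite_t, "data.frame")) {
    metabolite_t <- stats::setNames(metabolite_t$t, metabolite_t$feature_id)
  }
  metabolite_t <- metabolite_t[!is.na(metabolite_t)]
  if (length(metabolite_t) == 0) {
    stop("no measured metabolite t-values", call. = FALSE)
  }
  cfg <- attr(signatures, "config") %||% imbalance_config()
  rev_of <- stats::setNames(net$edges$reverse, net$edges$reaction_id)
  rev_of <- rev_of[!duplicated(names(rev_of))]

  side_scores <- signatures |>
    dplyr::filter(.data$metabolite %in% names(metabolite_t)) |>
    dplyr::mutate(t = unname(metabolite_t[.data$metabolite])) |>
    dplyr::group_by(.data$enzyme, .data$reaction_id, .data$side) |>
    dplyr::summarise(
      score = sum(.data$weight * .data$t) / sum(.data$weight),
      n_measured = dplyr::n(), .groups = "drop"
    )
  wide <- side_scores |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("score", "n_measured"))
  for (col in c("score_upstream", "score_downstream",
                "n_measured_upstream", "n_measured_downstream")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  per_reaction <- wide |>
    dplyr::filter(
      !is.na(.data$score_upstream), !is.na(.data$score_downstream),
      .data$n_measured_upstream >= cfg$min_branch_length,
      .data$n_measured_downstream >= cfg$min_branch_length
    ) |>
    dplyr::mutate(
      imbalance = (.data$score_downstream - .data$score_upstream) *
        ifelse(unname(rev_of[.data$reaction_id]), -1, 1)
    )
  all_enzymes <- unique(signatures$enzyme)
  per_enzyme <- per_reaction |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(
      upstream = mean(.data$score_upstream),
      downstream = mean(.data$score_downstream),
      imbalance = mean(.data$imbalance),
      n_reactions = dplyr::n(), .groups = "drop"
    )
  out <- tibble::tibble(enzyme = all_enzymes) |>
    dplyr::left_join(per_enzyme, by = "enzyme") |>
    dplyr::mutate(n_reactions = dplyr::coalesce(.data$n_reactions, 0L))
  attr(out, "unscored") <- out$enzyme[out$n_reactions == 0]
  attr(out, "per_reaction") <- per_reaction
  class(out) <- c("imbalance_result", class(out))
  out
}

#' Correlate imbalance scores with proteomic t-values
#'
#' Pearson correlation of per-enzyme metabolic imbalance scores against
#' the enzymes' proteomic differential t-values, optionally restricted to
#' a curated enzyme subset (e.g. the canonical TCA-cycle enzymes).
#'
#' @param imbalance an [score_imbalance()] result.
#' @param prot_t `diff_result` tibble (or tibble with `feature_id`, `t`)
#'   whose feature ids are enzyme ids.
#' @param enzyme_subset optional character vector restricting the
#'   comparison.
#' @return One-row tibble: `n`, `r`, `p.value`.
#' @export
correlate_with_proteomics <- function(imbalance, prot_t, enzyme_subset = NULL) {
  stopifnot(inherits(imbalance, "imbalance_result"))
  merged <- dplyr::inner_join(
    dplyr::select(imbalance, "enzyme", "imbalance"),
    dplyr::select(prot_t, enzyme = "feature_id", "t"),
    by = "enzyme"
  ) |> tidyr::drop_na()
  if (!is.null(enzyme_subset)) {
    merged <- dplyr::filter(merged, .data$enzyme %in% enzyme_subset)
  }
  if (nrow(merged) < 3) stop("need at least 3 matched enzymes", call. = FALSE)
  ct <- stats::cor.test(merged$imbalance, merged$t, method = "pearson")
  tibble::tibble(n = nrow(merged), r = unname(ct$estimate),
                 p.value = ct$p.value)
}
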