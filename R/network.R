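#' Bipartite metabolite-enzyme reaction network
#'
#' A directed bipartite graph: reactant edges run metabolite -> enzyme,
#' product edges enzyme -> metabolite, every edge tagged with a reaction
#' id, and every reaction optionally flagged `reverse` (its imbalance
#' score is sign-inverted downstream).
#'
#' @param edges tibble/data frame with columns `source`, `target`,
#'   `reaction_id`, `reverse` (logical).
#' @param node_types named character vector mapping every node id to
#'   `"metabolite"` or `"enzyme"`; if `NULL`, types are inferred from
#'   `metabolite_prefix`.
#' @param metabolite_prefix prefix marking metabolite ids when
#'   `node_types` is absent (all other nodes are enzymes).
#' @return An object of class `reaction_network`: validated `edges` with
#'   `edge_role` (`reactant`/`product`), plus `nodes` tibble.
#' @export
reaction_network <- function(edges, node_types = NULL, metabolite_prefix = "M") {
  need <- c("source", "target", "reaction_id", "reverse")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0) {
    stop("edge table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)[need]
  edges$reverse <- as.logical(edges$reverse)
  all_nodes <- unique(c(edges$source, edges$target))
  if (is.null(node_types)) {
    node_types <- stats::setNames(
      ifelse(startsWith(all_nodes, metabolite_prefix), "metabolite", "enzyme"),
      all_nodes
    )
  }
  missing_type <- setdiff(all_nodes, names(node_types))
  if (length(missing_type) > 0) {
    stop("nodes without a declared type: ",
         paste(missing_type, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(node_types), c("metabolite", "enzyme"))
  if (length(bad_type) > 0) {
    stop("node types must be metabolite or enzyme; found: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  st <- unname(node_types[edges$source])
  tt <- unname(node_types[edges$target])
  not_bipartite <- st == tt
  if (any(not_bipartite)) {
    i <- which(not_bipartite)[1]
    stop(sprintf("non-bipartite edge %s -> %s (both %s)",
                 edges$source[i], edges$target[i], st[i]), call. = FALSE)
  }
  edges$edge_role <- ifelse(st == "metabolite", "reactant", "product")
  roles <- split(edges$edge_role, edges$reaction_id)
  dangling <- names(roles)[!vapply(roles, function(r) {
    all(c("reactant", "product") %in% r)
  }, logical(1))]
  if (length(dangling) > 0) {
    stop("reaction(s) without both a reactant and a product edge: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  rev_by_rxn <- vapply(split(edges$reverse, edges$reaction_id),
                       function(z) length(unique(z)) == 1, logical(1))
  if (!all(rev_by_rxn)) {
    stop("inconsistent reverse flag within reaction(s): ",
         paste(names(rev_by_rxn)[!rev_by_rxn], collapse = ", "), call. = FALSE)
  }
  nodes <- tibble::tibble(
    node_id = names(node_types)[names(node_types) %in% all_nodes],
    node_type = unname(node_types[names(node_types) %in% all_nodes])
  )
  structure(list(edges = edges, nodes = nodes), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf(
    "<reaction_network> %d metabolites, %d enzymes, %d reactions (%d reverse)\n",
    sum(x$nodes$node_type == "metabolite"),
    sum(x$nodes$node_type == "enzyme"),
    length(unique(x$edges$reaction_id)),
    length(unique(x$edges$reaction_id[x$edges$reverse]))
  ))
  invisible(x)
}

#' Read a reaction network from a TSV edge list
#'
#' Columns `source`, `target`, `reaction_id`, `reverse`; optional columns
#' `source_type`, `target_type` declare node types, otherwise types are
#' inferred from `metabolite_prefix`.
#'
#' @param path TSV file.
#' @inheritParams reaction_network
#' @return A validated [reaction_network()].
#' @export
read_network <- function(path, metabolite_prefix = "M") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    reverse = readr::col_logical(), .default = readr::col_character()
  ))
  node_types <- NULL
  if (all(c("source_type", "target_type") %in% names(tab))) {
    node_types <- c(
      stats::setNames(tab$source_type, tab$source),
      stats::setNames(tab$target_type, tab$target)
    )
    node_types <- node_types[!duplicated(names(node_types))]
  }
  reaction_network(tab, node_types = node_types,
                   metabolite_prefix = metabolite_prefix)
}

#' @rdname read_network
#' @param net a [reaction_network()].
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  types <- stats::setNames(net$nodes$node_type, net$nodes$node_id)
  out <- net$edges |>
    dplyr::mutate(
      source_type = unname(types[.data$source]),
      target_type = unname(types[.data$target])
    ) |>
    dplyr::select("source", "target", "reaction_id", "reverse",
                  "source_type", "target_type")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard MSigDB dialect: one set per line — name, description, then
#' tab-separated member ids. Members are typed `gene` by default.
#'
#' @param path GMT file.
#' @param member_type type assigned to all members.
#' @return Tibble of class `geneset_collection` with columns `set_name`,
#'   `member`, `member_type`; an attribute `descriptions` keeps the
#'   per-set description.
#' @export
read_gmt <- function(path, member_type = "gene") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, character(1), 1)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup) > 0) {
    stop("duplicate set name(s) in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  empty <- lengths(fields) < 3
  if (any(empty)) {
    stop("set(s) with no members: ", paste(names_[empty], collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map(fields, function(f) {
    tibble::tibble(set_name = f[1], member = f[-(1:2)])
  })
  out <- dplyr::bind_rows(rows)
  out$member_type <- member_type
  attr(out, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2), names_
  )
  class(out) <- c("geneset_collection", class(out))
  out
}

#' @rdname read_gmt
#' @param sets a set-collection tibble (`set_name`, `member`).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% character(0)
  grps <- split(sets$member, factor(sets$set_name, levels = unique(sets$set_name)))
  out <- purrr::imap_chr(grps, function(members, nm) {
    paste(c(nm, desc[nm] %|NA|% "na", members), collapse = "\t")
  })
  readr::write_lines(out, path)
  invisible(path)
}

`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Transfer pathway membership from enzymes to adjacent metabolites
#'
#' For every metabolite directly adjacent (as reactant or product) to an
#' enzyme that belongs to a pathway set, the metabolite is added to that
#' set with type `metabolite`. Gene members are never removed, so the
#' result is a mixed gene + metabolite ontology.
#'
#' @param sets a set-collection tibble (`set_name`, `member`,
#'   `member_type`), e.g. from [read_gmt()].
#' @param net a [reaction_network()] whose enzyme ids are comparable to
#'   the gene ids in `sets`.
#' @return The augmented set collection, same class as `sets`.
#' @export
transfer_hallmarks <- function(sets, net) {
  stopifnot(inherits(net, "reaction_network"))
  stopifnot(all(c("set_name", "member") %in% names(sets)))
  if (!"member_type" %in% names(sets)) sets$member_type <- "gene"
  enzymes <- net$nodes$node_id[net$nodes$node_type == "enzyme"]
  hit <- intersect(enzymes, sets$member[sets$member_type == "gene"])
  if (length(hit) == 0) {
    warning("no network enzyme appears in the set collection; ",
            "sets returned unchanged", call. = FALSE)
    return(sets)
  }
  e <- net$edges
  adj <- dplyr::bind_rows(
    tibble::tibble(enzyme = e$target[e$edge_role == "reactant"],
                   metabolite = e$source[e$edge_role == "reactant"]),
    tibble::tibble(enzyme = e$source[e$edge_role == "product"],
                   metabolite = e$target[e$edge_role == "product"])
  ) |> dplyr::distinct()
  new_members <- sets |>
    dplyr::filter(.data$member_type == "gene") |>
    dplyr::inner_join(adj, by = c(member = "enzyme"),
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$set_name, member = .data$metabolite,
                     member_type = "metabolite") |>
    dplyr::distinct()
  out <- dplyr::bind_rows(tibble::as_tibble(sets), new_members) |>
    dplyr::distinct()
  class(out) <- unique(c("geneset_collection", class(out)))
  attr(out, "descriptions") <- attr(sets, "descriptions")
  out
}
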