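AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Kyte-Doolittle hydropathy table
#'
#' The packaged 20-residue hydropathy scale used by [gravy()]; positive
#' values are hydrophobic.
#'
#' @return Named numeric vector, one entry per standard residue.
#' @export
kyte_doolittle_hydropathy <- function() {
  path <- system.file("extdata", "kyte_doolittle_hydropathy.tsv",
                      package = "duomics", mustWork = TRUE)
  tab <- readr::read_tsv(path, comment = "#", col_types = "cd")
  stats::setNames(tab$hydropathy, tab$residue)
}

#' IPC_protein pKa table
#'
#' The packaged pKa values of the nine ionizable groups (N/C termini and
#' the D, E, C, Y, H, K, R side chains) used for net charge and
#' isoelectric-point calculations.
#'
#' @return Tibble with columns `group`, `pka`, `kind` (acidic/basic).
#' @export
ipc_protein_pka <- function() {
  path <- system.file("extdata", "ipc_protein_pka.tsv",
                      package = "duomics", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", col_types = "cdc")
}

check_sequence <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters), AA20)
  if (length(bad) > 0) {
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  letters
}

#' GRAVY: grand average of hydropathy
#'
#' Sum of per-residue hydropathy values divided by sequence length.
#' Positive scores mean hydrophobic sequences, which detergent-based and
#' solvent-based extraction protocols may recover differently.
#'
#' @param sequence single string over the 20 standard one-letter codes.
#' @param table named hydropathy vector; defaults to the packaged
#'   Kyte-Doolittle scale.
#' @return GRAVY score (dimensionless).
#' @examples
#' gravy("I") # 4.5
#' @export
gravy <- function(sequence, table = kyte_doolittle_hydropathy()) {
  letters <- check_sequence(sequence)
  if (length(setdiff(AA20, names(table))) > 0 || length(table) != 20) {
    stop("hydropathy table must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  sum(table[letters]) / length(letters)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch census over one N-terminal group, one C-terminal
#' group and every ionizable side chain (D, E, C, Y acidic; H, K, R basic):
#' \deqn{Q(pH) = \sum_{basic} \frac{1}{1+10^{pH-pKa}} -
#'       \sum_{acidic} \frac{1}{1+10^{pKa-pH}}.}
#' Q is strictly decreasing in pH, positive at pH 0 and negative at pH 14.
#'
#' @param sequence single string over the 20 standard one-letter codes.
#' @param pH pH in \[0, 14\].
#' @param pka pKa table as returned by [ipc_protein_pka()].
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(sequence, pH, pka = ipc_protein_pka()) {
  letters <- check_sequence(sequence)
  counts <- table(factor(letters, levels = AA20))
  pk <- stats::setNames(pka$pka, pka$group)
  kind <- stats::setNames(pka$kind, pka$group)
  n_of <- function(g) {
    if (g %in% c("N_terminal", "C_terminal")) 1 else unname(counts[g])
  }
  q <- 0
  for (g in pka$group) {
    n <- n_of(g)
    if (n == 0) next
    q <- q + if (kind[g] == "basic") {
      n / (1 + 10^(pH - pk[g]))
    } else {
      -n / (1 + 10^(pk[g] - pH))
    }
  }
  unname(q)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero by bisection on \[0, 14\].
#' The charge function is strictly decreasing so the root is unique; the
#' search stops once the bracket is narrower than `tol`.
#'
#' @inheritParams net_charge
#' @param tol bracket width in pH units (default 1e-4).
#' @return pI in pH units, inside (0, 14).
#' @export
isoelectric_point <- function(sequence, pka = ipc_protein_pka(), tol = 1e-4) {
  stopifnot(tol > 0)
  check_sequence(sequence)
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physico-chemical properties for a set of sequences
#'
#' Vectorised wrapper computing length, GRAVY and isoelectric point per
#' sequence.
#'
#' @param sequences data frame with columns `id` and `sequence`, or a
#'   named character vector.
#' @inheritParams isoelectric_point
#' @return Tibble with columns `id`, `length`, `gravy`,
#'   `isoelectric_point`.
#' @export
physchem_properties <- function(sequences, pka = ipc_protein_pka(), tol = 1e-4) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = names(sequences) %||% as.character(seq_along(sequences)),
      sequence = unname(sequences)
    )
  }
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  hydro <- kyte_doolittle_hydropathy()
  tibble::as_tibble(sequences) |>
    dplyr::transmute(
      id = .data$id,
      length = nchar(.data$sequence),
      gravy = purrr::map_dbl(.data$sequence, gravy, table = hydro),
      isoelectric_point = purrr::map_dbl(.data$sequence, isoelectric_point,
                                         pka = pka, tol = tol)
    )
}

#' Read protein/peptide sequences from FASTA
#'
#' @param path FASTA file; the id is the header up to the first whitespace.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, ">")
  if (!any(is_header) || !is_header[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(is_header)
  ids <- sub("^>(\\S+).*$", "\\1", lines[is_header])
  seqs <- vapply(
    split(lines[!is_header], grp[!is_header]),
    function(x) toupper(paste(x, collapse = "")), character(1)
  )
  check_unique_ids(ids, "sequence")
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' @rdname read_fasta_sequences
#' @param sequences tibble with `id`, `sequence`.
#' @param width line-wrap width.
#' @export
write_fasta_sequences <- function(sequences, path, width = 60) {
  out <- purrr::map2(sequences$id, sequences$sequence, function(id, s) {
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

#' Association between physico-chemical scores and differential statistics
#'
#' Spearman rank correlation (average ranks for ties, two-sided p via the
#' t approximation) between a physico-chemical property and per-feature
#' moderated t-values, matched by id. A significant association indicates
#' that one extraction route is biased with respect to that property.
#'
#' @param scores tibble with `id` plus one or more score columns
#'   (e.g. from [physchem_properties()]).
#' @param t_values tibble with `feature_id` (or `id`) and `t`.
#' @param property which score column to associate (default `"gravy"`).
#' @return One-row tibble: `property`, `n`, `rho`, `p.value`.
#' @export
associate_physchem <- function(scores, t_values, property = "gravy") {
  stopifnot(property %in% names(scores))
  id_col <- if ("feature_id" %in% names(t_values)) "feature_id" else "id"
  merged <- dplyr::inner_join(
    dplyr::select(scores, "id", dplyr::all_of(property)),
    dplyr::select(t_values, id = dplyr::all_of(id_col), "t"),
    by = "id"
  ) |>
    tidyr::drop_na()
  if (nrow(merged) < 4) {
    stop("need at least 4 matched observations", call. = FALSE)
  }
  x <- merged[[property]]
  y <- merged$t
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ", property, " or t",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  n <- nrow(merged)
  rho <- unname(ct$estimate)
  # t approximation for the two-sided p (robust to ties)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble::tibble(
    property = property, n = n, rho = rho,
    p.value = 2 * stats::pt(-abs(t_stat), df = n - 2)
  )
}
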