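#' Simulation parameters for a paired two-method cohort
#'
#' Defaults describe a desk-scale lung-cancer-style cohort: 10 patients
#' with paired tumour (TT) and adjacent normal (NAT) tissue, profiled by
#' two extraction methods that share the same biology but add small
#' method-specific offsets. Intensities are log-normal; missingness is
#' abundance-dependent (more missing at low abundance).
#'
#' @param n_subjects number of patients (paired TT/NAT).
#' @param conditions two condition labels.
#' @param methods two extraction-method labels.
#' @param n_proteins,n_metabolites feature-panel sizes.
#' @param fraction_de fraction of features with a non-zero TT-NAT effect.
#' @param effect_size_mean,effect_size_sd log2 effect magnitude
#'   distribution (signs random).
#' @param method_offset_sd sd of per-feature, per-method log2 offsets.
#' @param rho_block correlation in \[0, 1) between the two methods'
#'   measurements of the same tissue sample (ratio of shared tissue-state
#'   variance to total noise variance).
#' @param noise_sd per-measurement log2 noise sd.
#' @param missing_rate_base protein missingness rate at average abundance.
#' @param missing_abundance_slope logit-slope of missingness per log2 unit
#'   below average abundance; 0 gives missing-completely-at-random.
#' @param n_hallmarks number of planted pathway sets.
#' @param pathway_activity_sd sd (log2 units) of the tumour-specific
#'   per-(pathway, patient) activity shifts applied to all members of a
#'   set in that patient's TT sample; this patient-level pathway biology
#'   is shared between methods and is what per-patient enrichment
#'   analyses recover. 0 disables it.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param seed integer seed; same seed gives identical cohorts.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 10,
                              conditions = c("TT", "NAT"),
                              methods = c("autoSP3", "MTBE-SP3"),
                              n_proteins = 2000,
                              n_metabolites = 405,
                              fraction_de = 0.45,
                              effect_size_mean = 1,
                              effect_size_sd = 0.5,
                              method_offset_sd = 0.2,
                              rho_block = 0.8,
                              noise_sd = 0.25,
                              missing_rate_base = 0.1,
                              missing_abundance_slope = 0.3,
                              n_hallmarks = 50,
                              pathway_activity_sd = 0.3,
                              baseline_mean = 25,
                              baseline_sd = 2,
                              seed = 1L) {
  stopifnot(
    n_subjects >= 2, length(conditions) == 2, length(methods) == 2,
    n_proteins > 0, n_metabolites >= 0,
    fraction_de >= 0, fraction_de <= 1,
    effect_size_sd >= 0, method_offset_sd >= 0,
    noise_sd >= 0, missing_rate_base >= 0, missing_rate_base < 1,
    n_hallmarks >= 1, pathway_activity_sd >= 0
  )
  if (rho_block < 0 || rho_block >= 1) {
    stop("rho_block must lie in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_params")
}

# shared tissue-state sd implied by rho_block and the measurement noise
block_sd <- function(p) p$noise_sd * sqrt(p$rho_block / (1 - p$rho_block))

#' Simulate a paired tumour/normal two-method cohort
#'
#' Generates protein intensities for every subject x condition x method,
#' metabolite concentrations (with a quality-status matrix) for every
#' subject x condition, a sample annotation table, and the ground truth.
#' Each tissue sample's deviation from the cohort mean is drawn once per
#' (feature, subject, condition) and shared between the two methods —
#' the two routes profile aliquots of the same tissue — which is what
#' makes cross-method concordance measurable in silico.
#'
#' @param params a [simulation_params()] object.
#' @return List of class `cohort_sim` with elements `proteins` (raw-scale
#'   [feature_matrix()]), `metabolites`, `quality` ([quality_matrix()]),
#'   `annotation` ([sample_annotation()]) and `truth` (list: `features`
#'   tibble with `feature_id`, `feature_kind`, `true_effect`, `is_de`;
#'   `hallmarks` membership tibble; `bottleneck_enzyme`).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  local_rng(p$seed)
  subjects <- sprintf("S%02d", seq_len(p$n_subjects))
  sd_b <- block_sd(p)
  set_names <- sprintf("HALLMARK_%02d", seq_len(p$n_hallmarks))
  # tumour-specific pathway activity per (set, patient), shared by methods
  activity <- matrix(stats::rnorm(p$n_hallmarks * p$n_subjects, 0,
                                  p$pathway_activity_sd),
                     nrow = p$n_hallmarks,
                     dimnames = list(set_names, subjects))

  sim_block <- function(ids, kind, baseline_mean, baseline_sd, methods,
                        set_idx) {
    nf <- length(ids)
    baseline <- stats::rnorm(nf, baseline_mean, baseline_sd)
    is_de <- rep(FALSE, nf)
    n_de <- round(p$fraction_de * nf)
    if (n_de > 0) is_de[sample.int(nf, n_de)] <- TRUE
    effect <- ifelse(
      is_de,
      sample(c(-1, 1), nf, replace = TRUE) *
        abs(stats::rnorm(nf, p$effect_size_mean, p$effect_size_sd)),
      0
    )
    # tissue state shared across methods, per (feature, subject, condition)
    b <- array(stats::rnorm(nf * p$n_subjects * 2, 0, sd_b),
               dim = c(nf, p$n_subjects, 2))
    offsets <- matrix(stats::rnorm(nf * length(methods), 0, p$method_offset_sd),
                      nrow = nf)
    act <- matrix(0, nf, p$n_subjects)
    assigned <- !is.na(set_idx)
    act[assigned, ] <- activity[set_idx[assigned], , drop = FALSE]
    cols <- list()
    for (m_i in seq_along(methods)) {
      for (s_i in seq_len(p$n_subjects)) {
        for (c_i in 1:2) {
          is_tt <- p$conditions[c_i] == "TT"
          mu <- baseline + b[, s_i, c_i] +
            (effect + act[, s_i]) * is_tt +
            offsets[, m_i]
          nm <- paste(subjects[s_i], p$conditions[c_i],
                      gsub("[^A-Za-z0-9]", "", methods[m_i]), sep = "_")
          cols[[nm]] <- mu + stats::rnorm(nf, 0, p$noise_sd)
        }
      }
    }
    x <- do.call(cbind, cols)
    rownames(x) <- ids
    list(log2 = x, baseline = baseline, effect = effect, is_de = is_de)
  }

  prot_ids <- sprintf("PROT%04d", seq_len(p$n_proteins))
  prot_set_idx <- sample(rep_len(seq_len(p$n_hallmarks), p$n_proteins))
  prot <- sim_block(prot_ids, "protein", p$baseline_mean, p$baseline_sd,
                    p$methods, prot_set_idx)
  # abundance-dependent missingness on the protein panel
  centred <- prot$log2 - mean(prot$baseline)
  pmiss <- stats::plogis(stats::qlogis(max(p$missing_rate_base, 1e-12)) -
                           p$missing_abundance_slope * centred)
  if (p$missing_rate_base > 0) {
    drop <- matrix(stats::runif(length(pmiss)) < pmiss, nrow = nrow(pmiss))
    prot$log2[drop] <- NA
  }
  proteins <- feature_matrix(2^prot$log2, feature_kind = "protein")

  met_ids <- if (p$n_metabolites > 0) {
    sprintf("MET%04d", seq_len(p$n_metabolites))
  } else character(0)
  met_set_idx <- rep(NA_integer_, p$n_metabolites)
  if (p$n_metabolites > 0) {
    n_assigned <- floor(p$n_metabolites * 0.75)
    met_set_idx[sample.int(p$n_metabolites, n_assigned)] <-
      sample.int(p$n_hallmarks, n_assigned, replace = TRUE)
    met <- sim_block(met_ids, "metabolite", 3, 1.5, p$methods[2], met_set_idx)
    conc <- 2^met$log2
    lod <- stats::quantile(conc, 0.05)
    status <- matrix("valid", nrow(conc), ncol(conc), dimnames = dimnames(conc))
    status[conc < lod] <- "below_limit"
    status[matrix(stats::runif(length(conc)) < 0.02, nrow = nrow(conc))] <- "missing"
    conc[status == "missing"] <- NA
    colnames(conc) <- sub("_[^_]+$", "_met", colnames(conc))
    colnames(status) <- colnames(conc)
    metabolites <- feature_matrix(conc, feature_kind = "metabolite")
    quality <- quality_matrix(status)
  } else {
    met <- list(effect = numeric(0), is_de = logical(0))
    metabolites <- NULL
    quality <- NULL
  }

  ann <- dplyr::bind_rows(
    tidyr::expand_grid(method = p$methods, subject_id = subjects,
                       condition = p$conditions) |>
      dplyr::mutate(
        sample_id = paste(.data$subject_id, .data$condition,
                          gsub("[^A-Za-z0-9]", "", .data$method), sep = "_"),
        matrix_type = "fresh-frozen"
      ),
    if (p$n_metabolites > 0) {
      tidyr::expand_grid(subject_id = subjects, condition = p$conditions) |>
        dplyr::mutate(
          sample_id = paste(.data$subject_id, .data$condition, "met", sep = "_"),
          method = p$methods[2], matrix_type = "fresh-frozen"
        )
    }
  )
  annotation <- sample_annotation(ann)

  # planted hallmark sets partition the protein panel; 75% of the
  # metabolite panel joins them (the rest maps to no pathway)
  hallmarks <- dplyr::bind_rows(
    tibble::tibble(set_name = set_names[prot_set_idx], member = prot_ids,
                   member_type = "gene"),
    if (p$n_metabolites > 0) {
      keep <- !is.na(met_set_idx)
      tibble::tibble(set_name = set_names[met_set_idx[keep]],
                     member = met_ids[keep], member_type = "metabolite")
    }
  ) |>
    dplyr::arrange(.data$set_name, .data$member_type, .data$member)

  truth_features <- tibble::tibble(
    feature_id = c(prot_ids, met_ids),
    feature_kind = c(rep("protein", p$n_proteins),
                     rep("metabolite", p$n_metabolites)),
    true_effect = c(prot$effect, met$effect),
    is_de = c(prot$is_de, met$is_de)
  )
  structure(
    list(
      proteins = proteins, metabolites = metabolites, quality = quality,
      annotation = annotation,
      truth = list(features = truth_features, hallmarks = hallmarks,
                   bottleneck_enzyme = NA_character_),
      params = p
    ),
    class = "cohort_sim"
  )
}

#' Simulate technical replicate sets for two methods
#'
#' Two groups of technical replicates around shared per-feature means,
#' used for CV and between-method correlation checks.
#'
#' @param n_rep replicates per method (>= 2).
#' @param n_features panel size.
#' @param methods two method labels.
#' @param noise_sd replicate log2 noise sd.
#' @param method_offset_sd sd of per-feature method offsets (0 = methods
#'   identical up to noise).
#' @param seed integer seed.
#' @return List: `matrix` (raw-scale [feature_matrix()]), `annotation`.
#' @export
simulate_replicate_sets <- function(n_rep, n_features = 1000,
                                    methods = c("autoSP3", "MTBE-SP3"),
                                    noise_sd = 0.1, method_offset_sd = 0,
                                    seed = 1L) {
  if (n_rep < 2) stop("need at least 2 replicates per method", call. = FALSE)
  local_rng(seed)
  ids <- sprintf("PROT%04d", seq_len(n_features))
  baseline <- stats::rnorm(n_features, 25, 2)
  offsets <- matrix(stats::rnorm(n_features * 2, 0, method_offset_sd),
                    ncol = 2)
  cols <- list()
  for (m_i in 1:2) {
    for (r in seq_len(n_rep)) {
      nm <- paste0(gsub("[^A-Za-z0-9]", "", methods[m_i]), "_rep", r)
      cols[[nm]] <- baseline + offsets[, m_i] +
        stats::rnorm(n_features, 0, noise_sd)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- ids
  ann <- sample_annotation(tibble::tibble(
    sample_id = colnames(x),
    subject_id = "pool",
    condition = "replicate",
    method = rep(methods, each = n_rep),
    matrix_type = "cells"
  ))
  list(matrix = feature_matrix(2^x, feature_kind = "protein"),
       annotation = ann)
}

#' Simulate peptide sequences
#'
#' Random sequences over the 20 standard amino acids, optionally biased
#' toward hydrophobic or basic residues so that physico-chemical
#' association tests have signal to find.
#'
#' @param n number of sequences (0 gives an empty tibble).
#' @param length_range inclusive (min, max) length, both >= 1.
#' @param bias `"none"`, `"hydrophobic"` (up-weights A, C, F, I, L, M, V)
#'   or `"basic"` (up-weights H, K, R).
#' @param bias_strength multiplicative weight applied to favoured
#'   residues.
#' @param seed integer seed.
#' @return Tibble with columns `id`, `sequence`.
#' @export
simulate_sequences <- function(n, length_range = c(5, 50),
                               bias = c("none", "hydrophobic", "basic"),
                               bias_strength = 3, seed = 1L) {
  bias <- match.arg(bias)
  stopifnot(n >= 0, length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  if (n == 0) return(tibble::tibble(id = character(), sequence = character()))
  local_rng(seed)
  w <- stats::setNames(rep(1, 20), AA20)
  if (bias == "hydrophobic") {
    w[c("A", "C", "F", "I", "L", "M", "V")] <- bias_strength
  } else if (bias == "basic") {
    w[c("H", "K", "R")] <- bias_strength
  }
  len_choices <- seq.int(length_range[1], length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE, prob = w / sum(w)), collapse = "")
  }, character(1))
  tibble::tibble(id = sprintf("PEP%04d", seq_len(n)), sequence = seqs)
}

#' Simulate a linear reaction chain with a planted bottleneck
#'
#' Builds the toy analogue of a TCA-cycle-like chain
#' M1 -> E1 -> M2 -> E2 -> ... and assigns metabolite t-values that are
#' negative upstream of the planted bottleneck enzyme (substrates
#' accumulate less... are depleted) and positive downstream, so the
#' bottleneck enzyme must attain the maximal imbalance score.
#'
#' @param n_linear number of metabolites in the chain (>= 3); enzymes
#'   number `n_linear - 1`.
#' @param bottleneck_index which enzyme (1-based) is the bottleneck.
#' @param t_magnitude absolute t-value planted on each metabolite.
#' @param jitter_sd sd of seeded jitter added to the planted t-values.
#' @param seed integer seed.
#' @return List: `network` ([reaction_network()]), `metabolite_t` tibble
#'   (`feature_id`, `t`), `truth` (list with `bottleneck_enzyme`).
#' @export
simulate_network_truth <- function(n_linear = 5, bottleneck_index = 2,
                                   t_magnitude = 2, jitter_sd = 0,
                                   seed = 1L) {
  if (n_linear < 3) stop("chain needs at least 3 metabolites", call. = FALSE)
  n_enz <- n_linear - 1
  if (bottleneck_index < 1 || bottleneck_index > n_enz) {
    stop("bottleneck_index out of range 1..", n_enz, call. = FALSE)
  }
  local_rng(seed)
  mets <- sprintf("M%d", seq_len(n_linear))
  enzs <- sprintf("E%d", seq_len(n_enz))
  edges <- dplyr::bind_rows(
    tibble::tibble(source = mets[-n_linear], target = enzs,
                   reaction_id = sprintf("R%d", seq_len(n_enz)),
                   reverse = FALSE),
    tibble::tibble(source = enzs, target = mets[-1],
                   reaction_id = sprintf("R%d", seq_len(n_enz)),
                   reverse = FALSE)
  )
  net <- reaction_network(
    edges,
    node_types = stats::setNames(
      c(rep("metabolite", n_linear), rep("enzyme", n_enz)), c(mets, enzs)
    )
  )
  t_vals <- ifelse(seq_len(n_linear) <= bottleneck_index,
                   -t_magnitude, t_magnitude)
  if (jitter_sd > 0) t_vals <- t_vals + stats::rnorm(n_linear, 0, jitter_sd)
  list(
    network = net,
    metabolite_t = tibble::tibble(feature_id = mets, t = t_vals),
    truth = list(bottleneck_enzyme = enzs[bottleneck_index])
  )
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits the TSV inputs (protein and metabolite matrices, quality matrix,
#' annotation) plus a JSON ground-truth record, i.e. everything the
#' analysis side of the package reads.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(sim$proteins, file.path(dir, "proteins.tsv"))
  if (!is.null(sim$metabolites)) {
    write_feature_matrix(sim$metabolites, file.path(dir, "metabolites.tsv"))
    write_quality_matrix(sim$quality, file.path(dir, "metabolite_quality.tsv"))
  }
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(
    list(
      seed = sim$params$seed,
      features = sim$truth$features,
      hallmarks = sim$truth$hallmarks,
      bottleneck_enzyme = sim$truth$bottleneck_enzyme
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
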