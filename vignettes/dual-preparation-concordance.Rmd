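---
title: "Assessing concordance of dual sample-preparation proteo-metabolomics workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing concordance of dual sample-preparation proteo-metabolomics workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(duomics)
library(dplyr)
```

## The problem

When a biphasic extraction protocol yields both a metabolite fraction and
a protein pellet from a single tissue aliquot, the practical question is
whether the proteome quantified from that pellet is interchangeable with
the proteome obtained by the established single-purpose protocol. duomics
implements the computational side of that comparison: quality filtering,
blocked differential abundance with empirical-Bayes moderation,
physico-chemical bias diagnostics, set-overlap and concordance
statistics, mixed gene + metabolite pathway enrichment, and
enzyme-centred metabolic-imbalance scoring — plus a synthetic-cohort
generator with planted ground truth so each stage can be validated
without any external download.

## Data model and filtering rules

A `feature_matrix` carries a features-by-samples numeric matrix with an
explicit missing-value mask (`NA`), never zero-imputation: in label-free
proteomics a missing value means "not quantified", not "absent", and
silently coding it as zero biases every downstream estimate. Raw LFQ
intensities are log2-transformed (`log_transform()`), so coefficients
read directly as log2 fold changes.

Three filtering rules operate before modelling:

* **Completeness** (`filter_completeness()`): a feature is kept only if
  quantified in *strictly more than* `min_fraction` of samples (default
  0.5). The strict inequality matters: on a 35-sample cohort it puts the
  smallest passing count at 18.
* **Metabolite validity** (`filter_metabolite_validity()`): targeted
  metabolomics panels report a per-cell quality status; a metabolite is
  kept when at least 2/3 of its cells are `valid` (inclusive, so 6 of 9
  passes).
* **Sample QC** (`qc_flag_samples()`): low-quality samples show elevated
  missingness and shifted median intensity. The package operationalises
  this visual criterion as two robust-z rules with multiplier `k = 3` and
  a normal-consistent MAD (1.4826). The multiplier is a documented
  convention — interactive QC reports no threshold — and `k` is exposed
  in `analysis_config()`.

## Blocked differential abundance with moderated statistics

Per feature, ordinary least squares is fitted on the observed entries
(row-wise deletion; no imputation), with one coefficient per
condition-method cell and subject block columns. Subject fixed effects
stand in for a consensus intra-block correlation model: for complete
paired layouts the two give identical contrast estimates, and the fixed
effect version is deterministic and closed-form. When a feature misses
every sample of a subject, that subject's block column is dropped for
that feature rather than discarding the feature; features that cannot
identify the contrast or have no residual degrees of freedom are flagged
and excluded from moderation.

Residual variances are shrunk toward a scaled inverse-chi-square prior
estimated by method of moments on log variances: the excess of the
empirical log-variance dispersion over the expected chi-square sampling
dispersion (trigamma terms) identifies the prior degrees of freedom
`d0` by monotone root-finding, and the offset-corrected mean identifies
`s0^2`. When no excess dispersion remains, `d0 = Inf`; exactly equal
variances return their common value, otherwise the bias-corrected
geometric mean is used (the correction is what keeps the type-I level at
alpha — the raw geometric mean of chi-square draws is biased low by the
digamma offset). The moderated statistic

$$ t_g = \frac{c^T\hat\beta_g}{\tilde s_g\sqrt{c^T(X^TX)^{-1}c}},
\qquad \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g} $$

is referred to Student-t with `d0 + dg` degrees of freedom (normal when
`d0 = Inf`; exactly the classical t when `d0 = 0`). A unit test checks
the whole pipeline against limma on dispersed-variance data.

P-values are BH-adjusted with missing entries excluded from the test
count. Concordance between two methods is summarised by the Spearman
correlation of matched t-values, UpSet-style overlap counts (the
"percent shared" statistic is the largest disjoint intersection cell over
the union), and a rank-sum comparison of fold-change magnitudes between
shared and method-unique significant sets. The rank-sum p-value uses the
continuity-corrected normal approximation with tie-corrected variance —
the field's default. A known limitation: against exhaustive enumeration
the approximation is within 0.02 only once both groups have at least 5
observations; at 2 vs 2 the worst-case discrepancy reaches 0.088. The
intended use (hundreds of proteins per group) is far inside the safe
regime.

`random_split_test()` provides the negative control: within one method's
samples, a random split balanced within tissue condition should yield no
BH-significant features when the cohort is homogeneous.

## Physico-chemical bias diagnostics

Extraction chemistry can discriminate by hydrophobicity or charge, so
per-sequence GRAVY (mean Kyte-Doolittle hydropathy) and isoelectric
point are correlated (Spearman, t-approximation p) against differential
t-values. The pI solver bisects the Henderson-Hasselbalch net-charge
function on [0, 14] — strictly decreasing, so the root is unique — to a
bracket tolerance of 1e-4 pH, using the packaged IPC_protein pKa set for
the nine ionizable groups. Cysteine is treated as a free thiol, and
non-standard letters (B, Z, X, U) are rejected rather than skipped:
silently dropping residues would distort exactly the composition
statistics the diagnostic is about.

## Mixed-ontology enrichment

Metabolites inherit the pathway memberships of their directly adjacent
enzymes in a bipartite reactant → enzyme → product reaction network
(`transfer_hallmarks()`); direct adjacency is the narrowest reading of
"associated according to the reaction network" and is the implemented
one. Per-patient log2 fold changes are z-scored across patients and
scored per set with an unweighted sum, normalised against an empirical
permutation null (`B = 1000` by default, seeded; features are sorted by
id before permutation so input order is irrelevant). The normalised
score is the number of null standard deviations from the null mean —
note this is invariant to whether the raw statistic is a sum or a mean.
Sets whose null is degenerate score 0 if their members' values are
constant, and are flagged undefined when the set spans the whole
measured universe. Three data configurations are compared between
methods: proteins only, integrated proteins + metabolites, and the
element-wise average of separate modality scores (a set measured in only
one modality keeps that modality's score, preserving coverage).

## Metabolic imbalance scoring

For each reaction an enzyme catalyses, a breadth-first traversal
collects metabolites upstream (through reactant edges, against flow) and
downstream (through product edges) with minimal reaction-step distance
`d`, up to `max_depth = 5`, weighting them `p^-(d-1)` with distance
penalty `p = 8`. Each side's score is the weighted mean of measured
metabolite t-values — a mean, not a sum, so hub enzymes are not inflated
— and the reaction's imbalance is downstream minus upstream, negated for
reverse-annotated reactions; an enzyme's score averages its reactions.
A reaction is scored only when both sides have at least one measured
metabolite (`min_branch_length = 1`); nothing constrains the ratio of
the two branch depths. This scoring is a defined surrogate with the
same qualitative contract as published enzyme-footprint methods (a true
bottleneck — substrates depleted, products accumulating, or vice versa —
attains the extreme score); it does not claim numeric equivalence to any
specific implementation.

## The synthetic cohort generator

`simulate_cohort()` emulates a 10-patient paired tumour (TT) / adjacent
normal (NAT) cohort profiled by two extraction methods, with a
405-metabolite panel measured once per tissue sample. The model for a
log2 intensity is

baseline(feature) + tissue state(feature, subject, condition) +
[effect + pathway activity(set, subject)] x 1(TT) +
method offset(feature, method) + noise.

Key choices, made once from the study design the generator emulates:

* `n_proteins = 2000` — desk scale of a ~3000-protein filtered tissue
  proteome; `n_metabolites = 405` matches a post-QC targeted panel.
* `fraction_de = 0.45` — paired tumour/normal tissue really does change
  nearly half the quantified proteome (≈1386/3010 significant in the
  cohort this mirrors); effects are ±|N(1, 0.5)| log2 units.
* `rho_block = 0.8` — the correlation between the two methods'
  measurements of the same tissue sample, consistent with reported
  cross-method technical-replicate R² of 0.80-0.92. The tissue-state
  term is drawn per (feature, subject, condition) and shared across
  methods because both methods profile aliquots of the same piece.
* `pathway_activity_sd = 0.3` — tumour-specific per-(pathway, patient)
  activity shared across methods. Without it, z-scoring across patients
  removes the cohort-level effect and per-patient enrichment scores
  would be pure noise; with it, the per-patient analysis has coherent
  pathway biology to recover. 0.3 log2 units is a modest 30% of the
  mean effect size.
* Missingness is Bernoulli with a logit slope of 0.3 per log2 unit below
  average abundance (`slope = 0` recovers MCAR), stressing the
  completeness filter the way real LFQ data does.

What the generator does **not** emulate: peptide-to-protein inference,
retention-time or spectral artefacts, correlated measurement error
between features, batch effects, and non-normal heavy-tailed noise.
Passing tests therefore demonstrate correctness of the statistical
machinery under its stated model, not robustness to every failure mode
of real acquisitions.

`simulate_network_truth()` builds a linear metabolite-enzyme chain with
a planted bottleneck: t-values negative upstream, positive downstream,
so the bottleneck enzyme provably attains the maximal imbalance — the
property the scoring module is tested against.

## A worked run

```{r workflow, eval = FALSE}
sim <- simulate_cohort(simulation_params(seed = 1))
proteins <- filter_completeness(log_transform(sim$proteins), 0.5)

res <- lapply(c("autoSP3", "MTBE-SP3"), function(mm) {
  keep <- sim$annotation$sample_id[sim$annotation$method == mm &
                                     !grepl("_met$", sim$annotation$sample_id)]
  m <- proteins
  m$values <- m$values[, intersect(colnames(m$values), keep)]
  diff_abundance(m, sim$annotation, c(TT = 1, NAT = -1),
                 terms = "condition")
})
concordance_t(res[[1]], res[[2]])   # Spearman rho ~ 0.90
overlap_sets(setNames(res, c("autoSP3", "MTBE-SP3")))$percent_largest
```

## Numerical conventions and problem sizes

Tolerances: pI bisection bracket 1e-4 pH (checked against a 0.001-pH
grid search); moderation root-finding 1e-10; contrast variances via
Cholesky inverse per missingness pattern. Determinism: every stochastic
step takes an explicit seed, restores the caller's RNG state, and
permutations are drawn over canonically sorted feature positions. The
validation suite uses 2000-feature cohorts, 20-seed error-control
replicates, and B = 1000 permutations — sizes chosen so the planted
structure is recovered with comfortable Monte-Carlo margins while a full
run stays interactive on a laptop.
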