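test_that("cohort simulation is deterministic in the seed and honours fraction_de", {
  p <- simulation_params(n_proteins = 120, n_metabolites = 40, seed = 5)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$proteins$values, s2$proteins$values)
  expect_identical(s1$metabolites$values, s2$metabolites$values)
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_cohort(simulation_params(n_proteins = 120, seed = 6))
  expect_false(identical(s1$proteins$values, s3$proteins$values))

  null <- simulate_cohort(simulation_params(n_proteins = 100, fraction_de = 0,
                                            seed = 2))
  expect_identical(sum(null$truth$features$is_de), 0L)
  expect_true(all(null$truth$features$true_effect == 0))

  expect_error(simulation_params(rho_block = 1), "rho_block")
})

test_that("cohort structure: annotation covers samples, truth covers features, no zero-coded missingness", {
  sim <- simulate_cohort(simulation_params(n_proteins = 150, n_metabolites = 60,
                                           seed = 3))
  expect_setequal(
    c(colnames(sim$proteins$values), colnames(sim$metabolites$values)),
    sim$annotation$sample_id
  )
  expect_setequal(
    sim$truth$features$feature_id,
    c(feature_ids(sim$proteins), feature_ids(sim$metabolites))
  )
  expect_true(all(sim$proteins$values > 0, na.rm = TRUE))
  expect_identical(dim(sim$quality), dim(sim$metabolites))
  # DE indicator matches non-zero effects exactly
  expect_identical(sim$truth$features$is_de,
                   sim$truth$features$true_effect != 0)
})

test_that("naive paired mean differences recover the planted effects", {
  # pathway_activity_sd = 0: patient-level pathway biology is true
  # patient-varying signal, excluded when recovering the cohort effect
  # complete data: the check verifies the planted effects themselves, so
  # the informative-missingness stressor is switched off here
  p <- simulation_params(n_proteins = 800, n_metabolites = 0, noise_sd = 0.1,
                         effect_size_mean = 1, pathway_activity_sd = 0,
                         missing_rate_base = 0, seed = 17)
  sim <- simulate_cohort(p)
  lp <- log_transform(sim$proteins)
  fc <- patient_fold_changes(lp, sim$annotation, method = p$methods[1])
  fc2 <- patient_fold_changes(lp, sim$annotation, method = p$methods[2])
  est <- tapply(c(fc$log2fc, fc2$log2fc),
                c(fc$feature_id, fc2$feature_id),
                mean, na.rm = TRUE)
  tr <- sim$truth$features
  de <- tr[tr$is_de, ]
  err <- abs(est[de$feature_id] - de$true_effect)
  expect_gte(mean(err < 0.2), 0.95)
})

test_that("replicate sets give zero CV at zero noise and calibrated false positives when methods match", {
  rs0 <- simulate_replicate_sets(3, n_features = 50, noise_sd = 0, seed = 1)
  lp <- log_transform(rs0$matrix)
  cvs <- apply(rs0$matrix$values[, 1:3], 1, cv_percent)
  expect_true(all(cvs == 0))
  expect_error(simulate_replicate_sets(1), "at least 2")

  rs <- simulate_replicate_sets(4, n_features = 800, noise_sd = 0.2,
                                method_offset_sd = 0, seed = 9)
  res <- diff_abundance(log_transform(rs$matrix), rs$annotation,
                        contrast = c(replicate_autoSP3 = 1,
                                     `replicate_MTBE-SP3` = -1),
                        block = NULL)
  fp <- mean(res$p.value < 0.05, na.rm = TRUE)
  expect_lt(abs(fp - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("sequence simulation honours length range, seed and composition bias", {
  s5 <- simulate_sequences(30, c(5, 5), seed = 4)
  expect_true(all(nchar(s5$sequence) == 5))
  expect_identical(simulate_sequences(10, seed = 2),
                   simulate_sequences(10, seed = 2))
  expect_identical(nrow(simulate_sequences(0)), 0L)

  plain <- simulate_sequences(150, c(10, 30), bias = "none", seed = 6)
  oily <- simulate_sequences(150, c(10, 30), bias = "hydrophobic", seed = 6)
  basic <- simulate_sequences(150, c(10, 30), bias = "basic", seed = 6)
  expect_gt(mean(vapply(oily$sequence, gravy, numeric(1))),
            mean(vapply(plain$sequence, gravy, numeric(1))))
  expect_gt(mean(vapply(basic$sequence, isoelectric_point, numeric(1))),
            mean(vapply(plain$sequence, isoelectric_point, numeric(1))))
})

test_that("network truth plants sign-separated t-values around the bottleneck", {
  nt <- simulate_network_truth(5, bottleneck_index = 2, t_magnitude = 2)
  expect_true(all(nt$metabolite_t$t[1:2] < 0))
  expect_true(all(nt$metabolite_t$t[3:5] > 0))
  expect_identical(nt$truth$bottleneck_enzyme, "E2")
  # network invariants hold by construction
  expect_s3_class(nt$network, "reaction_network")
  expect_identical(sum(nt$network$nodes$node_type == "enzyme"), 4L)

  flat <- simulate_network_truth(4, 1, t_magnitude = 0)
  expect_true(all(flat$metabolite_t$t == 0))
  expect_error(simulate_network_truth(2, 1), "at least 3")
  expect_error(simulate_network_truth(5, 5), "out of range")
})

test_that("a cohort bundle writes to disk and reads back unchanged", {
  sim <- simulate_cohort(simulation_params(n_proteins = 40, n_metabolites = 15,
                                           seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  prot <- read_feature_matrix(file.path(dir, "proteins.tsv"))
  expect_equal(prot$values, sim$proteins$values)
  qual <- read_quality_matrix(file.path(dir, "metabolite_quality.tsv"))
  expect_identical(qual$statuses, sim$quality$statuses)
  ann <- read_sample_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann$sample_id, sim$annotation$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 13L)
})
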