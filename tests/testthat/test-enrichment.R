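test_that("patient z-scores match hand computation and the normalisation identities", {
  fc <- tidyr::expand_grid(feature_id = c("F1", "F2"),
                           patient_id = paste0("P", 1:4)) |>
    dplyr::mutate(log2fc = c(1, 2, 3, 4, 5, 5, 5, 5))
  z <- zscore_across_patients(fc)
  z1 <- z$z[z$feature_id == "F1"]
  expect_equal(z1, c(-1.161895, -0.3872983, 0.3872983, 1.161895),
               tolerance = 1e-6)
  # constant feature flagged missing
  expect_true(all(is.na(z$z[z$feature_id == "F2"])))
  expect_identical(attr(z, "constant_features"), "F2")
  expect_equal(mean(z1), 0)
  expect_equal(sd(z1), 1)
  expect_error(zscore_across_patients(fc[fc$patient_id == "P1", ]),
               "2 patients")
})

test_that("weighted-mean enrichment: degenerate cases, linearity and order invariance", {
  vals <- stats::setNames(rep(0, 20), sprintf("F%02d", 1:20))
  sets <- list(S1 = sprintf("F%02d", 1:5), ALL = sprintf("F%02d", 1:20))
  e <- wmean_enrichment(vals, sets, B = 200, seed = 1)
  expect_equal(e$raw, c(0, 0))
  # the whole-universe set has a constant permutation null
  expect_true(e$degenerate[e$set_name == "ALL"])
  expect_true(is.na(e$norm[e$set_name == "ALL"]))
  expect_equal(e$norm[e$set_name == "S1"], 0)

  set.seed(3)
  x <- stats::setNames(rnorm(30), sprintf("G%02d", 1:30))
  y <- stats::setNames(rnorm(30), sprintf("G%02d", 1:30))
  sets2 <- list(A = sprintf("G%02d", 3:9), B = sprintf("G%02d", c(1, 20:25)))
  ex <- wmean_enrichment(x, sets2, B = 100, seed = 2)
  ey <- wmean_enrichment(y, sets2, B = 100, seed = 2)
  exy <- wmean_enrichment(2 * x + 5 * y, sets2, B = 100, seed = 2)
  expect_equal(exy$raw, 2 * ex$raw + 5 * ey$raw)

  # permutations are drawn after a canonical id sort: row order irrelevant
  shuffled <- x[sample(length(x))]
  expect_equal(wmean_enrichment(shuffled, sets2, B = 100, seed = 2), ex)

  small <- list(tiny = "G01")
  expect_identical(attr(wmean_enrichment(x, c(sets2, small), B = 100,
                                         seed = 1), "skipped_sets"), "tiny")
  expect_error(wmean_enrichment(x, small, B = 100, seed = 1), "at least 2")
  expect_error(wmean_enrichment(x, sets2, B = 10, seed = 1), "100 permutations")
})

test_that("normalised null scores are calibrated and a planted set is recovered", {
  set.seed(8)
  ids <- sprintf("F%03d", 1:500)
  sets <- split(sample(ids), rep(1:50, each = 10))
  names(sets) <- paste0("S", names(sets))
  vals <- stats::setNames(rnorm(500), ids)
  e <- wmean_enrichment(vals, sets, B = 1000, seed = 4)
  expect_lt(abs(mean(e$norm)), 3 / sqrt(1000) + 3 / sqrt(50))
  expect_gt(sd(e$norm), 0.8)
  expect_lt(sd(e$norm), 1.2)

  planted <- stats::setNames(rnorm(500), ids)
  planted[sets$S7] <- planted[sets$S7] + 2
  ep <- wmean_enrichment(planted, sets, B = 1000, seed = 4)
  expect_identical(ep$set_name[which.max(ep$norm)], "S7")
})

test_that("the three data configurations collapse and average as specified", {
  set.seed(5)
  z <- tidyr::expand_grid(feature_id = sprintf("P%02d", 1:40),
                          patient_id = c("a", "b")) |>
    dplyr::mutate(z = rnorm(80))
  sets <- tibble::tibble(set_name = rep(c("H1", "H2"), each = 10),
                         member = sprintf("P%02d", 1:20),
                         member_type = "gene")
  # no metabolites: all three configurations are the same analysis
  cfg <- run_configurations(z, NULL, sets, B = 100, seed = 9)
  expect_equal(cfg$integrated, cfg$proteins_only)
  expect_equal(cfg$averaged, cfg$proteins_only)
  # determinism under a shared seed
  cfg2 <- run_configurations(z, NULL, sets, B = 100, seed = 9)
  expect_equal(cfg, cfg2)

  # all-zero metabolite values halve the averaged score of shared sets
  mz <- tidyr::expand_grid(feature_id = sprintf("M%02d", 1:16),
                           patient_id = c("a", "b")) |>
    dplyr::mutate(z = 0)
  mixed <- dplyr::bind_rows(
    sets,
    tibble::tibble(set_name = "H1", member = sprintf("M%02d", 1:10),
                   member_type = "metabolite")
  )
  cfg3 <- run_configurations(z, mz, sets, mixed_sets = mixed, B = 100,
                             seed = 9)
  h1 <- cfg3$averaged$set_name == "H1"
  expect_equal(cfg3$averaged$norm[h1],
               cfg3$proteins_only$norm[cfg3$proteins_only$set_name == "H1"] / 2)
  # H2 has no metabolite members: averaged keeps the protein score
  expect_equal(cfg3$averaged$norm[!h1],
               cfg3$proteins_only$norm[cfg3$proteins_only$set_name == "H2"])
})

test_that("method comparison returns perfect and inverted correlation for copies", {
  e <- tibble::tibble(
    set_name = rep(paste0("S", 1:6), 2),
    patient_id = rep(c("p1", "p2"), each = 6),
    norm = rnorm(12)
  )
  cmp <- compare_methods(e, e)
  expect_true(all(cmp$per_patient$r == 1))
  expect_equal(cmp$pooled_r, 1)
  flip <- dplyr::mutate(e, norm = -norm)
  expect_true(all(compare_methods(e, flip)$per_patient$r == -1))
  expect_error(compare_methods(e[1:2, ], e[1:2, ]), "3 shared sets")
})

test_that("paired correlation-difference test follows the closed form and its conventions", {
  r1 <- c(0.8, 0.85, 0.9, 0.75)
  same <- test_correlation_difference(r1, r1)
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  expect_identical(same$df, 3)

  d <- c(0.1, -0.1, 0.2, 0)
  res <- test_correlation_difference(r1, r1 - d)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), df = 3))
  expect_error(test_correlation_difference(0.5, numeric(0)), "paired")
  expect_error(test_correlation_difference(0.5, 0.4), "at least 2")
})
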