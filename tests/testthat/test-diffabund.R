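make_two_group <- function(nf = 20, n_per = 4, seed = 1, missing = 0) {
  set.seed(seed)
  x <- matrix(rnorm(nf * 2 * n_per, 20, 1), nf, 2 * n_per,
              dimnames = list(sprintf("F%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(2 * n_per))))
  if (missing > 0) x[runif(length(x)) < missing] <- NA
  ann <- sample_annotation(tibble::tibble(
    sample_id = colnames(x), subject_id = colnames(x),
    condition = rep(c("A", "B"), each = n_per),
    method = "m", matrix_type = "cells"
  ))
  list(m = feature_matrix(x, is_log = TRUE), ann = ann)
}

test_that("per-feature OLS matches the normal-equations oracle, with and without missing data", {
  d <- make_two_group(nf = 30, n_per = 5, seed = 2, missing = 0.15)
  design <- make_design(d$ann, terms = "condition", block = NULL)
  fit <- fit_feature_models(d$m, design)
  for (i in seq_len(30)) {
    obs <- !is.na(d$m$values[i, ])
    if (sum(obs) <= ncol(design)) next
    xo <- design[obs, , drop = FALSE]
    yo <- d$m$values[i, obs]
    beta <- solve(t(xo) %*% xo, t(xo) %*% yo)   # textbook normal equations
    expect_lt(max(abs(fit$coefficients[i, ] - drop(beta))), 1e-10)
    resid <- yo - drop(xo %*% beta)
    expect_equal(fit$sigma2[i],
                 sum(resid^2) / (sum(obs) - ncol(design)))
  }
  # two-group coefficients are group means, so the contrast is their difference
  cmplt <- make_two_group(nf = 10, n_per = 4, seed = 3)
  f2 <- fit_feature_models(cmplt$m, make_design(cmplt$ann, "condition", NULL))
  ga <- rowMeans(cmplt$m$values[, 1:4])
  gb <- rowMeans(cmplt$m$values[, 5:8])
  expect_equal(unname(f2$coefficients[, "A"] - f2$coefficients[, "B"]),
               unname(ga - gb))
})

test_that("saturated fits are flagged with zero residual df and excluded downstream", {
  d <- make_two_group(nf = 8, n_per = 1, seed = 4)
  fit <- fit_feature_models(d$m, make_design(d$ann, "condition", NULL))
  expect_true(all(fit$df_residual == 0))
  expect_false(any(fit$ok))
  expect_error(estimate_moderation(fit$sigma2, fit$df_residual), "at least 10")
})

test_that("rank-deficient designs fail loudly with the aliased coefficients named", {
  d <- make_two_group(nf = 5, n_per = 3, seed = 5)
  design <- make_design(d$ann, terms = "condition", block = NULL)
  design <- cbind(design, dup = design[, "A"])
  expect_error(fit_feature_models(d$m, design), "dup|A")
})

test_that("moderation hyperparameters: homogeneous variances give d0 = Inf, excess dispersion a finite d0, and the prior is recovered", {
  mp <- estimate_moderation(rep(0.3, 50), rep(4, 50))
  expect_identical(mp$d0, Inf)
  expect_equal(mp$s0_sq, 0.3)

  # parameter recovery from the scaled inverse-chi-square prior
  set.seed(42)
  d0 <- 4
  s0 <- 0.05
  dg <- 4
  s2 <- (d0 * s0 / rchisq(5000, d0)) * rchisq(5000, dg) / dg
  mp2 <- estimate_moderation(s2, rep(dg, 5000))
  expect_lt(abs(mp2$d0 - d0) / d0, 0.15)
  expect_lt(abs(mp2$s0_sq - s0) / s0, 0.10)
  expect_lt(mp2$d0, 20)  # heavy dispersion must not collapse to Inf
})

test_that("moderated t reduces to the classical t at d0 = 0 and to a z-test at d0 = Inf", {
  d <- make_two_group(nf = 50, n_per = 5, seed = 7)
  design <- make_design(d$ann, terms = "condition", block = NULL)
  fit <- fit_feature_models(d$m, design)
  contrast <- c(A = 1, B = -1)

  res0 <- moderated_t(fit, contrast, moderation = list(d0 = 0, s0_sq = 1))
  classical <- apply(d$m$values, 1, function(y) {
    unname(stats::t.test(y[1:5], y[6:10], var.equal = TRUE)$statistic)
  })
  expect_lt(max(abs(res0$t - classical)), 1e-10)
  expect_equal(res0$df.total, fit$df_residual)

  s0 <- 0.8
  resI <- moderated_t(fit, contrast, moderation = list(d0 = Inf, s0_sq = s0))
  u <- 1 / 5 + 1 / 5
  expect_equal(resI$t, res0$logFC / sqrt(s0 * u))
  expect_equal(resI$p.value, 2 * pnorm(-abs(resI$t)))
})

test_that("moderated t matches a brute-force reimplementation of the shrinkage formula", {
  d <- make_two_group(nf = 50, n_per = 6, seed = 8, missing = 0.1)
  design <- make_design(d$ann, terms = "condition", block = NULL)
  fit <- fit_feature_models(d$m, design)
  mod <- estimate_moderation(fit$sigma2, fit$df_residual)
  res <- moderated_t(fit, c(A = 1, B = -1), moderation = mod)
  for (i in which(fit$ok)) {
    obs <- !is.na(d$m$values[i, ])
    na <- sum(obs[1:6])
    nb <- sum(obs[7:12])
    beta <- mean(d$m$values[i, obs][seq_len(na)]) -
      mean(d$m$values[i, obs][na + seq_len(nb)])
    s2_post <- (mod$d0 * mod$s0_sq + fit$df_residual[i] * fit$sigma2[i]) /
      (mod$d0 + fit$df_residual[i])
    t_hand <- beta / sqrt(s2_post * (1 / na + 1 / nb))
    expect_lt(abs(res$t[i] - t_hand), 1e-8)
  }
})

test_that("the full moderated pipeline agrees with limma on complete data", {
  skip_if_not_installed("limma")
  d <- make_two_group(nf = 200, n_per = 5, seed = 10)
  # heterogeneous true variances so the finite-d0 branch is exercised
  set.seed(20)
  d$m$values <- d$m$values * exp(rnorm(200, 0, 0.6) / 2)
  design <- make_design(d$ann, terms = "condition", block = NULL)
  fit <- fit_feature_models(d$m, design)
  mod <- estimate_moderation(fit$sigma2, fit$df_residual)
  res <- moderated_t(fit, c(A = 1, B = -1), moderation = mod)

  lfit <- limma::lmFit(d$m$values, design)
  lfit <- limma::contrasts.fit(lfit, c(1, -1))
  lfit <- limma::eBayes(lfit)
  expect_true(is.finite(mod$d0))
  expect_equal(mod$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p.value, unname(lfit$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment matches a brute-force step-up oracle and handles NAs", {
  bh_oracle <- function(p) {
    # O(m^2) literal step-up: for each i, min over j >= rank(i) of p_(j)*m/j
    m <- length(p)
    ord <- order(p)
    out <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(ord == i)
      out[i] <- min(1, min(vapply(r:m, function(j) p[ord[j]] * m / j,
                                  numeric(1))))
    }
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  p_na <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p_na), c(bh_oracle(c(0.01, 0.04))[1], NA,
                                  bh_oracle(c(0.01, 0.04))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank-sum statistic follows the Mann-Whitney convention and its p the corrected normal approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$W, 0)
  x <- c(5, 1, 9, 3)
  expect_equal(wilcoxon_rank_sum(x, x)$W, length(x)^2 / 2)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  # exact-enumeration oracle over all assignments, tie-free cases
  exact_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    na <- length(a)
    w_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
    ws <- apply(utils::combn(n, na), 2, function(idx) {
      sum(rank(pooled)[idx]) - na * (na + 1) / 2
    })
    centre <- na * (n - na) / 2
    mean(abs(ws - centre) >= abs(w_obs - centre))
  }
  # the continuity-corrected normal approximation tracks the exact law
  # closely once both groups reach 5; the worst case over every possible
  # tie-free outcome stays bounded even at the smallest sizes
  set.seed(12)
  for (i in 1:10) {
    na <- sample(5:8, 1)
    nb <- sample(5:8, 1)
    v <- sample(seq_len(60), na + nb)  # distinct values: no ties
    a <- v[seq_len(na)]
    b <- v[na + seq_len(nb)]
    expect_lt(abs(wilcoxon_rank_sum(a, b)$p.value - exact_p(a, b)), 0.02)
  }
  splits <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  worst <- max(vapply(splits, function(a) {
    b <- setdiff(1:4, a)
    abs(wilcoxon_rank_sum(a, b)$p.value - exact_p(a, b))
  }, numeric(1)))
  expect_lt(worst, 0.1)
})

test_that("overlap summaries count intersection cells and the percent-shared statistic", {
  ov <- overlap_sets(list(m1 = c("A", "B", "C"), m2 = c("B", "C", "D")))
  expect_identical(ov$n_union, 4L)
  expect_equal(ov$percent_largest, 50)
  expect_equal(sort(ov$counts$n), c(1L, 1L, 2L))

  same <- overlap_sets(list(m1 = c("A", "B"), m2 = c("A", "B")))
  expect_equal(same$percent_largest, 100)

  none <- overlap_sets(list(m1 = character(0), m2 = character(0)))
  expect_identical(none$n_union, 0L)
  expect_identical(nrow(none$membership), 0L)
})

test_that("t-value concordance behaves as a correlation on matched features", {
  res <- tibble::tibble(feature_id = sprintf("F%02d", 1:20),
                        t = rnorm(20))
  class(res) <- c("diff_result", class(res))
  expect_equal(concordance_t(res, res)$estimate, 1)
  neg <- res
  neg$t <- -neg$t
  expect_equal(concordance_t(res, neg)$estimate, -1)
  expect_error(concordance_t(res[1:3, ], res[1:3, ]), "4 shared")
})

test_that("random splits are balanced within condition, seed-stable, and quiet under the null", {
  sim <- simulate_cohort(simulation_params(n_proteins = 300, n_metabolites = 0,
                                           fraction_de = 0.4, seed = 19))
  lp <- log_transform(sim$proteins)
  m1 <- method_subset(lp, sim$annotation, "autoSP3")
  r1 <- random_split_test(m1, sim$annotation, seed = 3)
  r2 <- random_split_test(m1, sim$annotation, seed = 3)
  expect_identical(attr(r1, "split"), attr(r2, "split"))
  split <- attr(r1, "split")
  ann <- sim$annotation[match(names(split), sim$annotation$sample_id), ]
  for (cond in unique(ann$condition)) {
    sizes <- table(split[ann$condition == cond])
    expect_lte(abs(diff(range(sizes))), 1)
  }
  # planted TT/NAT biology is orthogonal to a random split: nothing survives BH
  counts <- vapply(1:5, function(s) {
    sum(random_split_test(m1, sim$annotation, seed = s)$adj.p.value < 0.05,
        na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(counts), 1)
})

test_that("hypergeometric over-representation matches the combinatorial form", {
  # C(5,4)*C(5,0)/C(10,4) = 5/210
  res <- ora_hypergeometric(letters[1:4], letters[1:10],
                            list(S = letters[1:5]))
  expect_equal(res$p.value, 5 / 210)

  res0 <- ora_hypergeometric(character(0), letters[1:10],
                             list(S = letters[1:5]))
  expect_equal(res0$p.value, 1)
  expect_identical(res0$overlap, 0L)

  full <- ora_hypergeometric(letters[1:4], letters[1:10],
                             list(S = letters[1:10]))
  expect_equal(full$p.value, 1)

  expect_error(ora_hypergeometric(c("a", "zz"), letters[1:10], list(S = "a")),
               "outside the universe")
})
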