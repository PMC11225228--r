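#' Build a design matrix from sample annotation
#'
#' Constructs the design used for blocked differential abundance:
#' one coefficient per condition-method cell (no intercept, so contrasts
#' read directly as cell differences) plus, optionally, subject block
#' columns. Subject fixed effects reproduce the paired-contrast estimates
#' of a consensus-correlation mixed model exactly for complete paired
#' layouts.
#'
#' @param annotation a [sample_annotation()] tibble.
#' @param terms character vector of annotation columns to cross into cell
#'   coefficients (default `c("condition", "method")`).
#' @param block annotation column used as blocking factor (default
#'   `"subject_id"`); `NULL` for no blocking.
#' @return Numeric design matrix, rows in annotation order (rownames are
#'   sample ids).
#' @export
make_design <- function(annotation, terms = c("condition", "method"),
                        block = "subject_id") {
  stopifnot(all(terms %in% names(annotation)))
  cell <- interaction(annotation[terms], sep = "_", drop = TRUE, lex.order = TRUE)
  x <- stats::model.matrix(~ 0 + cell)
  colnames(x) <- levels(cell)
  if (!is.null(block)) {
    b <- factor(annotation[[block]])
    if (nlevels(b) > 1) {
      xb <- stats::model.matrix(~ b)[, -1, drop = FALSE]
      colnames(xb) <- paste0("block_", levels(b)[-1])
      x <- cbind(x, xb)
    }
  }
  rownames(x) <- annotation$sample_id
  if (qr(x)$rank < ncol(x)) {
    keep <- qr(x)$pivot[seq_len(qr(x)$rank)]
    stop("design matrix is rank deficient; aliased coefficients: ",
         paste(colnames(x)[-keep], collapse = ", "), call. = FALSE)
  }
  x
}

#' Per-feature least-squares fits
#'
#' Fits ordinary least squares to every feature on its observed entries
#' (row-wise deletion of missing values, the standard treatment for LFQ
#' data — no imputation). Features whose observed samples leave no
#' residual degrees of freedom, or that cannot identify all coefficients,
#' are flagged and excluded from downstream moderation.
#'
#' @param m a log-scale [feature_matrix()].
#' @param design design matrix from [make_design()]; rows must cover the
#'   matrix's samples.
#' @return An object of class `feature_fit`: per-feature coefficients,
#'   residual variances `sigma2`, residual df, and the unscaled
#'   coefficient covariance per missingness pattern.
#' @export
fit_feature_models <- function(m, design) {
  stopifnot(inherits(m, "feature_matrix"))
  if (!m$is_log) stop("fit requires a log-scale matrix", call. = FALSE)
  if (is.null(rownames(design))) stop("design needs sample rownames", call. = FALSE)
  miss <- setdiff(sample_ids(m), rownames(design))
  if (length(miss) > 0) {
    stop("samples missing from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x_full <- design[sample_ids(m), , drop = FALSE]
  if (qr(x_full)$rank < ncol(x_full)) {
    qrf <- qr(x_full)
    stop("design matrix is rank deficient; aliased coefficients: ",
         paste(colnames(x_full)[-qrf$pivot[seq_len(qrf$rank)]], collapse = ", "),
         call. = FALSE)
  }
  y <- m$values
  p <- ncol(x_full)
  nfeat <- nrow(y)
  obs <- !is.na(y)
  # group features sharing a missingness pattern: one QR per pattern
  pat_key <- apply(obs, 1, function(z) rawToChar(as.raw(as.integer(z) + 48L)))
  coefficients <- matrix(NA_real_, nfeat, p,
                         dimnames = list(rownames(y), colnames(x_full)))
  sigma2 <- rep(NA_real_, nfeat)
  df_residual <- rep(0, nfeat)
  ok <- rep(FALSE, nfeat)
  pattern_id <- rep(NA_integer_, nfeat)
  xtxinv <- list()
  groups <- split(seq_len(nfeat), pat_key)
  pid <- 0L
  kept_cols <- list()
  for (idx in groups) {
    sel <- obs[idx[1], ]
    nobs <- sum(sel)
    if (nobs == 0) next
    xs <- x_full[sel, , drop = FALSE]
    # block levels with no observed sample contribute an empty column;
    # drop them so the remaining coefficients stay estimable
    keep <- colSums(abs(xs)) > 0
    xs <- xs[, keep, drop = FALSE]
    pk <- ncol(xs)
    if (nobs < pk || qr(xs)$rank < pk) next  # genuinely aliased
    pid <- pid + 1L
    fit <- stats::lm.fit(xs, t(y[idx, sel, drop = FALSE]))
    cf <- t(as.matrix(fit$coefficients))
    res <- t(as.matrix(fit$residuals))
    coefficients[idx, keep] <- cf
    dfr <- nobs - pk
    df_residual[idx] <- dfr
    if (dfr > 0) sigma2[idx] <- rowSums(res^2) / dfr
    ok[idx] <- dfr > 0
    pattern_id[idx] <- pid
    xtxinv[[pid]] <- chol2inv(chol(crossprod(xs)))
    kept_cols[[pid]] <- which(keep)
  }
  structure(
    list(
      coefficients = coefficients, sigma2 = sigma2,
      df_residual = df_residual, ok = ok,
      pattern_id = pattern_id, xtxinv = xtxinv, kept_cols = kept_cols,
      design_colnames = colnames(x_full), n_samples = ncol(y)
    ),
    class = "feature_fit"
  )
}

#' Empirical-Bayes variance moderation hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of a scaled inverse-chi-square prior on the residual variances, by
#' method of moments on log variances: the empirical variance of
#' `log(s_g^2)` in excess of the expected chi-square sampling variance
#' (trigamma terms) identifies `d0` via monotone root-finding, and the
#' mean identifies `s0_sq` after digamma/log offsets. When the variances
#' are no more dispersed than sampling alone explains, `d0` is infinite
#' and all features share `s0_sq`.
#'
#' @param sigma2 per-feature residual variances.
#' @param df_residual matching residual degrees of freedom.
#' @return List of class `moderation_params` with elements `d0`, `s0_sq`,
#'   and `n_used`.
#' @export
estimate_moderation <- function(sigma2, df_residual) {
  use <- !is.na(sigma2) & df_residual > 0 & sigma2 > 0
  if (sum(use) < 10) {
    stop("need at least 10 features with positive residual df", call. = FALSE)
  }
  s2 <- sigma2[use]
  d <- df_residual[use]
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2 * n / (n - 1)) - mean(trigamma(d / 2))
  if (excess <= 0) {
    # no dispersion beyond sampling noise; exactly equal variances keep
    # their common value, otherwise the bias-corrected geometric mean
    s0_sq <- if (stats::var(z) < 1e-12) exp(mean(z)) else exp(ebar)
    out <- list(d0 = Inf, s0_sq = s0_sq, n_used = n)
  } else {
    # trigamma is strictly decreasing: solve trigamma(d0/2) = excess
    f <- function(x) trigamma(x) - excess
    lower <- 1e-8
    upper <- 10
    while (f(upper) > 0) upper <- upper * 2
    half_d0 <- stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
    d0 <- 2 * half_d0
    out <- list(
      d0 = d0,
      s0_sq = exp(ebar + digamma(half_d0) - log(half_d0)),
      n_used = n
    )
  }
  structure(out, class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("<moderation_params> d0 = %s, s0^2 = %.4g (n = %d)\n",
              format(x$d0, digits = 4), x$s0_sq, x$n_used))
  invisible(x)
}

#' Moderated t-statistics for a contrast
#'
#' Shrinks each feature's residual variance toward the prior,
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and tests the contrast with
#' \eqn{t = c^T\hat\beta / (\tilde s_g \sqrt{c^T (X^TX)^{-1} c})} against a
#' Student-t reference with `d0 + d_g` degrees of freedom (normal when
#' `d0` is infinite; the classical t when `d0 = 0`).
#'
#' @param fit a [fit_feature_models()] result.
#' @param contrast named numeric vector of weights over design
#'   coefficients (unnamed coefficients get weight 0), or a single
#'   coefficient name.
#' @param moderation a [estimate_moderation()] result, or a list with
#'   `d0` and `s0_sq` (use `d0 = 0` for unmoderated classical t).
#' @param alpha significance level recorded for convenience filtering.
#' @return Tibble of class `diff_result`: `feature_id`, `logFC`, `t`,
#'   `p.value`, `adj.p.value`, `df.residual`, `df.total`, `ok`.
#' @export
moderated_t <- function(fit, contrast, moderation = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "feature_fit"))
  cn <- fit$design_colnames
  if (is.character(contrast)) {
    contrast <- stats::setNames(1, contrast)
  }
  bad <- setdiff(names(contrast), cn)
  if (length(bad) > 0) {
    stop("contrast names not in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cvec <- stats::setNames(rep(0, length(cn)), cn)
  cvec[names(contrast)] <- contrast
  if (is.null(moderation)) {
    moderation <- estimate_moderation(fit$sigma2, fit$df_residual)
  }
  d0 <- moderation$d0
  s0_sq <- moderation$s0_sq
  stopifnot(d0 >= 0, is.null(s0_sq) || s0_sq > 0 || d0 == 0)

  active <- which(cvec != 0)
  # per pattern: contrast variance if every contrasted coefficient was
  # estimable for that pattern, NA otherwise
  cuc <- vapply(seq_along(fit$xtxinv), function(i) {
    kc <- fit$kept_cols[[i]]
    if (!all(active %in% kc)) return(NA_real_)
    cv <- cvec[kc]
    drop(crossprod(cv, fit$xtxinv[[i]] %*% cv))
  }, numeric(1))
  cf0 <- fit$coefficients
  cf0[is.na(cf0)] <- 0
  logfc <- drop(cf0 %*% cvec)
  logfc[rowSums(is.na(fit$coefficients[, active, drop = FALSE])) > 0] <- NA
  u <- rep(NA_real_, length(logfc))
  has_pat <- !is.na(fit$pattern_id)
  u[has_pat] <- cuc[fit$pattern_id[has_pat]]

  dg <- fit$df_residual
  s2 <- fit$sigma2
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- dg
  } else {
    s2_post <- (d0 * s0_sq + dg * ifelse(dg > 0, s2, 0)) / (d0 + dg)
    df_total <- d0 + dg
  }
  tt <- logfc / sqrt(s2_post * u)
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(tt), df = df_total),
              2 * stats::pnorm(-abs(tt)))
  usable <- !is.na(tt)
  out <- tibble::tibble(
    feature_id = rownames(fit$coefficients),
    logFC = unname(logfc),
    t = unname(tt),
    p.value = unname(p),
    adj.p.value = bh_adjust(unname(p)),
    df.residual = unname(dg),
    df.total = unname(df_total),
    ok = unname(usable)
  )
  attr(out, "contrast") <- cvec
  attr(out, "moderation") <- moderation
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_result", class(out))
  out
}

#' One-call blocked differential abundance
#'
#' Convenience pipeline: build the design, fit per-feature models,
#' estimate moderation, and test a contrast.
#'
#' @inheritParams fit_feature_models
#' @param annotation a [sample_annotation()] covering the matrix samples.
#' @param contrast named weight vector over condition-method cell names
#'   (see [make_design()] for naming: `condition_method`).
#' @param terms,block passed to [make_design()].
#' @param alpha significance level.
#' @return A `diff_result` tibble (see [moderated_t()]).
#' @export
diff_abundance <- function(m, annotation, contrast,
                           terms = c("condition", "method"),
                           block = "subject_id", alpha = 0.05) {
  check_annotation_covers(m, annotation)
  ann <- annotation[match(sample_ids(m), annotation$sample_id), ]
  design <- make_design(ann, terms = terms, block = block)
  fit <- fit_feature_models(m, design)
  moderated_t(fit, contrast, alpha = alpha)
}
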