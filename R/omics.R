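#' Internal-standard normalization of peak areas
#'
#' Each analyte's integrated peak area is divided by the area of its
#' pre-assigned internal standard in the same sample and the ratio is log2
#' transformed. Missing areas propagate as `NA`.
#'
#' @param peak_areas analyte x sample matrix of integrated peak areas
#'   (positive; `NA` allowed).
#' @param standard_areas standard x sample matrix of internal-standard
#'   areas (strictly positive everywhere).
#' @param standard_map tibble mapping `feature` to `standard` (rownames of
#'   `standard_areas`); defaults to a single shared standard when
#'   `standard_areas` has one row.
#' @return analyte x sample matrix of log2 ratios.
#' @export
normalize_internal_standard <- function(peak_areas, standard_areas,
                                        standard_map = NULL) {
  if (is.null(standard_map)) {
    if (nrow(standard_areas) != 1) {
      abort("supply `standard_map` when there are several standards")
    }
    standard_map <- tibble(feature = rownames(peak_areas),
                           standard = rownames(standard_areas)[1])
  }
  idx <- match(standard_map$standard[match(rownames(peak_areas),
                                           standard_map$feature)],
               rownames(standard_areas))
  if (anyNA(idx)) abort("every feature must map to a known standard")
  std <- standard_areas[idx, , drop = FALSE]
  if (any(!is.finite(std)) || any(std <= 0)) {
    abort("internal-standard areas must be positive in every sample")
  }
  out <- log2(peak_areas / std)
  dimnames(out) <- dimnames(peak_areas)
  out
}

#' Remove analytes detected in too few samples
#'
#' A feature is removed iff it is detected (non-missing) in strictly less
#' than `min_frac` of the samples; a feature detected in exactly 75% of
#' samples is kept under the default.
#'
#' @param m feature x sample matrix (NA = not detected).
#' @param min_frac minimum detected fraction (default 0.75).
#' @return the filtered matrix.
#' @export
filter_detection <- function(m, min_frac = 0.75) {
  frac <- rowMeans(!is.na(m))
  m[frac >= min_frac, , drop = FALSE]
}

#' Median scaling of log2 abundances
#'
#' Subtracts each sample's median over observed values, so every sample's
#' post-scaling median is 0.
#'
#' @param m feature x sample matrix of log2 abundances.
#' @return the scaled matrix.
#' @export
median_scale <- function(m) {
  med <- apply(m, 2, median, na.rm = TRUE)
  sweep(m, 2, med)
}

#' Remove lowly expressed genes from a count matrix
#'
#' A gene is kept iff it has strictly more than `min_reads` reads in at
#' least `min_samples` samples (the minimum replicate size of the
#' experiment); exactly `min_reads` reads do not count toward the
#' requirement.
#'
#' @param counts gene x sample count matrix.
#' @param min_samples minimum replicate size.
#' @param min_reads read threshold (default 10, strict).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_samples, min_reads = 10) {
  keep <- rowSums(counts > min_reads) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Per-feature ordinary least squares with a named contrast coefficient
#'
#' Fits `log2(abundance) ~ covariates` independently for every feature on
#' its complete observations (per-feature complete-case) and extracts one
#' coefficient of interest (the condition effect, i.e. the log2 fold
#' change). Features with fewer residual degrees of freedom than `min_df`
#' are skipped with a recorded reason. Rank-deficient designs raise an
#' error naming the collinear columns.
#'
#' @param m feature x sample matrix of log2 abundances (NA allowed).
#' @param metadata tibble of sample covariates, rows aligned with the
#'   columns of `m`.
#' @param formula right-hand-side formula of covariates, e.g.
#'   `~ genotype + batch + sex`.
#' @param coef name of the design-matrix column whose coefficient is the
#'   effect of interest; defaults to the first non-intercept column.
#' @param min_df minimum residual degrees of freedom (default 3).
#' @param design optional explicit design matrix (overrides `metadata` +
#'   `formula`).
#' @return a list of class `feature_fits`: per-feature `coefficients`
#'   (log2fc), `stdev_unscaled`, `sigma2`, `df_residual`, `skipped`
#'   (logical with reasons), plus the resolved `coef` name.
#' @export
fit_linear_model <- function(m, metadata = NULL, formula = ~ genotype,
                             coef = NULL, min_df = 3, design = NULL) {
  X <- design %||% stats::model.matrix(formula, data = metadata)
  if (nrow(X) != ncol(m)) {
    abort("metadata rows must match matrix columns (no missing covariates)")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  coef <- coef %||% colnames(X)[min(2L, ncol(X))]
  if (!coef %in% colnames(X)) {
    abort(sprintf("coefficient '%s' is not a design column (%s)", coef,
                  paste(colnames(X), collapse = ", ")))
  }
  j <- match(coef, colnames(X))
  p <- ncol(X)
  nf <- nrow(m)
  beta <- se_unscaled <- sigma2 <- rep(NA_real_, nf)
  dfres <- rep(NA_real_, nf)
  skipped <- rep(NA_character_, nf)

  complete <- !is.na(m)
  all_obs <- rowSums(!complete) == 0
  # fast path: features observed in every sample share one decomposition
  if (any(all_obs)) {
    XtXinv <- chol2inv(qr.R(qrX))
    Y <- t(m[all_obs, , drop = FALSE])
    B <- qr.coef(qrX, Y)
    res <- Y - X %*% B
    dfr <- nrow(X) - p
    beta[all_obs] <- B[j, ]
    se_unscaled[all_obs] <- sqrt(XtXinv[j, j])
    sigma2[all_obs] <- colSums(res^2) / dfr
    dfres[all_obs] <- dfr
  }
  for (f in which(!all_obs)) {
    ok <- complete[f, ]
    Xf <- X[ok, , drop = FALSE]
    dfr <- sum(ok) - p
    if (dfr < min_df || qr(Xf)$rank < p) {
      skipped[f] <- if (dfr < min_df) "insufficient observations" else
        "design rank deficient on observed samples"
      next
    }
    fit <- stats::lm.fit(Xf, m[f, ok])
    XtXinv_f <- chol2inv(qr.R(fit$qr))
    beta[f] <- fit$coefficients[j]
    se_unscaled[f] <- sqrt(XtXinv_f[j, j])
    sigma2[f] <- sum(fit$residuals^2) / dfr
    dfres[f] <- dfr
  }
  structure(list(
    feature = rownames(m) %||% as.character(seq_len(nf)),
    coefficients = beta,
    stdev_unscaled = se_unscaled,
    sigma2 = sigma2,
    df_residual = dfres,
    skipped = skipped,
    coef = coef,
    design_columns = colnames(X)
  ), class = "feature_fits")
}

#' @export
print.feature_fits <- function(x, ...) {
  cat(sprintf("<feature_fits> %d features, coefficient '%s', %d skipped\n",
              length(x$coefficients), x$coef, sum(!is.na(x$skipped))))
  invisible(x)
}

#' @method tidy feature_fits
#' @export
tidy.feature_fits <- function(x, ...) {
  tibble(feature = x$feature, log2fc = x$coefficients,
         stdev_unscaled = x$stdev_unscaled, sigma2 = x$sigma2,
         df_residual = x$df_residual, skipped = x$skipped)
}

#' @method glance feature_fits
#' @export
glance.feature_fits <- function(x, ...) {
  tibble(n_features = length(x$coefficients),
         n_skipped = sum(!is.na(x$skipped)),
         coef = x$coef,
         moderated = !is.null(x$s2_post))
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks the per-feature residual variances toward a common prior by
#' fitting a scaled inverse chi-square prior to the observed variances
#' (moment estimation on the log scale), the standard moderated-t
#' construction: the posterior variance is `(d0*s0^2 + d_g*s_g^2) / (d0 +
#' d_g)` and the moderated degrees of freedom are `d_g + d0`. When the
#' observed variances are equidispersed the prior df is infinite and all
#' posterior variances equal the common prior value; with `prior_df = 0`
#' the fit is returned unmoderated (ordinary t).
#'
#' @param fits a [fit_linear_model()] result.
#' @param prior_df prior degrees of freedom; `NULL` (default) estimates it
#'   from the data, `0` disables shrinkage, `Inf` forces full pooling.
#' @return the fits with `s2_post`, `df_total`, `df_prior` and `s2_prior`
#'   added.
#' @export
moderate_variance <- function(fits, prior_df = NULL) {
  stopifnot(inherits(fits, "feature_fits"))
  ok <- !is.na(fits$sigma2) & fits$df_residual > 0
  s2 <- fits$sigma2[ok]
  df <- fits$df_residual[ok]
  if (!length(s2)) abort("no features with a residual variance to moderate")

  if (is.null(prior_df)) {
    pf <- fit_inv_chisq_prior(s2, df)
    d0 <- pf$df_prior
    s20 <- pf$s2_prior
  } else if (prior_df == 0) {
    d0 <- 0
    s20 <- NA_real_
  } else {
    d0 <- prior_df
    s20 <- exp(mean(log(s2)))
  }
  post <- fits$sigma2
  if (d0 == 0) {
    post[ok] <- s2
  } else if (is.infinite(d0)) {
    post[ok] <- s20
  } else {
    post[ok] <- (d0 * s20 + df * s2) / (d0 + df)
  }
  fits$s2_post <- post
  fits$df_total <- fits$df_residual + d0
  fits$df_prior <- d0
  fits$s2_prior <- s20
  fits
}

# Moment fit of a scaled inverse chi-square prior to observed variances,
# on the log scale: log(s^2) is distributed as log(s0^2) plus the log of
# an F variate, whose mean and variance involve di/trigamma functions.
fit_inv_chisq_prior <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- if (n > 1) sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
          else 0
  if (n > 1 && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s20 <- exp(emean)
  }
  list(df_prior = d0, s2_prior = s20)
}

# Newton solve of trigamma(x) = y (y > 0), monotone decreasing
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated test against a fold-change threshold
#'
#' Tests the null `|true log2fc| <= lfc_threshold` per feature with the
#' threshold-offset moderated t construction: with `a = |coef|`,
#' `t_right = (a - lfc)/se`, `t_left = (a + lfc)/se`, and `p =
#' P(T > t_right) + P(T > t_left)` on the moderated degrees of freedom.
#' With `lfc_threshold = 0` this reduces exactly to the two-sided
#' moderated t-test. The reported `t` is the signed threshold-offset
#' statistic `sign(coef) * t_right`.
#'
#' @param fits a moderated [feature_fits] (run [moderate_variance()]
#'   first; unmoderated fits use the raw residual variances).
#' @param lfc_threshold log2 fold-change threshold (default `log2(1.2)`).
#' @return tibble: `feature`, `log2fc`, `t`, `p_value`, `df_total`,
#'   `lfc_threshold`.
#' @export
treat_test <- function(fits, lfc_threshold = log2(1.2)) {
  stopifnot(inherits(fits, "feature_fits"), lfc_threshold >= 0)
  s2 <- fits$s2_post %||% fits$sigma2
  df <- fits$df_total %||% fits$df_residual
  se <- fits$stdev_unscaled * sqrt(s2)
  a <- abs(fits$coefficients)
  t_right <- (a - lfc_threshold) / se
  t_left <- (a + lfc_threshold) / se
  p <- pt(t_right, df = df, lower.tail = FALSE) +
    pt(t_left, df = df, lower.tail = FALSE)
  p <- pmin(p, 1)
  tibble(
    feature = fits$feature,
    log2fc = fits$coefficients,
    t = sign(fits$coefficients) * t_right,
    p_value = p,
    df_total = df,
    lfc_threshold = lfc_threshold
  )
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with the usual
#' monotonicity enforcement; q-values lie in (0, 1].
#'
#' @param p vector of p-values.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Apply the study significance rules to per-feature statistics
#'
#' Two named rule presets: `"analyte"` (LC-MS) calls a feature significant
#' iff the absolute fold difference exceeds 20% (`|2^log2fc - 1| > 0.20`,
#' evaluated symmetrically on the log scale as `|log2fc| > log2(1.2)`,
#' strict) and the FDR is below 10% (strict); `"gene"` (fold-change
#' threshold test path) uses `q <= 0.10` alone, since the fold-change
#' requirement is built into the test. The thresholds applied are recorded
#' in the output.
#'
#' @param results tibble with `feature`, `log2fc`, `p_value` (and
#'   optionally `t`).
#' @param rule `"analyte"` or `"gene"`.
#' @param fc_threshold fold-difference threshold for the analyte rule
#'   (fraction; default 0.20, strict).
#' @param fdr_threshold FDR cutoff (default 0.10; strict for `"analyte"`,
#'   inclusive for `"gene"`).
#' @return a `DiffResult` tibble: input columns plus `q_value`,
#'   `significant`, `rule`, `fc_threshold`, `fdr_threshold`.
#' @export
classify_differential <- function(results, rule = c("analyte", "gene"),
                                  fc_threshold = 0.20,
                                  fdr_threshold = 0.10) {
  rule <- match.arg(rule)
  stopifnot(all(c("feature", "log2fc", "p_value") %in% names(results)))
  q <- bh_fdr(results$p_value)
  sig <- if (rule == "analyte") {
    abs(results$log2fc) > log2(1 + fc_threshold) & q < fdr_threshold
  } else {
    q <= fdr_threshold
  }
  sig[is.na(sig)] <- FALSE
  dplyr::mutate(as_tibble(results),
                q_value = q,
                significant = sig,
                rule = rule,
                fc_threshold = ifelse(rule == "analyte", fc_threshold, NA),
                fdr_threshold = fdr_threshold)
}

#' Estimate surrogate variables by residual SVD
#'
#' A simple estimator of unmodelled systematic variation: regress out the
#' known covariates feature-wise, then take the top right-singular vectors
#' of the (complete-feature) residual matrix as surrogate variable
#' columns, ready to be appended to the model metadata.
#'
#' @param m feature x sample matrix.
#' @param metadata sample covariates.
#' @param formula known covariates.
#' @param n_sv number of surrogate variables (default 2).
#' @return metadata with columns `SV1..SVn` appended.
#' @export
estimate_sv <- function(m, metadata, formula = ~ genotype, n_sv = 2) {
  X <- stats::model.matrix(formula, data = metadata)
  ok <- rowSums(is.na(m)) == 0
  Y <- t(m[ok, , drop = FALSE])
  res <- Y - X %*% qr.coef(qr(X), Y)
  sv <- svd(res, nu = n_sv, nv = 0)$u[, seq_len(n_sv), drop = FALSE]
  for (i in seq_len(n_sv)) metadata[[paste0("SV", i)]] <- sv[, i]
  metadata
}

#' Within-subject differences for a paired repeated-measures comparison
#'
#' The transparent default for repeated measures from the same animal
#' (e.g. methoxy-X04 positive vs negative microglia sorted from one
#' brain): compute per-subject differences (condition minus reference) and
#' analyse them with an intercept-only (or covariate) model. Requires a
#' balanced design: exactly one sample per subject per condition level.
#'
#' @param m feature x sample matrix.
#' @param metadata sample covariates with `subject` and `condition`
#'   columns.
#' @param condition name of the two-level condition column.
#' @param subject name of the subject id column.
#' @param ref reference level (differences are other minus `ref`).
#' @return list with `m` (feature x subject difference matrix) and
#'   `metadata` (one row per subject).
#' @export
paired_differences <- function(m, metadata, condition = "methoxy_status",
                               subject = "subject_id", ref = NULL) {
  cond <- metadata[[condition]]
  subj <- metadata[[subject]]
  lev <- sort(unique(cond))
  if (length(lev) != 2) abort("condition must have exactly two levels")
  ref <- ref %||% lev[1]
  other <- setdiff(lev, ref)
  tab <- table(subj, cond)
  if (any(tab != 1)) {
    abort("paired analysis requires one sample per subject and condition")
  }
  subjects <- sort(unique(subj))
  i_ref <- match(paste(subjects, ref), paste(subj, cond))
  i_oth <- match(paste(subjects, other), paste(subj, cond))
  dm <- m[, i_oth, drop = FALSE] - m[, i_ref, drop = FALSE]
  colnames(dm) <- subjects
  meta <- metadata[i_ref, , drop = FALSE]
  meta[[condition]] <- NULL
  meta$subject <- subjects
  list(m = dm, metadata = tibble::as_tibble(meta))
}

#' Consensus intra-subject correlation
#'
#' The optional alternative to the paired default for repeated measures: a
#' single common intra-subject correlation, estimated per feature from the
#' within- vs between-subject decomposition of residuals (after removing
#' fixed effects) and combined on the Fisher z scale. The returned value
#' can be used to generalized-least-squares whiten a block-equicorrelated
#' design via [fit_linear_model_blocked()].
#'
#' @param m feature x sample matrix (complete features only are used).
#' @param metadata sample covariates.
#' @param formula fixed-effect covariates.
#' @param subject subject id column name.
#' @return the consensus correlation (scalar in (-1, 1)).
#' @export
consensus_correlation <- function(m, metadata, formula = ~ 1,
                                  subject = "subject_id") {
  X <- stats::model.matrix(formula, data = metadata)
  ok <- rowSums(is.na(m)) == 0
  Y <- t(m[ok, , drop = FALSE])
  res <- Y - X %*% qr.coef(qr(X), Y)
  subj <- metadata[[subject]]
  rho <- apply(res, 2, function(r) {
    # one-way random-effect decomposition per feature
    gm <- tapply(r, subj, mean)
    k <- tapply(r, subj, length)
    within <- sum((r - gm[subj])^2)
    df_w <- length(r) - length(gm)
    df_b <- length(gm) - 1
    if (df_w <= 0 || df_b <= 0) return(NA_real_)
    msw <- within / df_w
    msb <- sum(k * (gm - mean(r))^2) / df_b
    k0 <- mean(k)
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
    max(min(icc, 0.99), -0.99)
  })
  rho <- rho[!is.na(rho)]
  tanh(mean(atanh(rho)))
}

#' GLS fit with a common intra-subject correlation
#'
#' Whitens a block-equicorrelated covariance (correlation `rho` within
#' each subject's samples) and fits the usual per-feature least squares on
#' the whitened data, so repeated measures can be modelled without a
#' paired reduction.
#'
#' @inheritParams fit_linear_model
#' @param rho common intra-subject correlation (e.g. from
#'   [consensus_correlation()]).
#' @param subject subject id column name.
#' @return a `feature_fits` object.
#' @export
fit_linear_model_blocked <- function(m, metadata, formula = ~ 1, rho,
                                     subject = "subject_id", coef = NULL,
                                     min_df = 3) {
  subj <- factor(metadata[[subject]])
  n <- ncol(m)
  V <- diag(n)
  for (s in levels(subj)) {
    idx <- which(subj == s)
    V[idx, idx] <- rho
  }
  diag(V) <- 1
  e <- eigen(V, symmetric = TRUE)
  if (any(e$values <= 0)) abort("intra-subject correlation is too extreme")
  Wh <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  X <- stats::model.matrix(formula, data = metadata)
  mw <- m %*% t(Wh)
  colnames(mw) <- colnames(m)
  Xw <- Wh %*% X
  colnames(Xw) <- colnames(X)
  fit_linear_model(mw, design = Xw, coef = coef, min_df = min_df)
}

#' Select a signature from differential results
#'
#' Keeps genes with an estimated log2 fold change at or above
#' `min_log2fc` (inclusive).
#'
#' @param diff tibble with `feature` and `log2fc`.
#' @param min_log2fc inclusive lower bound (default 1).
#' @return character vector of feature names.
#' @export
extract_signature <- function(diff, min_log2fc = 1) {
  if (nrow(diff) == 0) return(character(0))
  diff$feature[!is.na(diff$log2fc) & diff$log2fc >= min_log2fc]
}
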