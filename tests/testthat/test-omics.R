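two_group_meta <- function(n_per_group) {
  tibble::tibble(
    genotype = factor(rep(c("WT", "KI"), each = n_per_group),
                      levels = c("WT", "KI"))
  )
}

test_that("internal-standard normalization is an elementwise log2 ratio", {
  pa <- matrix(c(200, 100, 50, 400), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  std <- matrix(c(100, 100), 1, 2, dimnames = list("IS", c("s1", "s2")))
  out <- normalize_internal_standard(pa, std)
  expect_equal(out["a", "s1"], 1)   # log2(200/100)
  expect_equal(out["b", "s1"], 0)   # area equal to the standard
  # random positive tables match the direct computation
  set.seed(1)
  pa2 <- matrix(runif(60, 1, 1000), 10, 6,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  std2 <- matrix(runif(6, 10, 100), 1, 6,
                 dimnames = list("IS", paste0("s", 1:6)))
  out2 <- normalize_internal_standard(pa2, std2)
  expect_equal(unname(out2),
               unname(log2(sweep(pa2, 2, std2[1, ], "/"))))
  std_bad <- std2
  std_bad[1, 2] <- 0
  expect_error(normalize_internal_standard(pa2, std_bad), "positive")
})

test_that("detection filter removes strictly below 75%", {
  m <- matrix(1, 3, 10, dimnames = list(c("p70", "p80", "full"), NULL))
  m[1, 1:3] <- NA # 7/10 detected -> below 75%, removed
  m[2, 1:2] <- NA # 8/10 detected -> kept
  out <- filter_detection(m, 0.75)
  expect_identical(rownames(out), c("p80", "full"))
  # fully detected matrices are unchanged
  full <- matrix(rnorm(20), 4, 5)
  expect_identical(filter_detection(full), full)
  # random missingness agrees with a per-feature counting oracle
  set.seed(4)
  r <- matrix(rnorm(200), 20, 10)
  r[sample(length(r), 60)] <- NA
  keep <- rowSums(!is.na(r)) / 10 >= 0.75
  expect_identical(filter_detection(r), r[keep, , drop = FALSE])
})

test_that("median scaling zeroes each sample's median", {
  set.seed(6)
  m <- matrix(rnorm(50, 5), 10, 5)
  m[sample(50, 5)] <- NA
  out <- median_scale(m)
  expect_equal(unname(apply(out, 2, median, na.rm = TRUE)), rep(0, 5))
  # shift invariance: adding a constant to a sample changes nothing
  m2 <- m
  m2[, 3] <- m2[, 3] + 7
  expect_equal(median_scale(m2), out)
  # an already centred sample is untouched
  m3 <- sweep(m, 2, apply(m, 2, median, na.rm = TRUE))
  expect_equal(median_scale(m3), m3)
})

test_that("low-expression filter requires strictly more than ten reads", {
  cnt <- rbind(
    eleven = c(rep(11, 6), rep(0, 6)),   # 11 reads in 6 samples: kept
    ten = c(rep(10, 12)),                # never exceeds 10: removed
    zero = rep(0, 12)
  )
  out <- filter_low_expression(cnt, min_samples = 6)
  expect_identical(rownames(out), "eleven")
  # random counts agree with the counting oracle
  set.seed(8)
  r <- matrix(rnbinom(300, mu = 12, size = 1), 25, 12)
  keep <- rowSums(r > 10) >= 6
  expect_identical(filter_low_expression(r, 6), r[keep, , drop = FALSE])
})

test_that("two-group fits return group mean differences", {
  meta <- two_group_meta(4)
  set.seed(10)
  m <- matrix(rnorm(32), 4, 8)
  fits <- fit_linear_model(m, meta, ~ genotype)
  want <- rowMeans(m[, 5:8]) - rowMeans(m[, 1:4])
  expect_equal(unname(fits$coefficients), unname(want))
  # an orthogonal covariate leaves the condition coefficient unchanged
  meta$cov <- rep(c(-1, -1, 1, 1), 2) # balanced within each group
  fits2 <- fit_linear_model(m, meta, ~ genotype + cov, coef = "genotypeKI")
  expect_equal(fits2$coefficients, fits$coefficients)
  # collinear designs fail loudly
  meta$dup <- as.numeric(meta$genotype == "KI")
  expect_error(fit_linear_model(m, meta, ~ genotype + dup), "rank deficient")
})

test_that("planted effects are recovered exactly at zero noise", {
  tr <- omics_truth(n_features = 25, n_per_group = 5,
                    true_log2fc = seq(-2, 2, length.out = 25),
                    batch_effects = 0.5, sex_effects = -0.3,
                    noise_sd = 0, seed = 3)
  ds <- make_analyte_dataset(tr)
  fits <- fit_linear_model(ds$log2, ds$samples, ~ genotype + batch + sex,
                           coef = "genotypeKI")
  expect_equal(unname(fits$coefficients), tr$true_log2fc, tolerance = 1e-10)
})

test_that("per-feature complete-case fitting matches a direct lm", {
  meta <- two_group_meta(6)
  set.seed(12)
  m <- matrix(rnorm(60), 5, 12)
  m[2, c(1, 7)] <- NA
  fits <- fit_linear_model(m, meta, ~ genotype)
  ok <- !is.na(m[2, ])
  ref <- lm(m[2, ok] ~ genotype, data = meta[ok, ])
  expect_equal(unname(fits$coefficients[2]), unname(coef(ref)[2]))
  expect_equal(unname(fits$df_residual[2]), ref$df.residual)
  # under-observed features are skipped with a reason
  m[3, 1:9] <- NA
  fits2 <- fit_linear_model(m, meta, ~ genotype, min_df = 3)
  expect_match(fits2$skipped[3], "insufficient")
  expect_true(is.na(fits2$coefficients[3]))
})

test_that("variance moderation matches the reference empirical Bayes fit", {
  meta <- two_group_meta(6)
  set.seed(14)
  m <- matrix(rnorm(100 * 12, sd = rep(sqrt(1 / rgamma(100, 4, 4)), 12)),
              100, 12)
  fits <- fit_linear_model(m, meta, ~ genotype)
  mod <- moderate_variance(fits)
  X <- stats::model.matrix(~ genotype, meta)
  lf <- limma::lmFit(m, X)
  sq <- limma::squeezeVar(lf$sigma^2, lf$df.residual)
  expect_equal(mod$df_prior, sq$df.prior, tolerance = 1e-8)
  expect_equal(mod$s2_prior, sq$var.prior, tolerance = 1e-8)
  expect_equal(unname(mod$s2_post), unname(sq$var.post), tolerance = 1e-10)
  # moderated variances sit between per-feature and fully pooled
  lo <- pmin(fits$sigma2, mod$s2_prior)
  hi <- pmax(fits$sigma2, mod$s2_prior)
  expect_true(all(mod$s2_post >= lo - 1e-12 & mod$s2_post <= hi + 1e-12))
})

test_that("moderation limiting cases behave", {
  meta <- two_group_meta(4)
  set.seed(15)
  m <- matrix(rnorm(10 * 8), 10, 8)
  fits <- fit_linear_model(m, meta, ~ genotype)
  # prior_df = 0: no shrinkage, ordinary variances
  un <- moderate_variance(fits, prior_df = 0)
  expect_equal(un$s2_post, fits$sigma2)
  # identical observed variances: full pooling to (nearly) that variance
  m2 <- m
  m2[,] <- rnorm(80)
  f2 <- fit_linear_model(m2, meta, ~ genotype)
  f2$sigma2 <- rep(0.5, 10) # force exact equality
  mod2 <- moderate_variance(f2)
  expect_true(is.infinite(mod2$df_prior))
  expect_equal(unname(mod2$s2_post), rep(mod2$s2_prior, 10))
  expect_equal(mod2$s2_prior, 0.5, tolerance = 0.2)
})

test_that("fold-change threshold test matches the reference implementation", {
  meta <- two_group_meta(5)
  set.seed(16)
  m <- matrix(rnorm(60 * 10) + rep(c(1.5, 0), c(10, 50)), 60, 10)
  m[, 6:10] <- m[, 6:10] + rep(c(1, 0), c(10, 50))
  fits <- moderate_variance(fit_linear_model(m, meta, ~ genotype))
  tt <- treat_test(fits, log2(1.2))
  X <- stats::model.matrix(~ genotype, meta)
  ref <- limma::treat(limma::eBayes(limma::lmFit(m, X)), lfc = log2(1.2))
  expect_equal(tt$p_value, unname(ref$p.value[, "genotypeKI"]),
               tolerance = 1e-12)
  expect_equal(tt$log2fc, unname(ref$coefficients[, "genotypeKI"]))
  # threshold 0 equals the two-sided moderated t exactly
  tt0 <- treat_test(fits, 0)
  eb <- limma::eBayes(limma::lmFit(m, X))
  expect_equal(tt0$p_value, unname(eb$p.value[, "genotypeKI"]),
               tolerance = 1e-12)
  # a coefficient far inside the null gives p ~ 1
  f1 <- fits
  f1$coefficients[] <- 0.01
  expect_true(all(treat_test(f1, 1)$p_value > 0.95))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # against the direct step-up formula on random p-values
  set.seed(18)
  p <- runif(50)
  o <- order(p)
  want <- numeric(50)
  want[o] <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(bh_fdr(p), pmin(want, 1))
})

test_that("significance rules apply the quoted thresholds exactly", {
  res <- tibble::tibble(
    feature = c("up25", "up10", "boundary", "down25"),
    log2fc = c(log2(1.25), log2(1.10), log2(1.20), -log2(1.25)),
    p_value = c(0.001, 1e-6, 0.001, 0.001)
  )
  out <- classify_differential(res, "analyte")
  expect_true(out$significant[out$feature == "up25"])
  # 10% fold change never passes the 20% rule, however small the p
  expect_false(out$significant[out$feature == "up10"])
  # exactly 20% is NOT "more than 20%"
  expect_false(out$significant[out$feature == "boundary"])
  expect_true(out$significant[out$feature == "down25"])

  # gene rule: FDR <= 10% inclusive
  res2 <- tibble::tibble(feature = c("a", "b"), log2fc = c(2, 2),
                         p_value = c(0.05, 0.2))
  out2 <- classify_differential(res2, "gene")
  expect_equal(out2$q_value, c(0.1, 0.2))
  expect_true(out2$significant[1])   # q exactly 0.10 -> significant
  expect_false(out2$significant[2])
})

test_that("signature extraction is inclusive at the fold-change bound", {
  d <- tibble::tibble(feature = c("a", "b", "c"),
                      log2fc = c(1.0, 0.99, 2.5))
  expect_identical(extract_signature(d, 1), c("a", "c"))
  expect_identical(extract_signature(d[0, ], 1), character(0))
})

test_that("residual-SVD surrogate variables recover a planted factor", {
  set.seed(20)
  meta <- two_group_meta(8)
  hidden <- rnorm(16)
  load <- rnorm(120, sd = 1)
  m <- outer(rep(0, 120), rep(0, 16)) + outer(load, hidden) +
    matrix(rnorm(120 * 16, sd = 0.1), 120, 16)
  meta2 <- estimate_sv(m, meta, ~ genotype, n_sv = 1)
  expect_gt(abs(cor(meta2$SV1, hidden)), 0.95)
})

test_that("paired reduction and blocked GLS handle repeated measures", {
  set.seed(22)
  n_subj <- 8
  meta <- tibble::tibble(
    subject_id = rep(sprintf("A%02d", 1:n_subj), each = 2),
    methoxy_status = rep(c("neg", "pos"), n_subj)
  )
  subj_eff <- rnorm(n_subj, sd = 2)
  eff <- c(rep(1, 5), rep(0, 15))
  m <- sapply(seq_len(2 * n_subj), function(s) {
    eff * (meta$methoxy_status[s] == "pos") +
      subj_eff[(s + 1) %/% 2] + rnorm(20, sd = 0.2)
  })
  pd <- paired_differences(m, meta, "methoxy_status", "subject_id",
                           ref = "neg")
  expect_equal(dim(pd$m), c(20, n_subj))
  fits <- fit_linear_model(pd$m, pd$metadata, ~ 1, coef = "(Intercept)")
  expect_equal(unname(fits$coefficients), eff, tolerance = 0.25)
  # blocked GLS with the consensus correlation agrees on the effect
  rho <- consensus_correlation(m, meta, ~ methoxy_status, "subject_id")
  expect_gt(rho, 0.9) # strong subject effect by construction
  meta$methoxy_status <- factor(meta$methoxy_status,
                                levels = c("neg", "pos"))
  bf <- fit_linear_model_blocked(m, meta, ~ methoxy_status, rho = rho,
                                 subject = "subject_id",
                                 coef = "methoxy_statuspos")
  expect_equal(unname(bf$coefficients), eff, tolerance = 0.25)
  # unbalanced designs are rejected for the paired path
  expect_error(paired_differences(m[, -1], meta[-1, ], "methoxy_status",
                                  "subject_id"),
               "one sample per subject")
})
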