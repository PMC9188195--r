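#' Ground truth for a synthetic analyte (or expression) dataset
#'
#' Emulates the statistical structure of a two-genotype sorted-microglia
#' LC-MS or expression experiment: per-feature condition effects on the
#' log2 scale, additive batch and sex offsets, Gaussian noise, and
#' per-feature missingness (missing completely at random at `1 -
#' detection_rate`).
#'
#' @param n_features number of features (analytes/genes).
#' @param n_per_group samples per genotype group.
#' @param true_log2fc per-feature condition effect, recycled.
#' @param batch_effects,sex_effects per-feature offsets, recycled.
#' @param detection_rate per-feature detection probability in `[0, 1]`.
#' @param baseline per-feature baseline log2 abundance, recycled.
#' @param noise_sd residual standard deviation (log2 units).
#' @param seed integer seed.
#' @return a list of class `omics_truth`; `affected_features` is the index
#'   set of features with a nonzero planted effect.
#' @export
omics_truth <- function(n_features = 200, n_per_group = 10,
                        true_log2fc = 0, batch_effects = 0, sex_effects = 0,
                        detection_rate = 1, baseline = 20, noise_sd = 0.3,
                        seed = 1) {
  stopifnot(n_features >= 1, n_per_group >= 2, noise_sd >= 0)
  detection_rate <- rep_len(detection_rate, n_features)
  if (any(detection_rate < 0 | detection_rate > 1)) {
    abort("detection rates must lie in [0, 1]")
  }
  lfc <- rep_len(true_log2fc, n_features)
  structure(list(
    n_features = n_features, n_per_group = n_per_group,
    true_log2fc = lfc,
    affected_features = which(lfc != 0),
    batch_effects = rep_len(batch_effects, n_features),
    sex_effects = rep_len(sex_effects, n_features),
    detection_rate = detection_rate,
    baseline = rep_len(baseline, n_features),
    noise_sd = noise_sd, seed = seed
  ), class = "omics_truth")
}

#' Generate a synthetic analyte-by-sample dataset with internal standards
#'
#' Samples carry a balanced genotype / sex / batch design plus subject ids
#' and a methoxy-X04 status column (positive in the affected genotype,
#' negative otherwise) mirroring a sorted-microglia design. The peak-area
#' form is constructed so that internal-standard normalization
#' ([normalize_internal_standard()]) recovers the log2 abundances exactly.
#'
#' @param truth an [omics_truth()].
#' @return a list of class `synthetic_analytes`: `log2` (feature x sample
#'   matrix with `NA` for undetected values), `peak_areas`,
#'   `standard_areas` (1 x sample matrix for the shared internal
#'   standard), `standard_map`, `samples` (metadata tibble), and
#'   `feature_truth`.
#' @export
make_analyte_dataset <- function(truth) {
  stopifnot(inherits(truth, "omics_truth"))
  n <- truth$n_features
  ns <- 2L * truth$n_per_group
  features <- sprintf("feature_%03d", seq_len(n))
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(ns)),
    genotype = factor(rep(c("WT", "KI"), each = truth$n_per_group),
                      levels = c("WT", "KI")),
    sex = rep_len(c("M", "F"), ns),
    batch = rep_len(c("day1", "day1", "day2", "day2"), ns),
    methoxy_status = rep(c("neg", "pos"), each = truth$n_per_group),
    subject_id = sprintf("A%02d", seq_len(ns))
  )
  cond <- as.numeric(samples$genotype == "KI")
  bat <- as.numeric(samples$batch == "day2")
  sx <- as.numeric(samples$sex == "F")

  with_seed(truth$seed, {
    mu <- truth$baseline +
      outer(truth$true_log2fc, cond) +
      outer(truth$batch_effects, bat) +
      outer(truth$sex_effects, sx)
    noise <- if (truth$noise_sd > 0) {
      matrix(rnorm(n * ns, 0, truth$noise_sd), n, ns)
    } else {
      0
    }
    log2v <- mu + noise
    detected <- matrix(runif(n * ns), n, ns) <=
      matrix(truth$detection_rate, n, ns)
    log2v[!detected] <- NA_real_
    dimnames(log2v) <- list(features, samples$sample_id)

    standard_areas <- matrix(2^rnorm(ns, 17, 0.2), 1, ns,
                             dimnames = list("IS1", samples$sample_id))
    peak_areas <- 2^log2v *
      matrix(standard_areas, n, ns, byrow = TRUE)

    structure(list(
      log2 = log2v,
      peak_areas = peak_areas,
      standard_areas = standard_areas,
      standard_map = tibble(feature = features, standard = "IS1"),
      samples = samples,
      feature_truth = tibble(
        feature = features,
        true_log2fc = truth$true_log2fc,
        affected = seq_len(n) %in% truth$affected_features,
        detection_rate = truth$detection_rate
      )
    ), class = "synthetic_analytes")
  })
}
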