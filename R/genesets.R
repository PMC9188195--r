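#' Eigen-weighted single-sample gene-set activity scores
#'
#' Restricts the expression matrix to the set's genes, centres each gene,
#' and scores each sample by a weighted average of the centred expression,
#' the weights being the genes' loadings on the first principal component
#' of the centred gene-by-sample matrix. The loading sign is ambiguous, so
#' the weight vector is oriented to correlate positively with the set's
#' mean expression profile (the orientation sign is reported); scores
#' equal the PC1 sample projection up to a positive scalar (the weights
#' are normalized to unit L1 mass).
#'
#' @param expr gene x sample expression matrix with rownames.
#' @param set character vector of gene names.
#' @param name optional set name for the output.
#' @param allow_single with a single overlapping gene, fall back to that
#'   gene's centred expression instead of erroring.
#' @return a list of class `geneset_score`: `set`, per-sample `scores`,
#'   per-gene `weights`, and `orientation_sign`.
#' @export
eigen_weighted_score <- function(expr, set, name = "set",
                                 allow_single = FALSE) {
  genes <- intersect(set, rownames(expr))
  if (length(genes) < 2) {
    if (length(genes) == 1 && allow_single) {
      x <- expr[genes, ] - mean(expr[genes, ])
      return(structure(list(set = name, scores = x,
                            weights = setNames(1, genes),
                            orientation_sign = 1L),
                       class = "geneset_score"))
    }
    abort(paste0("fewer than 2 set genes found in the matrix; ",
                 "use allow_single = TRUE for a single-gene fallback"))
  }
  if (ncol(expr) < 2) abort("at least 2 samples are required")
  Xc <- expr[genes, , drop = FALSE]
  Xc <- Xc - rowMeans(Xc)
  sv <- svd(Xc, nu = 1, nv = 0)
  w <- sv$u[, 1]
  proj <- as.numeric(crossprod(Xc, w)) # PC1 sample projection
  mean_profile <- colMeans(Xc)
  s <- sum(proj * mean_profile)
  sign_flip <- if (s < 0) -1L else 1L
  w <- w * sign_flip
  scores <- as.numeric(crossprod(Xc, w)) / sum(abs(w))
  structure(list(set = name,
                 scores = setNames(scores, colnames(expr)),
                 weights = setNames(w, genes),
                 orientation_sign = sign_flip),
            class = "geneset_score")
}

#' @export
print.geneset_score <- function(x, ...) {
  cat(sprintf("<geneset_score> '%s': %d genes, %d samples\n",
              x$set, length(x$weights), length(x$scores)))
  invisible(x)
}

#' @method tidy geneset_score
#' @export
tidy.geneset_score <- function(x, ...) {
  tibble(set = x$set, sample = names(x$scores) %||%
           as.character(seq_along(x$scores)),
         score = unname(x$scores))
}

#' Running-sum enrichment score and leading edge
#'
#' The standard weighted running sum over a ranking: walking down the
#' ranked list, set members increment the sum by `|stat| / sum_set |stat|`
#' and non-members decrement it by `1 / (N - K)`; the enrichment score is
#' the maximum-deviation extremum. The leading edge contains the set
#' members at or before a positive extremum, or at or after a negative
#' one. The gene weighting exponent is fixed at 1 (|stat| weighting) by
#' default and exposed.
#'
#' @param ranked tibble with columns `gene` and `stat`, sorted in
#'   descending `stat` order (resorted if not).
#' @param set character vector of gene names.
#' @param name optional set name.
#' @param exponent gene-weighting exponent applied to `|stat|`.
#' @return a list of class `enrichment_result`: `set`, `es`,
#'   `leading_edge`, `running` (the full running sum), `positions` of the
#'   set members.
#' @export
running_sum_enrichment <- function(ranked, set, name = "set", exponent = 1) {
  stopifnot(all(c("gene", "stat") %in% names(ranked)))
  ranked <- ranked[order(-ranked$stat), , drop = FALSE]
  N <- nrow(ranked)
  hit <- ranked$gene %in% set
  K <- sum(hit)
  if (K == 0 || K == N) {
    abort("the set must overlap the ranking partially (0 < K < N)")
  }
  w <- abs(ranked$stat)^exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - K)
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (running[i_max] >= abs(running[i_min])) {
    running[i_max]
  } else {
    running[i_min]
  }
  le <- if (es >= 0) {
    ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    ranked$gene[i_min:N][hit[i_min:N]]
  }
  structure(list(set = name, es = es, leading_edge = le,
                 running = running, positions = which(hit)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> '%s': ES = %.3f, leading edge %d genes\n",
              x$set, x$es, length(x$leading_edge)))
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(set = x$set, es = x$es,
         leading_edge_size = length(x$leading_edge),
         leading_edge = list(x$leading_edge))
}

#' Leading-edge mean-t enrichment score
#'
#' The mean of the moderated t-statistics over a fixed gene universe --
#' by convention the union of the set's leading edges across all
#' comparisons being displayed -- so scores are comparable across
#' comparisons. Genes absent from `t_by_gene` are dropped with a warning.
#'
#' @param t_by_gene named numeric vector of per-gene statistics for one
#'   comparison.
#' @param union_leading_edge character vector: the cross-comparison
#'   leading-edge universe.
#' @return the mean statistic (scalar).
#' @export
leading_edge_score <- function(t_by_gene, union_leading_edge) {
  if (length(union_leading_edge) == 0) {
    abort("the leading-edge universe is empty")
  }
  found <- union_leading_edge %in% names(t_by_gene)
  if (!all(found)) {
    warn(sprintf("%d universe genes missing from the statistics",
                 sum(!found)))
  }
  mean(t_by_gene[union_leading_edge[found]])
}

#' Union of leading edges across comparisons
#'
#' @param enrichments list of [running_sum_enrichment()] results for the
#'   same set across comparisons.
#' @return character vector union.
#' @export
leading_edge_union <- function(enrichments) {
  sort(unique(unlist(lapply(enrichments, function(e) e$leading_edge))))
}

#' Hypergeometric overlap test (upper tail)
#'
#' Exact probability of observing at least `k` genes in the intersection
#' of a set of size `K` and a set of size `n` drawn from a universe of
#' `N` genes: `P[X >= k]` for `X` hypergeometric.
#'
#' @param k observed overlap.
#' @param K first set size.
#' @param n second set size.
#' @param N universe size.
#' @return the upper-tail p-value.
#' @export
hypergeometric_overlap <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, k <= min(K, n), max(K, n) <= N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
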