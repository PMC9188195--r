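# Independent brute-force oracles. These deliberately share no code with the
# package implementations: labelling is iterative min-label propagation,
# dilation is exhaustive distance checking, geodesic assignment is per-peak
# relaxation, Otsu is exhaustive threshold search, and the hypergeometric
# tail is a combinatorial sum.

# shift a 3D array by (di, dj, dk), padding with `fill`
shift3 <- function(a, di, dj, dk, fill = Inf) {
  d <- dim(a)
  out <- array(fill, d)
  rng <- function(n, off) {
    lo <- max(1, 1 - off)
    hi <- min(n, n - off)
    if (lo > hi) integer(0) else lo:hi
  }
  src_i <- rng(d[1], di)
  src_j <- rng(d[2], dj)
  src_k <- rng(d[3], dk)
  if (!length(src_i) || !length(src_j) || !length(src_k)) return(out)
  out[src_i + di, src_j + dj, src_k + dk] <- a[src_i, src_j, src_k]
  out
}

as3d <- function(m) {
  if (length(dim(m)) == 2) array(m, c(dim(m), 1)) else m
}

neighbour_offsets <- function(full) {
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  if (!full) off <- off[abs(off$di) + abs(off$dj) + abs(off$dk) == 1, ]
  off
}

# connected components by iterative minimum-label propagation
oracle_label_components <- function(mask, full = TRUE) {
  m <- as3d(mask)
  lab <- array(Inf, dim(m))
  lab[m] <- which(m)
  off <- neighbour_offsets(full)
  repeat {
    new <- lab
    for (r in seq_len(nrow(off))) {
      shifted <- shift3(lab, off$di[r], off$dj[r], off$dk[r])
      new <- pmin(new, shifted)
    }
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  # after propagation each component carries its minimum linear index;
  # number components by that index (column-major first appearance), the
  # same deterministic order the implementation promises
  out <- array(0L, dim(m))
  ids <- sort(unique(lab[is.finite(lab)]))
  remap <- setNames(rank(ids), ids)
  out[is.finite(lab)] <- as.integer(remap[as.character(lab[is.finite(lab)])])
  array(out, dim(mask))
}

# exhaustive Euclidean dilation: positive iff within radius of any positive
oracle_dilate <- function(mask, radius) {
  pos <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim(mask))
  if (nrow(pos) == 0) return(out)
  all_px <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  r2 <- radius^2 + 1e-9
  for (q in seq_len(nrow(all_px))) {
    d2 <- (pos[, 1] - all_px[q, 1])^2 + (pos[, 2] - all_px[q, 2])^2
    if (any(d2 <= r2)) out[all_px[q, 1], all_px[q, 2]] <- TRUE
  }
  out
}

# per-peak in-mask geodesic distance by relaxation, then argmin with
# ties to the smaller peak label
oracle_geodesic <- function(mask, peaks, spacing = c(1, 1, 1)) {
  m <- as3d(mask)
  off <- neighbour_offsets(full = FALSE)
  dist_from <- function(p) {
    d <- array(Inf, dim(m))
    d[p[1], p[2], p[3]] <- 0
    repeat {
      new <- d
      for (r in seq_len(nrow(off))) {
        step <- spacing[which(c(off$di[r], off$dj[r], off$dk[r]) != 0)]
        cand <- shift3(d, off$di[r], off$dj[r], off$dk[r]) + step
        new <- pmin(new, cand)
      }
      new[!m] <- Inf
      new[p[1], p[2], p[3]] <- 0
      if (identical(new, d)) break
      d <- new
    }
    d
  }
  best <- array(Inf, dim(m))
  lab <- array(0L, dim(m))
  for (i in seq_len(nrow(peaks))) {
    d <- dist_from(as.integer(peaks[i, ]))
    upd <- m & (d < best)
    best[upd] <- d[upd]
    lab[upd] <- i
  }
  array(lab, dim(mask))
}

# exhaustive Otsu: maximize between-class variance over all cut points
oracle_otsu <- function(x) {
  v <- sort(unique(as.numeric(x)))
  cuts <- (v[-1] + v[-length(v)]) / 2
  bc <- vapply(cuts, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    w1 <- 1 - w0
    w0 * w1 * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bc)]
}

# combinatorial upper-tail hypergeometric
oracle_hypergeom <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

random_mask <- function(dims, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(dims)) < p, dims)
}
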