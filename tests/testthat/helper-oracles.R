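# Independent oracles and random-input helpers. These are deliberately
# written as naive/brute-force computations, separate from the package's
# dynamic-programming and prefix-sum code paths.

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

random_fold_model <- function() {
  fold_model(
    pair_weight = c(
      AU = runif(1, 0.2, 3),
      GC = runif(1, 0.2, 3),
      GU = runif(1, 0.2, 3)
    ),
    min_loop = sample(0:3, 1),
    stacking = sample(c(1, 1, runif(1, 0.5, 3)), 1)
  )
}

# Random valid bpp: sparse entries with the row-sum bound enforced by
# rescaling, returned as a bpp object.
random_bpp <- function(L, n_entries = max(3L, L), max_p = 0.9) {
  pool <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  take <- pool[sample.int(nrow(pool), min(n_entries, nrow(pool))), , drop = FALSE]
  p <- runif(nrow(take), 0, max_p)
  rs <- numeric(L)
  for (k in seq_along(p)) {
    rs[take[k, 1]] <- rs[take[k, 1]] + p[k]
    rs[take[k, 2]] <- rs[take[k, 2]] + p[k]
  }
  scale <- max(1, max(rs) * 1.01)
  bpp(data.frame(i = take[, 1], j = take[, 2], p = p / scale), length = L)
}

# Naive Eq-style domain scores: explicit double loop over all position
# pairs, classifying each as inside / cross by membership tests.
naive_domain_scores <- function(P, start, end, double_count = FALSE) {
  L <- nrow(P)
  inside <- 0
  cross <- 0
  size <- end - start + 1L
  for (i in 1:(L - 1)) {
    for (j in (i + 1):L) {
      in_i <- i >= start && i <= end
      in_j <- j >= start && j <= end
      if (in_i && in_j) {
        inside <- inside + P[i, j]
      } else if (in_i || in_j) {
        cross <- cross + P[i, j]
      }
    }
  }
  if (double_count) cross <- 2 * cross
  c(
    p_inside = inside / size^2,
    p_io = if (size == L) 0 else cross / ((L - size) * size)
  )
}

# Brute-force gamma-centroid: enumerate every subset of the above-threshold
# pairs, keep those forming a valid nested structure (checked directly),
# and maximize the gain.
brute_centroid <- function(x, gamma) {
  thresh <- 1 / (gamma + 1)
  cand <- as.data.frame(x[x$p > thresh, , drop = FALSE])
  n <- nrow(cand)
  best_gain <- 0
  best_pairs <- 0L
  if (n > 0) {
    for (mask in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      if (!length(sel)) next
      ii <- cand$i[sel]
      jj <- cand$j[sel]
      occ <- c(ii, jj)
      if (anyDuplicated(occ)) next
      ok <- TRUE
      if (length(sel) > 1) {
        for (a in seq_along(sel)) {
          for (b in seq_along(sel)) {
            if (a != b && ii[a] < ii[b] && ii[b] < jj[a] && jj[a] < jj[b]) ok <- FALSE
          }
        }
      }
      if (!ok) next
      gain <- sum((gamma + 1) * cand$p[sel] - 1)
      if (gain > best_gain) {
        best_gain <- gain
        best_pairs <- length(sel)
      }
    }
  }
  list(gain = best_gain, n_pairs = best_pairs)
}

# Independent count of nested structures (recursion over the leftmost
# position), used to cross-check the enumeration oracle itself.
count_structures <- function(seq, model) {
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  W <- model$weight_matrix
  ml <- model$min_loop
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (k in (i + 1):j) {
      if (k - i > ml && W[codes[i], codes[k]] > 0) {
        total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
      }
    }
    memo[[key]] <- total
    total
  }
  cnt(1, length(codes))
}
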