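# McCaskill-style inside-outside machinery.
#
# Inside recursion (rightmost-pair decomposition; every nested structure is
# generated exactly once):
#   Q(i, j)  = Q(i, j-1) + sum_{k = i..j-ml-1} Q(i, k-1) * Qb(k, j)
#   Qb(i, j) = w(i, j) * ( Q(i+1, j-1) + (s - 1) * Qb(i+1, j-1) )
# with Q over an empty interval = 1, w the pair weight (0 if not pairable or
# j - i <= min_loop) and s the stacking bonus attributed to the enclosing
# pair (algebraic split: interior ensembles where the immediately nested
# positions pair pick up the extra factor).
#
# Outside pass propagates context weights Qh (for Q cells) and Qbh (for Qb
# cells) top-down; pair probability p_ij = Qb(i,j) * Qbh(i,j) / Z.
#
# For long sequences the raw Q values overflow double precision (the
# structure count grows exponentially in L), so all recursions run on
# per-cell rescaled quantities Q'(i,j) = Q(i,j) / sigma^(j-i+1); sigma
# cancels from every probability and is estimated from a prefix of the
# sequence when L exceeds `rescale_above`.

fold_inside <- function(codes, model, sigma) {
  L <- length(codes)
  W <- model$weight_matrix
  ml <- model$min_loop
  s <- model$stacking
  Q <- matrix(0, L, L)
  Qb <- matrix(0, L, L)
  wmat <- W[codes, codes, drop = FALSE] / sigma^2
  for (span in 1:L) {
    for (i in 1:(L - span + 1L)) {
      j <- i + span - 1L
      if (span > ml + 1L && wmat[i, j] > 0) {
        qint <- if (j - 1L >= i + 1L) Q[i + 1L, j - 1L] else 1 / sigma^(span - 2L)
        qbint <- if (j - 1L > i + 1L) Qb[i + 1L, j - 1L] else 0
        Qb[i, j] <- wmat[i, j] * (qint + (s - 1) * qbint)
      }
      acc <- (if (j - 1L >= i) Q[i, j - 1L] else 1) / sigma
      kmax <- j - ml - 1L
      if (kmax >= i) {
        acc <- acc + Qb[i, j]
        if (kmax > i) {
          ks <- (i + 1L):kmax
          acc <- acc + sum(Q[i, ks - 1L] * Qb[ks, j])
        }
      }
      Q[i, j] <- acc
    }
  }
  list(Q = Q, Qb = Qb, Zs = Q[1L, L], sigma = sigma)
}

fold_outside <- function(codes, model, inside) {
  L <- length(codes)
  ml <- model$min_loop
  s <- model$stacking
  sigma <- inside$sigma
  W <- model$weight_matrix
  wmat <- W[codes, codes, drop = FALSE] / sigma^2
  Q <- inside$Q
  Qb <- inside$Qb
  Qh <- matrix(0, L, L)
  Qbh <- matrix(0, L, L)
  Qh[1L, L] <- 1
  for (span in L:1) {
    for (i in 1:(L - span + 1L)) {
      j <- i + span - 1L
      qh <- Qh[i, j]
      if (qh != 0) {
        if (j - 1L >= i) Qh[i, j - 1L] <- Qh[i, j - 1L] + qh / sigma
        kmax <- j - ml - 1L
        if (kmax >= i) {
          Qbh[i, j] <- Qbh[i, j] + qh
          if (kmax > i) {
            ks <- (i + 1L):kmax
            Qh[i, ks - 1L] <- Qh[i, ks - 1L] + qh * Qb[ks, j]
            Qbh[ks, j] <- Qbh[ks, j] + qh * Q[i, ks - 1L]
          }
        }
      }
      qbh <- Qbh[i, j]
      if (qbh != 0 && Qb[i, j] != 0 && j - 1L >= i + 1L) {
        Qh[i + 1L, j - 1L] <- Qh[i + 1L, j - 1L] + qbh * wmat[i, j]
        if (j - 1L > i + 1L && s != 1) {
          Qbh[i + 1L, j - 1L] <- Qbh[i + 1L, j - 1L] + qbh * wmat[i, j] * (s - 1)
        }
      }
    }
  }
  Qbh
}

choose_sigma <- function(codes, model, rescale_above) {
  L <- length(codes)
  if (L <= rescale_above) return(1)
  n <- min(150L, L)
  pre <- fold_inside(codes[seq_len(n)], model, sigma = 1)
  max(1, pre$Zs^(1 / n))
}

#' Partition function of the secondary-structure ensemble
#'
#' Sums the Boltzmann weights of all nested structures of `seq` under
#' `model` (the empty structure contributes 1), by the O(L^3) inside
#' recursion. `Z = 1` exactly when no pair is possible.
#'
#' @param seq A single RNA sequence (DNA input is normalized).
#' @param model A [fold_model()].
#' @param rescale_above Sequence length beyond which per-cell rescaling is
#'   applied; below it the raw double-precision recursion is used.
#' @return For unrescaled runs, `Z` as a plain number; for rescaled runs the
#'   (possibly astronomically large) value is returned as `exp(log Z)` and
#'   may overflow to `Inf` -- use `log = TRUE` for long sequences.
#' @param log Return `log(Z)` instead of `Z`.
#' @examples
#' partition_function("GAAAC", fold_model()) # 2: empty + the G1:C5 pair
#' @export
partition_function <- function(seq, model = fold_model(), log = FALSE,
                               rescale_above = 300L) {
  seq <- rna_residues(seq)
  if (length(seq) != 1L) stop_data("partition_function takes a single sequence")
  codes <- encode_residues(seq)
  L <- length(codes)
  sigma <- choose_sigma(codes, model, rescale_above)
  inside <- fold_inside(codes, model, sigma)
  logZ <- log(inside$Zs) + L * log(sigma)
  if (log) logZ else exp(logZ)
}

#' Base-pairing probability matrix by inside-outside recursion
#'
#' Computes `p_ij`, the probability that positions `i` and `j` pair over the
#' Boltzmann ensemble defined by `model`, for all `i < j`. Probabilities are
#' exact sums over the ensemble (weight of structures containing the pair,
#' divided by the partition function), obtained from the inside and outside
#' dynamic programs in O(L^3) time. Entries with `j - i <= min_loop` are
#' zero by construction, and every position's total pairing probability is
#' at most 1.
#'
#' @inheritParams partition_function
#' @param tol Probabilities at or below `tol` are dropped from the sparse
#'   result (guards against negative-zero noise from the algebraic
#'   stacking split).
#' @return A [bpp] object.
#' @examples
#' base_pair_probabilities("GAAAC", fold_model()) # p(1,5) = 0.5
#' @export
base_pair_probabilities <- function(seq, model = fold_model(),
                                    rescale_above = 300L, tol = 1e-15) {
  seq <- rna_residues(seq)
  if (length(seq) != 1L) stop_data("base_pair_probabilities takes a single sequence")
  codes <- encode_residues(seq)
  L <- length(codes)
  if (L == 1L) {
    return(bpp(data.frame(i = integer(), j = integer(), p = numeric()),
               length = 1L, seq = seq))
  }
  sigma <- choose_sigma(codes, model, rescale_above)
  inside <- fold_inside(codes, model, sigma)
  Qbh <- fold_outside(codes, model, inside)
  P <- inside$Qb * Qbh / inside$Zs
  idx <- which(upper.tri(P) & P > tol, arr.ind = TRUE)
  out <- bpp(data.frame(i = idx[, 1], j = idx[, 2], p = pmin(P[idx], 1)),
             length = L, seq = seq)
  out
}
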