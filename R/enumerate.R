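#' Exhaustively enumerate the secondary-structure ensemble
#'
#' Brute-force oracle for the folding recursions: generates every nested set
#' of allowed pairs (by the unambiguous leftmost-position decomposition, so
#' each structure appears exactly once), weights each structure as the
#' product of its pair weights times the stacking bonus per directly stacked
#' pair, and sums the weights into the partition value. Exponential in `L`,
#' hence capped.
#'
#' @inheritParams partition_function
#' @param max_length Refuse sequences longer than this (default 20).
#' @return A tibble with one row per structure: `structure` (list column of
#'   two-column pair matrices, possibly zero-row), `n_pairs`, `weight` and
#'   `dot_bracket`. The partition value `Z = sum(weight)` is attached as
#'   attribute `"Z"`, the sequence length as `"length"`.
#' @examples
#' enumerate_structures("GAAAC") # empty structure + (1,5)
#' @export
enumerate_structures <- function(seq, model = fold_model(), max_length = 20L) {
  seq <- rna_residues(seq)
  if (length(seq) != 1L) stop_data("enumerate_structures takes a single sequence")
  codes <- encode_residues(seq)
  L <- length(codes)
  if (L > max_length) {
    stop_usage("enumeration refused: length %d exceeds the cap of %d (combinatorial explosion); raise max_length deliberately if you must",
               L, max_length)
  }
  W <- model$weight_matrix
  ml <- model$min_loop
  pairable <- function(i, j) j - i > ml && W[codes[i], codes[j]] > 0

  # All nested pair sets on positions i..j; leftmost position either unpaired
  # or paired to some k, splitting the problem into two independent intervals.
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(), 0, 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- enum(i + 1L, j)
    for (k in (i + 1L):j) {
      if (pairable(i, k)) {
        left <- enum(i + 1L, k - 1L)
        right <- enum(k + 1L, j)
        for (a in left) {
          for (b in right) {
            out <- c(out, list(rbind(matrix(c(i, k), 1, 2), a, b)))
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  structures <- enum(1L, L)
  weight_of <- function(m) {
    if (nrow(m) == 0L) return(1)
    w <- prod(W[cbind(codes[m[, 1]], codes[m[, 2]])])
    if (model$stacking != 1) {
      key <- paste(m[, 1], m[, 2])
      stacked <- sum(paste(m[, 1] + 1L, m[, 2] - 1L) %in% key)
      w <- w * model$stacking^stacked
    }
    w
  }
  weights <- vapply(structures, weight_of, numeric(1))
  out <- tibble(
    structure = structures,
    n_pairs = vapply(structures, nrow, integer(1)),
    weight = weights,
    dot_bracket = vapply(structures, function(m) {
      to_dot_bracket(secondary_structure(m, L))
    }, character(1))
  )
  attr(out, "Z") <- sum(weights)
  attr(out, "length") <- L
  out
}

#' Pair probabilities from an enumerated ensemble
#'
#' Independent of the inside-outside code path: sums the weights of the
#' enumerated structures containing each pair and divides by the partition
#' value.
#'
#' @param ensemble Result of [enumerate_structures()].
#' @return A [bpp] object.
#' @export
ensemble_probabilities <- function(ensemble) {
  L <- attr(ensemble, "length")
  Z <- attr(ensemble, "Z")
  if (is.null(L) || is.null(Z)) stop_data("not an enumerated ensemble")
  P <- matrix(0, L, L)
  for (r in seq_len(nrow(ensemble))) {
    m <- ensemble$structure[[r]]
    if (nrow(m)) P[m] <- P[m] + ensemble$weight[r]
  }
  P <- P / Z
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  as_bpp(P)
}
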