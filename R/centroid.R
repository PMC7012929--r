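#' Secondary structures as nested pair sets
#'
#' A (pseudoknot-free) secondary structure on a sequence of length `L` is a
#' set of base pairs `(i, j)`, `i < j`, that are mutually non-crossing and in
#' which each position occurs at most once.
#'
#' @param pairs A two-column matrix or data frame of pairs (possibly
#'   zero-row); order within and between rows is normalized.
#' @param length Sequence length `L`.
#' @return An object of class `secondary_structure`.
#' @examples
#' secondary_structure(cbind(1, 8), 8)
#' @export
secondary_structure <- function(pairs, length) {
  L <- as.integer(length)
  if (is.na(L) || L < 1) stop_data("structure length must be >= 1")
  m <- as.matrix(pairs)
  if (base::length(m) == 0L) m <- matrix(integer(), 0, 2)
  if (ncol(m) != 2L) stop_data("pairs must have two columns (i, j)")
  storage.mode(m) <- "integer"
  if (nrow(m)) {
    sw <- m[, 1] > m[, 2]
    m[sw, ] <- m[sw, c(2, 1)]
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    if (any(m[, 1] < 1L) || any(m[, 2] > L)) stop_data("pair positions out of range 1..%d", L)
    if (any(m[, 1] == m[, 2])) stop_data("a position cannot pair with itself")
    occ <- c(m[, 1], m[, 2])
    if (anyDuplicated(occ)) {
      stop_data("position %d occurs in more than one pair", occ[duplicated(occ)][1])
    }
    if (nrow(m) > 1L) {
      for (a in seq_len(nrow(m) - 1L)) {
        b <- (a + 1L):nrow(m)
        crossing <- m[a, 1] < m[b, 1] & m[b, 1] < m[a, 2] & m[a, 2] < m[b, 2]
        if (any(crossing)) {
          k <- b[which(crossing)[1]]
          stop_data("pairs (%d,%d) and (%d,%d) cross (pseudoknots are not representable)",
                    m[a, 1], m[a, 2], m[k, 1], m[k, 2])
        }
      }
    }
  }
  structure(list(pairs = m, length = L), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary structure: L = %d, %d pairs>\n%s\n",
              x$length, nrow(x$pairs), to_dot_bracket(x)))
  invisible(x)
}

#' @export
#' @rdname secondary_structure
#' @param x A `secondary_structure`.
#' @param ... Unused.
tidy.secondary_structure <- function(x, ...) {
  tibble(i = x$pairs[, 1], j = x$pairs[, 2])
}

#' Dot-bracket rendering of a secondary structure
#'
#' `to_dot_bracket()` writes `'('` at each 5' partner, `')'` at each 3'
#' partner and `'.'` elsewhere; `from_dot_bracket()` inverts it, reporting
#' the offending position on unbalanced input. The round trip is the
#' identity.
#'
#' @param x A [secondary_structure()].
#' @return A single dot-bracket string.
#' @examples
#' to_dot_bracket(secondary_structure(cbind(1, 8), 8)) # "(......)"
#' from_dot_bracket("((...))")
#' @export
to_dot_bracket <- function(x) {
  if (!inherits(x, "secondary_structure")) stop_data("to_dot_bracket needs a secondary_structure")
  ch <- rep(".", x$length)
  ch[x$pairs[, 1]] <- "("
  ch[x$pairs[, 2]] <- ")"
  paste(ch, collapse = "")
}

#' @rdname to_dot_bracket
#' @param text A single dot-bracket string over `(`, `)`, `.`.
#' @export
from_dot_bracket <- function(text) {
  if (!is.character(text) || base::length(text) != 1L) {
    stop_data("dot-bracket input must be a single string")
  }
  ch <- strsplit(text, "")[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (base::length(bad)) {
    stop_data("invalid dot-bracket character '%s' at position %d", ch[bad[1]], bad[1])
  }
  stack <- integer()
  pairs <- matrix(integer(), 0, 2)
  for (pos in seq_along(ch)) {
    if (ch[pos] == "(") {
      stack <- c(stack, pos)
    } else if (ch[pos] == ")") {
      if (!base::length(stack)) {
        stop_data("unbalanced dot-bracket: unmatched ')' at position %d", pos)
      }
      pairs <- rbind(pairs, c(stack[base::length(stack)], pos))
      stack <- stack[-base::length(stack)]
    }
  }
  if (base::length(stack)) {
    stop_data("unbalanced dot-bracket: unmatched '(' at position %d", stack[1])
  }
  secondary_structure(pairs, base::length(ch))
}

#' Expected gain of a structure under the gamma-centroid objective
#'
#' The gamma-centroid estimator scores a candidate structure `S` against a
#' pairing-probability matrix as
#' \deqn{g(S) = \sum_{(i,j) \in S} \left[ (\gamma + 1)\, p_{ij} - 1 \right],}
#' so each predicted pair trades its probability against a fixed cost:
#' only pairs with `p_ij > 1/(gamma+1)` contribute positively. The gain is
#' additive over disjoint pair sets.
#'
#' @param structure A [secondary_structure()].
#' @param x A [bpp] object of the same length.
#' @param gamma Positive trade-off parameter (default 4, the setting used
#'   for domain work in this package).
#' @return The gain, a single number (0 for the empty structure).
#' @examples
#' m <- bpp(data.frame(i = 1, j = 8, p = 0.9), 8)
#' expected_gain(secondary_structure(cbind(1, 8), 8), m, gamma = 4) # 3.5
#' @export
expected_gain <- function(structure, x, gamma = 4) {
  if (!inherits(structure, "secondary_structure")) {
    stop_data("expected_gain needs a secondary_structure")
  }
  if (!is.numeric(gamma) || base::length(gamma) != 1L || gamma <= 0) {
    stop_data("gamma must be a single positive value")
  }
  L <- bpp_length(x)
  if (structure$length != L) {
    stop_data("structure length %d does not match matrix length %d", structure$length, L)
  }
  if (nrow(structure$pairs) == 0L) return(0)
  p <- bpp_at(x, structure$pairs[, 1], structure$pairs[, 2])
  sum((gamma + 1) * p - 1)
}

#' Gamma-centroid structure prediction
#'
#' Returns the nested structure maximizing the expected gain
#' `sum over pairs of [(gamma+1) p_ij - 1]` by an O(L^3) interval dynamic
#' program. Only pairs with `p_ij` strictly above `1/(gamma+1)` can appear;
#' pairs exactly at the threshold have zero gain and are excluded so the
#' output is canonical. Ties between equal-gain decompositions are broken
#' deterministically: fewer pairs first, then the lexicographically smallest
#' pair set.
#'
#' @param x A [bpp] object.
#' @param gamma Positive trade-off parameter; larger values admit
#'   lower-probability pairs (threshold `1/(gamma+1)`). Default 4.
#' @param min_loop Re-impose a minimum hairpin-loop size on the prediction.
#'   Default 0: matrices produced by folding already carry zero probability
#'   inside the loop constraint, so no extra constraint is needed; set this
#'   for imported matrices that do not.
#' @return A [secondary_structure()] with attribute `"gain"`.
#' @examples
#' m <- bpp(data.frame(i = 1, j = 8, p = 0.9), 8)
#' gamma_centroid(m) # single pair (1,8), gain 3.5
#' @export
gamma_centroid <- function(x, gamma = 4, min_loop = 0L) {
  if (!inherits(x, "bpp")) stop_data("gamma_centroid needs a bpp object")
  if (!is.numeric(gamma) || base::length(gamma) != 1L || gamma <= 0) {
    stop_data("gamma must be a single positive value")
  }
  L <- bpp_length(x)
  thresh <- 1 / (gamma + 1)
  cand <- x[x$p > thresh & (x$j - x$i) > min_loop, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- secondary_structure(matrix(integer(), 0, 2), L)
    attr(out, "gain") <- 0
    return(out)
  }
  G <- matrix(0, L, L) # gain of eligible pair, 0 = ineligible
  G[cbind(cand$i, cand$j)] <- (gamma + 1) * cand$p - 1

  # M[i,j]: best gain on i..j; N[i,j]: pair count of the tie-broken optimum;
  # K[i,j]: decision (0 = leave i unpaired, k = pair i with k).
  # Padded (L+1) so interval queries i > j read 0 without branching.
  M <- matrix(0, L + 1L, L + 1L)
  N <- matrix(0L, L + 1L, L + 1L)
  K <- matrix(0L, L, L)
  for (span in 2:L) {
    for (i in 1:(L - span + 1L)) {
      j <- i + span - 1L
      best_g <- M[i + 1L, j]
      best_n <- N[i + 1L, j]
      best_k <- 0L
      ks <- which(G[i, i:j] > 0) + i - 1L
      for (k in ks) {
        g <- G[i, k] +
          (if (i + 1L <= k - 1L) M[i + 1L, k - 1L] else 0) +
          (if (k + 1L <= j) M[k + 1L, j] else 0)
        n <- 1L +
          (if (i + 1L <= k - 1L) N[i + 1L, k - 1L] else 0L) +
          (if (k + 1L <= j) N[k + 1L, j] else 0L)
        if (g > best_g || (g == best_g && n < best_n) ||
            (g == best_g && n == best_n && best_k == 0L)) {
          # last clause: at equal gain and pair count, pairing position i as
          # early as possible yields the lexicographically smallest pair set

          best_g <- g
          best_n <- n
          best_k <- k
        }
      }
      M[i, j] <- best_g
      N[i, j] <- best_n
      K[i, j] <- best_k
    }
  }
  pairs <- matrix(integer(), 0, 2)
  if (L >= 2L) {
    stack <- list(c(1L, L))
    while (base::length(stack)) {
      iv <- stack[[base::length(stack)]]
      stack[[base::length(stack)]] <- NULL
      i <- iv[1]
      j <- iv[2]
      while (i < j) {
        k <- K[i, j]
        if (k == 0L) {
          i <- i + 1L
        } else {
          pairs <- rbind(pairs, c(i, k))
          if (k + 1L <= j) stack[[base::length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
        }
      }
    }
  }
  out <- secondary_structure(pairs, L)
  attr(out, "gain") <- if (L >= 2L) M[1L, L] else 0
  out
}
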