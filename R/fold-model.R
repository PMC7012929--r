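#' Simplified Boltzmann folding model
#'
#' The domain-detection method consumes a base-pairing probability matrix and
#' is agnostic to the energy model that produced it. For self-contained use
#' this package folds under a deliberately simple ensemble: every nested
#' (pseudoknot-free) set of allowed pairs is a structure, the empty structure
#' has weight 1, and a structure's Boltzmann weight is the product of one
#' weight per pair, optionally multiplied by a stacking bonus for each pair
#' directly stacked inside another (`(i, j)` and `(i+1, j-1)` both present).
#' Full nearest-neighbor thermodynamics are intentionally not reproduced;
#' Turner-model matrices from external tools can be supplied via
#' [read_bpp()] instead.
#'
#' @param allowed_pairs Character vector of unordered pairable residue pairs.
#'   Default `c("AU", "GC", "GU")` (Watson-Crick plus wobble).
#' @param min_loop Minimum number of unpaired nucleotides enclosed by a pair
#'   (steric hairpin-loop constraint). A pair `(i, j)` requires
#'   `j - i > min_loop`. Default 3.
#' @param pair_weight Positive Boltzmann weight per pair: a single value for
#'   all pair types, or a named vector keyed by pair type (e.g.
#'   `c(AU = 1, GC = 3, GU = 0.5)`). Unnamed types fall back to 1.
#' @param stacking Multiplicative bonus for each directly stacked pair;
#'   1 (default) disables stacking.
#' @return An object of class `fold_model`.
#' @examples
#' fold_model(pair_weight = c(AU = 1, GC = 3, GU = 0.5), stacking = 2)
#' @export
fold_model <- function(allowed_pairs = c("AU", "GC", "GU"),
                       min_loop = 3L,
                       pair_weight = 1,
                       stacking = 1) {
  if (!is.numeric(min_loop) || length(min_loop) != 1L || min_loop < 0 ||
      min_loop != floor(min_loop)) {
    stop_data("min_loop must be a single integer >= 0")
  }
  if (!is.numeric(pair_weight) || any(pair_weight <= 0)) {
    stop_data("pair weights must be positive")
  }
  if (!is.numeric(stacking) || length(stacking) != 1L || stacking <= 0) {
    stop_data("stacking bonus must be a single positive value")
  }
  allowed_pairs <- toupper(chartr("Tt", "Uu", allowed_pairs))
  if (any(nchar(allowed_pairs) != 2L) ||
      any(grepl("[^ACGU]", allowed_pairs))) {
    stop_data("allowed_pairs must be two-letter combinations of A/C/G/U")
  }
  bases <- c("A", "C", "G", "U")
  W <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (p in unique(allowed_pairs)) {
    a <- substr(p, 1, 1)
    b <- substr(p, 2, 2)
    w <- if (!is.null(names(pair_weight))) {
      key <- names(pair_weight)
      hit <- match(TRUE, key %in% c(p, paste0(b, a)))
      idx <- which(key == p | key == paste0(b, a))
      if (length(idx)) pair_weight[[idx[1]]] else 1
    } else {
      pair_weight[[1]]
    }
    W[a, b] <- w
    W[b, a] <- w
  }
  structure(
    list(
      allowed_pairs = allowed_pairs,
      min_loop = as.integer(min_loop),
      pair_weight = pair_weight,
      stacking = stacking,
      weight_matrix = W
    ),
    class = "fold_model"
  )
}

#' @export
print.fold_model <- function(x, ...) {
  cat("<fold_model>\n")
  cat("  allowed pairs:", paste(x$allowed_pairs, collapse = ", "), "\n")
  cat("  min loop:", x$min_loop, "nt\n")
  cat("  stacking bonus:", x$stacking, "\n")
  wm <- x$weight_matrix
  nz <- which(upper.tri(wm) & wm > 0, arr.ind = TRUE)
  lab <- apply(nz, 1L, function(k) {
    sprintf("%s%s=%g", rownames(wm)[k[1]], colnames(wm)[k[2]], wm[k[1], k[2]])
  })
  cat("  pair weights:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

# Integer-encode residues as indices into the model weight matrix.
encode_residues <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  stopifnot(!anyNA(codes))
  codes
}
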