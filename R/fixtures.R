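#' Specify a synthetic fixture with planted structural domains
#'
#' Describes a synthetic test input: either a base-pairing probability
#' matrix with planted hairpin-like domains (`mode = "matrix_only"`) or an
#' RNA sequence whose planted intervals are complementary inverted repeats
#' (`mode = "sequence_with_hairpins"`).
#'
#' In matrix mode each planted domain `(start, end)` receives anti-diagonal
#' stem entries `p(start+k, end-k) = stem_probability` for
#' `k = 0..floor(span/3) - 1` (a stem closing the region, with the middle
#' third left as loop), and background noise is laid uniformly over pairs
#' with *both* ends outside every planted domain, with per-entry values in
#' `[0.9, 1] x background_noise`. The planted domain is thus insulated --
#' it pairs only within itself, which is exactly the property the domain
#' statistics are designed to detect -- while the noise floor gives every
#' candidate that merely contains a domain a nonzero inside-outside
#' statistic, so the planted interval is the unique maximal passing
#' candidate under the default thresholds.
#'
#' @param seed Integer seed; identical specs generate identical fixtures.
#' @param length Sequence length, nucleotides.
#' @param domains A data frame with columns `start`, `end` and
#'   `stem_probability` (one row per planted domain), or `NULL` for none.
#'   Domains must be disjoint and within `1..length`.
#' @param background_noise Maximum off-domain entry value (default 0.0025).
#'   Must stay below 0.006 so that noise-only regions cannot fake the
#'   default inside threshold (0.003), and low enough that row sums stay
#'   below 1.
#' @param mode `"matrix_only"` or `"sequence_with_hairpins"`.
#' @return An object of class `fixture_spec`.
#' @examples
#' fixture_spec(1, 60, data.frame(start = 21, end = 50, stem_probability = 0.9),
#'              background_noise = 0)
#' @export
fixture_spec <- function(seed, length,
                         domains = NULL,
                         background_noise = 0.0025,
                         mode = c("matrix_only", "sequence_with_hairpins")) {
  mode <- match.arg(mode)
  L <- as.integer(length)
  if (is.na(L) || L < 1) stop_data("fixture length must be >= 1")
  if (!is.numeric(seed) || base::length(seed) != 1L) stop_data("seed must be a single integer")
  if (!is.numeric(background_noise) || background_noise < 0) {
    stop_data("background_noise must be >= 0")
  }
  if (background_noise >= 0.006) {
    stop_data("background_noise %g too large: noise-only regions would approach the inside threshold (guarantee requires < 0.006)",
              background_noise)
  }
  if (!is.null(domains)) {
    if (!is.data.frame(domains) ||
        !all(c("start", "end", "stem_probability") %in% names(domains))) {
      stop_data("domains must have columns start, end, stem_probability")
    }
    domains <- as_tibble(domains)
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)
    if (any(domains$start < 1L) || any(domains$end > L) ||
        any(domains$end <= domains$start)) {
      stop_data("planted domains must satisfy 1 <= start < end <= %d", L)
    }
    if (any(domains$stem_probability <= 0) || any(domains$stem_probability > 1)) {
      stop_data("stem_probability must be in (0, 1]")
    }
    d <- domains[order(domains$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop_data("planted domains overlap")
    }
  } else {
    domains <- tibble(start = integer(), end = integer(),
                      stem_probability = numeric())
  }
  if (background_noise * (L - 1L) > 1) {
    stop_data("background_noise %g violates the row-sum bound at length %d",
              background_noise, L)
  }
  structure(
    list(seed = as.integer(seed), length = L, domains = domains,
         background_noise = background_noise, mode = mode),
    class = "fixture_spec"
  )
}

n_stem_pairs <- function(start, end) {
  span <- end - start + 1L
  max(1L, span %/% 3L)
}

#' Generate a synthetic fixture
#'
#' Deterministically realizes a [fixture_spec()]: identical specs give
#' byte-identical outputs. See [fixture_spec()] for the construction.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `truth` (tibble of planted domains) and
#'   either `bpp` (a [bpp] object, matrix mode) or `residues` (a sequence
#'   string, sequence mode).
#' @examples
#' fx <- generate_fixture(fixture_spec(1, 60,
#'   data.frame(start = 21, end = 50, stem_probability = 0.9),
#'   background_noise = 0))
#' extract_domains(fx$bpp)
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop_data("generate_fixture needs a fixture_spec")
  L <- spec$length
  d <- spec$domains
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (spec$mode == "matrix_only") {
    ent <- list()
    in_domain <- rep(FALSE, L)
    for (r in seq_len(nrow(d))) {
      ns <- n_stem_pairs(d$start[r], d$end[r])
      k <- seq_len(ns) - 1L
      ent[[base::length(ent) + 1L]] <- tibble(
        i = d$start[r] + k, j = d$end[r] - k, p = d$stem_probability[r]
      )
      in_domain[d$start[r]:d$end[r]] <- TRUE
    }
    if (spec$background_noise > 0) {
      out_pos <- which(!in_domain)
      if (base::length(out_pos) >= 2L) {
        grid <- expand.grid(i = out_pos, j = out_pos)
        grid <- grid[grid$i < grid$j, , drop = FALSE]
        ent[[base::length(ent) + 1L]] <- tibble(
          i = grid$i, j = grid$j,
          p = runif(nrow(grid), 0.9, 1) * spec$background_noise
        )
      }
    }
    entries <- if (base::length(ent)) bind_rows(ent) else {
      tibble(i = integer(), j = integer(), p = numeric())
    }
    rs <- rowsum_bound(entries, L)
    if (any(rs > 1 + 1e-9)) {
      stop_data("fixture spec violates the row-sum bound (max row sum %g)", max(rs))
    }
    list(bpp = bpp(entries, length = L), truth = d)
  } else {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    res <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    for (r in seq_len(nrow(d))) {
      ns <- n_stem_pairs(d$start[r], d$end[r])
      k <- seq_len(ns) - 1L
      arm <- sample(c("A", "C", "G", "U"), ns, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
      res[d$start[r] + k] <- arm
      res[d$end[r] - k] <- unname(comp[arm])
      loop <- setdiff(d$start[r]:d$end[r],
                      c(d$start[r] + k, d$end[r] - k))
      # A-rich loops avoid spurious pairing within the unpaired stretch
      res[loop] <- sample(c("A", "A", "A", "C"), base::length(loop), replace = TRUE)
    }
    list(residues = paste(res, collapse = ""), truth = d)
  }
}

# save/restore the global RNG state so fixture generation is hermetic
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Random block-aligned fixture specs for recovery studies
#'
#' Draws a planted-domain spec at random (block-aligned span between
#' `min_span` and `max_span`, uniform placement, stem probability in
#' `stem_range`) -- the configuration under which the planted interval is
#' recoverable as the unique maximal passing candidate.
#'
#' @param seed Integer seed (also used as the fixture seed).
#' @param length Sequence length (default 120).
#' @param block_size Alignment grid (default 10).
#' @param min_span,max_span Domain span bounds in nucleotides (defaults 20
#'   and 50); both are rounded to multiples of `block_size`.
#' @param stem_range Range of stem probabilities (default `c(0.7, 0.95)`).
#' @param background_noise Noise level (default 0.0025).
#' @return A [fixture_spec()].
#' @export
random_domain_spec <- function(seed, length = 120L, block_size = 10L,
                               min_span = 20L, max_span = 50L,
                               stem_range = c(0.7, 0.95),
                               background_noise = 0.0025) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spans <- seq.int(min_span, max_span, by = block_size)
  span <- sample(spans, 1L)
  n_blocks <- length %/% block_size
  start_block <- sample.int(n_blocks - span %/% block_size + 1L, 1L)
  start <- (start_block - 1L) * block_size + 1L
  stem <- runif(1, stem_range[1], stem_range[2])
  fixture_spec(
    seed = seed, length = length,
    domains = tibble(start = start, end = start + span - 1L,
                     stem_probability = stem),
    background_noise = background_noise,
    mode = "matrix_only"
  )
}
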