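# Block-based structural-domain detection.
#
# The sequence is cut into fixed-size blocks; every run of consecutive
# blocks is a domain candidate D. Two normalized sums of base-pairing
# probabilities score it:
#
#   p_inside(D)  = [ sum over unordered pairs i<j with both ends in D ] / |D|^2
#   p_io(D)      = [ sum over unordered pairs with exactly one end in D ]
#                  / ( (L - |D|) |D| )
#
# A region with p_inside above a high threshold and p_io below a low one
# pairs within itself but hardly with the rest of the molecule: a stable
# local secondary structure. The matrix is defined on the upper triangle,
# so both sums count each unordered pair once; `double_count_cross = TRUE`
# reproduces the alternative reading in which each cross pair enters the
# inside-outside sum twice (once per ordering). For the whole-sequence
# candidate (|D| = L) the cross set is empty and p_io is defined as 0.

#' Decompose a sequence length into fixed-size blocks
#'
#' Cuts `1..L` into consecutive blocks of `block_size` nucleotides
#' (default 10). A trailing remainder is kept as its own short block so
#' every position is covered.
#'
#' @param L Sequence length.
#' @param block_size Block size in nucleotides.
#' @return A tibble with columns `block`, `start`, `end`, `width`
#'   (`ceiling(L / block_size)` rows).
#' @examples
#' decompose_blocks(656) # 66 blocks, the last of 6 nt
#' @export
decompose_blocks <- function(L, block_size = 10L) {
  L <- as.integer(L)
  block_size <- as.integer(block_size)
  if (is.na(L) || L < 1) stop_data("sequence length must be >= 1")
  if (is.na(block_size) || block_size < 1) stop_data("block_size must be >= 1")
  starts <- seq.int(1L, L, by = block_size)
  ends <- pmin(starts + block_size - 1L, L)
  tibble(block = seq_along(starts), start = starts, end = ends,
         width = ends - starts + 1L)
}

#' Enumerate every domain candidate of a block decomposition
#'
#' Every combination of successive blocks is a candidate: `B(B+1)/2`
#' candidates for `B` blocks, ordered lexicographically by
#' `(first_block, last_block)`.
#'
#' @param decomp A block decomposition from [decompose_blocks()].
#' @return A tibble with columns `first_block`, `last_block`, `start`,
#'   `end`, `width`.
#' @examples
#' nrow(enumerate_candidates(decompose_blocks(656))) # 2211
#' @export
enumerate_candidates <- function(decomp) {
  if (!is.data.frame(decomp) || !all(c("block", "start", "end") %in% names(decomp))) {
    stop_data("decomp must come from decompose_blocks()")
  }
  B <- nrow(decomp)
  first <- rep(seq_len(B), times = B - seq_len(B) + 1L)
  last <- unlist(lapply(seq_len(B), function(a) a:B))
  tibble(
    first_block = first,
    last_block = last,
    start = decomp$start[first],
    end = decomp$end[last],
    width = decomp$end[last] - decomp$start[first] + 1L
  )
}

#' Score domain candidates by inside and inside-outside statistics
#'
#' Computes `p_inside` and `p_io` (see the formulas above) for each
#' candidate against a base-pairing probability matrix, via 2-D prefix sums
#' so the whole candidate table costs O(L^2 + number of candidates).
#'
#' @param x A [bpp] object.
#' @param candidates A candidate tibble from [enumerate_candidates()], or
#'   `NULL` to score every candidate of the default decomposition of the
#'   matrix length.
#' @param block_size Block size used when `candidates` is `NULL`.
#' @param double_count_cross Count each cross pair twice in the
#'   inside-outside sum (the symmetric-double-count convention). Default
#'   `FALSE`: unordered pairs counted once, matching the upper-triangle
#'   definition of the matrix.
#' @return The candidate tibble with added columns `p_inside` and `p_io`.
#' @export
score_candidates <- function(x, candidates = NULL, block_size = 10L,
                             double_count_cross = FALSE) {
  if (!inherits(x, "bpp")) stop_data("score_candidates needs a bpp object")
  L <- bpp_length(x)
  if (is.null(candidates)) {
    candidates <- enumerate_candidates(decompose_blocks(L, block_size))
  }
  if (any(candidates$end > L) || any(candidates$start < 1L)) {
    stop_data("candidate positions out of range for matrix length %d", L)
  }
  P <- bpp_matrix(x)
  # Cumulative machinery: S2 is the padded 2-D prefix sum of the full
  # symmetric matrix; crs the prefix sum of row totals.
  S2 <- matrix(0, L + 1L, L + 1L)
  S2[-1L, -1L] <- apply(apply(P, 2L, cumsum), 1L, cumsum) |> t()
  crs <- c(0, cumsum(rowSums(P)))
  a <- candidates$start
  b <- candidates$end
  size <- candidates$width
  inside_full <- S2[cbind(b + 1L, b + 1L)] - S2[cbind(a, b + 1L)] -
    S2[cbind(b + 1L, a)] + S2[cbind(a, a)]
  rows_total <- crs[b + 1L] - crs[a]
  inside <- inside_full / 2 # symmetric matrix counts each unordered pair twice
  cross <- rows_total - inside_full # each unordered cross pair appears once
  if (double_count_cross) cross <- 2 * cross
  p_inside <- inside / size^2
  p_io <- ifelse(size == L, 0, cross / ((L - size) * size))
  out <- as_tibble(candidates)
  out$p_inside <- p_inside
  out$p_io <- pmax(p_io, 0)
  out
}

#' Scan a matrix (or sequence) and report every domain candidate
#'
#' One row per candidate with its scores and pass flag; the extraction
#' policy's selected domains are attached and retrievable with [tidy()],
#' summary counts with [glance()].
#'
#' @param x A [bpp] object, or a single RNA sequence (folded internally
#'   with `model`).
#' @param block_size Block size in nucleotides (default 10).
#' @param threshold_inside Candidates must have `p_inside` strictly above
#'   this (default 0.003).
#' @param threshold_io Candidates must have `p_io` strictly below this
#'   (default 0.0003).
#' @param mode Extraction policy for overlapping passing candidates:
#'   `"maximal_passing"` (default) keeps passing candidates not strictly
#'   contained in another passing candidate; `"all_passing"` keeps every
#'   passing candidate; `"best_nonoverlapping"` greedily keeps the highest
#'   `p_inside` candidates without overlap.
#' @param double_count_cross See [score_candidates()].
#' @param model Folding model used when `x` is a sequence.
#' @return A `domain_scan` tibble: the full candidate table (columns
#'   `first_block`, `last_block`, `start`, `end`, `width`, `p_inside`,
#'   `p_io`, `pass`), sorted by `(start, end)`, with the extracted domains
#'   as attribute `"domains"`.
#' @examples
#' m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), 60)
#' scan_domains(m)
#' @export
scan_domains <- function(x, block_size = 10L,
                         threshold_inside = 0.003, threshold_io = 0.0003,
                         mode = c("maximal_passing", "all_passing",
                                  "best_nonoverlapping"),
                         double_count_cross = FALSE,
                         model = fold_model()) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold_inside) || threshold_inside < 0 ||
      !is.numeric(threshold_io) || threshold_io < 0) {
    stop_data("thresholds must be >= 0")
  }
  if (is.character(x)) x <- base_pair_probabilities(x, model)
  scored <- score_candidates(x, block_size = block_size,
                             double_count_cross = double_count_cross)
  scored$pass <- scored$p_inside > threshold_inside & scored$p_io < threshold_io
  scored <- arrange(scored, .data$start, .data$end)
  domains <- extract_passing(scored, mode)
  structure(
    scored,
    length = bpp_length(x),
    block_size = as.integer(block_size),
    threshold_inside = threshold_inside,
    threshold_io = threshold_io,
    mode = mode,
    domains = domains,
    class = c("domain_scan", class(tibble()))
  )
}

extract_passing <- function(scored, mode) {
  passing <- scored[scored$pass, , drop = FALSE]
  passing <- as_tibble(passing)[, c("first_block", "last_block", "start",
                                    "end", "width", "p_inside", "p_io")]
  if (nrow(passing) == 0L || mode == "all_passing") {
    return(arrange(passing, .data$start, .data$end))
  }
  if (mode == "maximal_passing") {
    keep <- vapply(seq_len(nrow(passing)), function(k) {
      contained <- passing$start <= passing$start[k] &
        passing$end >= passing$end[k] &
        (passing$start < passing$start[k] | passing$end > passing$end[k])
      !any(contained)
    }, logical(1))
    return(arrange(passing[keep, , drop = FALSE], .data$start, .data$end))
  }
  # best_nonoverlapping: greedy by descending p_inside, ties by start
  ord <- order(-passing$p_inside, passing$start, passing$end)
  chosen <- integer()
  for (k in ord) {
    overlaps <- any(passing$start[chosen] <= passing$end[k] &
                      passing$end[chosen] >= passing$start[k])
    if (!overlaps) chosen <- c(chosen, k)
  }
  arrange(passing[sort(chosen), , drop = FALSE], .data$start, .data$end)
}

#' Extract structural domains from a pairing-probability matrix
#'
#' Convenience wrapper around [scan_domains()] returning only the extracted
#' domains.
#'
#' @inheritParams scan_domains
#' @return A tibble of domains (1-based inclusive `start`/`end`) with their
#'   `p_inside` and `p_io` scores, sorted by start position.
#' @examples
#' m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), 60)
#' extract_domains(m)
#' @export
extract_domains <- function(x, block_size = 10L,
                            threshold_inside = 0.003, threshold_io = 0.0003,
                            mode = c("maximal_passing", "all_passing",
                                     "best_nonoverlapping"),
                            double_count_cross = FALSE,
                            model = fold_model()) {
  scan <- scan_domains(x, block_size, threshold_inside, threshold_io,
                       mode, double_count_cross, model)
  attr(scan, "domains")
}

#' @export
print.domain_scan <- function(x, ...) {
  d <- attr(x, "domains")
  cat(sprintf("<domain scan: L = %d, block %d nt, %d candidates, %d passing, %d extracted (%s)>\n",
              attr(x, "length"), attr(x, "block_size"), nrow(x),
              sum(x$pass), nrow(d), attr(x, "mode")))
  NextMethod()
}

#' @export
#' @rdname scan_domains
#' @param ... Unused.
tidy.domain_scan <- function(x, ...) {
  attr(x, "domains")
}

#' @export
#' @rdname scan_domains
glance.domain_scan <- function(x, ...) {
  tibble(
    length = attr(x, "length"),
    block_size = attr(x, "block_size"),
    n_candidates = nrow(x),
    n_passing = sum(x$pass),
    n_domains = nrow(attr(x, "domains")),
    threshold_inside = attr(x, "threshold_inside"),
    threshold_io = attr(x, "threshold_io"),
    mode = attr(x, "mode")
  )
}

#' @export
#' @rdname scan_domains
#' @param object A `domain_scan`.
autoplot.domain_scan <- function(object, ...) {
  df <- as_tibble(object)
  doms <- attr(object, "domains")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$end)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(pmax(.data$p_inside, 1e-6)),
                                    width = attr(object, "block_size"),
                                    height = attr(object, "block_size"))) +
    ggplot2::geom_point(data = df[df$pass, , drop = FALSE],
                        shape = 1, colour = "red", size = 2) +
    ggplot2::geom_point(data = doms, shape = 16, colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "log10 p_inside") +
    ggplot2::labs(
      x = "candidate start (nt)", y = "candidate end (nt)",
      title = "Domain candidates",
      subtitle = "open circles: passing; filled: extracted"
    ) +
    ggplot2::theme_minimal()
}

#' Export domains as BED intervals
#'
#' The scanner's coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start` is shifted down by one. The score column is
#' `p_inside` scaled by 1000 and clamped to `[0, 1000]`.
#'
#' @param domains A domain tibble from [extract_domains()] or
#'   [tidy()] of a scan.
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1 (default
#'   `"seq"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(domains, path, chrom = "seq") {
  if (!is.data.frame(domains) || !all(c("start", "end") %in% names(domains))) {
    stop_data("domains must be a data frame with start/end columns")
  }
  score <- if ("p_inside" %in% names(domains)) {
    pmin(pmax(round(domains$p_inside * 1000), 0), 1000)
  } else {
    rep(0, nrow(domains))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", chrom,
                   domains$start - 1L, domains$end,
                   sprintf("domain_%d", seq_len(max(nrow(domains), 0L))),
                   as.integer(score))
  writeLines(lines, path)
  invisible(path)
}
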