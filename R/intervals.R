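#' Parse genomic interval strings
#'
#' Parses strings of the form `"chrom:start-end(strand)"` (for example
#' `"chr6:151937260-151937915(-)"`) into a tibble. Coordinates are 1-based and
#' inclusive on both ends, matching the convention used when naming RNA
#' fragments by base numbers. The strand may be given as ASCII `-`/`+` or as
#' the typographic minus sign; a missing `(strand)` suffix defaults to `+`.
#'
#' @param x Character vector of interval strings.
#' @return A tibble with one row per input and columns `chrom` (character),
#'   `start`, `end` (integers, 1-based inclusive), `strand` (`"+"` or `"-"`)
#'   and `width` (`end - start + 1`, in nucleotides).
#' @examples
#' parse_interval("chr6:151937260-151937915(-)")
#' @seealso [interval_width()] for the width alone.
#' @export
parse_interval <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop_data("interval must be a non-empty character vector")
  }
  x_norm <- gsub("−", "-", trimws(x)) # typographic minus
  rx <- "^([^:[:space:]]+):([0-9,]+)-([0-9,]+)(\\(([+-])\\))?$"
  bad <- !grepl(rx, x_norm)
  if (any(bad)) {
    first <- x[which(bad)[1]]
    part <- if (!grepl(":", x_norm[which(bad)[1]])) "chrom" else "start-end"
    stop_data("malformed interval '%s': cannot parse %s field (expected chrom:start-end(strand))",
              first, part)
  }
  chrom <- sub(rx, "\\1", x_norm)
  start <- as.numeric(gsub(",", "", sub(rx, "\\2", x_norm)))
  end <- as.numeric(gsub(",", "", sub(rx, "\\3", x_norm)))
  strand <- sub(rx, "\\5", x_norm)
  strand[strand == ""] <- "+"
  if (any(start < 1)) {
    stop_data("malformed interval '%s': start field must be >= 1", x[which(start < 1)[1]])
  }
  if (any(end < start)) {
    stop_data("malformed interval '%s': end field must be >= start", x[which(end < start)[1]])
  }
  tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    width = as.integer(end - start + 1)
  )
}

#' Width of a genomic interval in nucleotides
#'
#' With 1-based inclusive coordinates the width is `end - start + 1`; the
#' 656-nt conserved Eleanor2 unit `chr6:151937260-151937915(-)` is the
#' canonical example.
#'
#' @param x Character vector of interval strings, or a data frame with
#'   `start` and `end` columns (as returned by [parse_interval()]).
#' @return Integer vector of widths.
#' @examples
#' interval_width("chr6:151937260-151937915(-)") # 656
#' @export
interval_width <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("start", "end") %in% names(x))) {
      stop_data("interval data frame must have 'start' and 'end' columns")
    }
    return(as.integer(x$end - x$start + 1L))
  }
  parse_interval(x)$width
}
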