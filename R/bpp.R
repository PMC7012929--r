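#' Base-pairing probability matrices
#'
#' A base-pairing probability (BPP) matrix records, for every position pair
#' `1 <= i < j <= L`, the equilibrium probability `p_ij` that positions `i`
#' and `j` are paired over the Boltzmann ensemble of secondary structures.
#' The package stores it sparsely as a tibble of `(i, j, p)` triplets
#' (upper triangle only) carrying the sequence length `L` as an attribute,
#' so dplyr verbs apply directly and dense storage is only materialized on
#' demand via [bpp_matrix()].
#'
#' Validity requires `0 <= p_ij <= 1` and, because a base pairs with at most
#' one partner, a row-sum bound `sum_j p_ij <= 1` for every position `i`.
#'
#' @param entries Data frame with numeric columns `i`, `j`, `p`; rows with
#'   `p = 0` are dropped. Indices are 1-based with `i < j`.
#' @param length Sequence length `L`.
#' @param seq Optional residue string of length `L`, kept as an attribute.
#' @return An object of class `bpp` (a tibble of triplets).
#' @examples
#' m <- bpp(data.frame(i = 1, j = 5, p = 0.5), length = 5)
#' bpp_at(m, 5, 1)
#' @export
bpp <- function(entries, length, seq = NULL) {
  if (!is.data.frame(entries) || !all(c("i", "j", "p") %in% names(entries))) {
    stop_data("bpp entries must be a data frame with columns i, j, p")
  }
  L <- as.integer(length)
  if (is.na(L) || L < 1) stop_data("bpp length must be >= 1")
  e <- as_tibble(entries)[, c("i", "j", "p")]
  e$i <- as.integer(e$i)
  e$j <- as.integer(e$j)
  e$p <- as.numeric(e$p)
  if (any(e$i >= e$j)) {
    k <- which(e$i >= e$j)[1]
    stop_data("bpp entry %d has i >= j (%d >= %d); entries are upper-triangle only",
              k, e$i[k], e$j[k])
  }
  if (any(e$i < 1L) || any(e$j > L)) {
    stop_data("bpp entries out of range 1..%d", L)
  }
  if (any(e$p < -1e-9) || any(e$p > 1 + 1e-9)) {
    k <- which(e$p < -1e-9 | e$p > 1 + 1e-9)[1]
    stop_data("bpp entry %d has probability %g outside [0, 1]", k, e$p[k])
  }
  e$p <- pmin(pmax(e$p, 0), 1)
  if (anyDuplicated(e[, c("i", "j")])) {
    stop_data("duplicate bpp entries for the same (i, j)")
  }
  e <- e[e$p > 0, , drop = FALSE]
  e <- e[order(e$i, e$j), , drop = FALSE]
  rs <- rowsum_bound(e, L)
  if (any(rs > 1 + 1e-9)) {
    k <- which.max(rs)
    stop_data("bpp row-sum invariant violated: position %d has total pairing probability %g > 1",
              k, rs[k])
  }
  structure(e, length = L, seq = seq, class = c("bpp", class(tibble())))
}

rowsum_bound <- function(entries, L) {
  rs <- numeric(L)
  if (nrow(entries)) {
    t1 <- tapply(entries$p, entries$i, sum)
    t2 <- tapply(entries$p, entries$j, sum)
    rs[as.integer(names(t1))] <- rs[as.integer(names(t1))] + t1
    rs[as.integer(names(t2))] <- rs[as.integer(names(t2))] + t2
  }
  rs
}

#' @rdname bpp
#' @param x A `bpp` object (or, for `as_bpp()`, a dense square matrix).
#' @export
bpp_length <- function(x) {
  L <- attr(x, "length")
  if (is.null(L)) stop_data("object has no bpp length attribute; is it a bpp?")
  L
}

#' @rdname bpp
#' @param tol Entries below `tol` are dropped when converting from dense form.
#' @export
as_bpp <- function(x, tol = 0) {
  if (inherits(x, "bpp")) return(x)
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop_data("dense bpp matrix must be square")
    idx <- which(upper.tri(x) & x > tol, arr.ind = TRUE)
    return(bpp(
      data.frame(i = idx[, 1], j = idx[, 2], p = x[idx]),
      length = nrow(x)
    ))
  }
  stop_data("cannot convert object of class '%s' to bpp", class(x)[1])
}

#' Dense symmetric matrix form of a BPP object
#'
#' @param x A `bpp` object.
#' @return An `L x L` symmetric numeric matrix with zero diagonal.
#' @export
bpp_matrix <- function(x) {
  L <- bpp_length(x)
  P <- matrix(0, L, L)
  if (nrow(x)) {
    P[cbind(x$i, x$j)] <- x$p
    P[cbind(x$j, x$i)] <- x$p
  }
  P
}

#' Query pairing probabilities with unordered indices
#'
#' The matrix is defined for `i < j`; the accessor symmetrizes, so
#' `bpp_at(x, i, j) == bpp_at(x, j, i)`. Absent entries are 0.
#'
#' @param x A `bpp` object.
#' @param i,j Position vectors (recycled to a common length).
#' @return Numeric vector of probabilities.
#' @export
bpp_at <- function(x, i, j) {
  L <- bpp_length(x)
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n)
  j <- rep_len(as.integer(j), n)
  if (any(i < 1L | i > L | j < 1L | j > L)) stop_data("positions out of range 1..%d", L)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  hit <- match(key, paste(x$i, x$j))
  out <- numeric(n)
  out[!is.na(hit)] <- x$p[hit[!is.na(hit)]]
  out[lo == hi] <- 0
  out
}

#' @export
print.bpp <- function(x, ...) {
  cat(sprintf("<base-pairing probability matrix: L = %d, %d nonzero entries>\n",
              bpp_length(x), nrow(x)))
  NextMethod()
}

#' Read a base-pairing probability matrix
#'
#' Supports two plain-text dialects:
#' \describe{
#'   \item{`tsv`}{Tab-separated triplets `i<TAB>j<TAB>p` (1-based, `i < j`),
#'     with optional `#`-prefixed header lines; a `# length=L` header declares
#'     the sequence length.}
#'   \item{`vienna_ubox`}{The PostScript dot-plot dialect written by Vienna
#'     tools: data lines `i j v ubox`, where the stored value is the square
#'     root of the probability (`p = v^2`). The length is taken from the
#'     embedded `/sequence` block when present.}
#' }
#' Unlisted entries are 0. This import path lets matrices computed by
#' external Turner-model tools feed the domain scanner unchanged.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vienna_ubox"`.
#' @param length Sequence length; overrides (and is required in the absence
#'   of) the length declared in the file.
#' @return A [bpp] object.
#' @export
read_bpp <- function(path, dialect = c("tsv", "vienna_ubox"), length = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_usage("bpp file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    read_bpp_tsv(path, lines, length)
  } else {
    read_bpp_ubox(path, lines, length)
  }
}

read_bpp_tsv <- function(path, lines, length) {
  header <- grep("^#", lines, value = TRUE)
  decl <- regmatches(header, regexpr("length\\s*=\\s*[0-9]+", header))
  file_len <- if (base::length(decl)) as.integer(sub(".*=\\s*", "", decl[1])) else NULL
  L <- length %||% file_len
  if (is.null(L)) {
    stop_data("bpp file '%s' declares no length (no '# length=L' header); pass length=", path)
  }
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  ent <- data.frame(i = integer(), j = integer(), p = numeric())
  if (base::length(data_idx)) {
    parts <- strsplit(trimws(lines[data_idx]), "\t|\\s+")
    nf <- lengths(parts)
    if (any(nf != 3L)) {
      bad <- data_idx[which(nf != 3L)[1]]
      stop_data("format error in '%s' line %d: expected 3 fields 'i\tj\tp'", path, bad)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
    if (anyNA(m)) {
      bad <- data_idx[which(rowSums(is.na(m)) > 0)[1]]
      stop_data("format error in '%s' line %d: non-numeric field", path, bad)
    }
    if (any(m[, 1] >= m[, 2])) {
      bad <- data_idx[which(m[, 1] >= m[, 2])[1]]
      stop_data("format error in '%s' line %d: requires i < j", path, bad)
    }
    if (any(m[, 3] < 0 | m[, 3] > 1)) {
      bad <- data_idx[which(m[, 3] < 0 | m[, 3] > 1)[1]]
      stop_data("format error in '%s' line %d: probability outside [0, 1]", path, bad)
    }
    if (any(m[, 2] > L)) {
      bad <- data_idx[which(m[, 2] > L)[1]]
      stop_data("format error in '%s' line %d: index exceeds declared length %d", path, bad, L)
    }
    ent <- data.frame(i = m[, 1], j = m[, 2], p = m[, 3])
  }
  bpp(ent, length = L)
}

read_bpp_ubox <- function(path, lines, length) {
  L <- length
  if (is.null(L)) {
    seq_start <- grep("^/sequence", lines)
    if (base::length(seq_start)) {
      seq_end <- grep("def", lines[seq_start[1]:base::length(lines)])[1] + seq_start[1] - 1L
      block <- paste(lines[seq_start[1]:seq_end], collapse = "")
      residues <- gsub("[^A-Za-z]", "", sub("^/sequence", "", block))
      residues <- sub("def$", "", residues)
      if (nzchar(residues)) L <- nchar(residues)
    }
  }
  if (is.null(L)) {
    stop_data("ubox file '%s' embeds no /sequence block; pass length=", path)
  }
  data_idx <- grep("^\\s*[0-9]+\\s+[0-9]+\\s+[0-9.eE+-]+\\s+ubox\\s*$", lines)
  ent <- data.frame(i = integer(), j = integer(), p = numeric())
  if (base::length(data_idx)) {
    parts <- strsplit(trimws(lines[data_idx]), "\\s+")
    m <- matrix(as.numeric(vapply(parts, function(x) x[1:3], character(3))),
                ncol = 3, byrow = TRUE)
    if (any(m[, 1] >= m[, 2])) {
      bad <- data_idx[which(m[, 1] >= m[, 2])[1]]
      stop_data("format error in '%s' line %d: requires i < j", path, bad)
    }
    p <- m[, 3]^2
    if (any(p > 1 + 1e-9)) {
      bad <- data_idx[which(p > 1 + 1e-9)[1]]
      stop_data("format error in '%s' line %d: squared value outside [0, 1]", path, bad)
    }
    if (any(m[, 2] > L)) {
      bad <- data_idx[which(m[, 2] > L)[1]]
      stop_data("format error in '%s' line %d: index exceeds length %d", path, bad, L)
    }
    ent <- data.frame(i = m[, 1], j = m[, 2], p = pmin(p, 1))
  }
  bpp(ent, length = L)
}

#' Write a base-pairing probability matrix as TSV
#'
#' Writes the triplet dialect read by [read_bpp()]: a `# length=L` header
#' followed by `i<TAB>j<TAB>p` lines sorted by `(i, j)`. Entries at or below
#' `floor` are omitted.
#'
#' @param x A [bpp] object.
#' @param path Output path.
#' @param floor Smallest probability emitted (default `1e-6`).
#' @return `path`, invisibly.
#' @export
write_bpp <- function(x, path, floor = 1e-6) {
  if (!inherits(x, "bpp")) stop_data("write_bpp needs a bpp object")
  keep <- x[x$p > floor, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# base-pairing probability matrix (i\tj\tp, 1-based, i<j)",
    sprintf("# length=%d", bpp_length(x))
  ), con)
  if (nrow(keep)) {
    writeLines(sprintf("%d\t%d\t%.17g", keep$i, keep$j, keep$p), con)
  }
  invisible(path)
}

#' Dot-plot of a base-pairing probability matrix
#'
#' @param object A [bpp] object.
#' @param ... Unused.
#' @return A ggplot: upper-triangle tiles sized by nothing and shaded by
#'   probability, the classic RNA dot-plot.
#' @export
autoplot.bpp <- function(object, ...) {
  L <- bpp_length(object)
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(limits = c(L + 0.5, 0.5)) +
    ggplot2::scale_x_continuous(limits = c(0.5, L + 0.5), position = "top") +
    ggplot2::scale_fill_gradient(low = "grey92", high = "black",
                                 limits = c(0, 1), name = "p(i,j)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j", y = "position i") +
    ggplot2::theme_minimal()
}
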