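#' Normalize a character vector to RNA residues
#'
#' Upper-cases and converts `T` to `U` (templates are routinely given as DNA),
#' then validates that only `A`, `C`, `G`, `U` remain.
#'
#' @param x Character vector of sequences.
#' @return Character vector of normalized RNA sequences.
#' @examples
#' rna_residues("acgt") # "ACGU"
#' @export
rna_residues <- function(x) {
  if (!is.character(x)) stop_data("sequence must be character")
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1], regexpr("[^ACGU]", out[bad][1]))
    stop_data("invalid residue '%s' in sequence (alphabet is A/C/G/U, T accepted as U)", ch)
  }
  out
}

#' Extract a subfragment by 1-based inclusive positions
#'
#' Returns residues `start..end` of a sequence, the operation used to name
#' fragments such as "320-447" (a 128-nt piece of a 656-nt RNA).
#'
#' @param seq A single sequence string (RNA or DNA; returned as given).
#' @param start,end 1-based inclusive positions, `1 <= start <= end <= nchar(seq)`.
#' @return The fragment string, of length `end - start + 1`.
#' @examples
#' subfragment("GGGAUCCC", 2, 4) # "GGA"
#' @export
subfragment <- function(seq, start, end) {
  if (!is.character(seq) || length(seq) != 1L) stop_data("seq must be a single string")
  L <- nchar(seq)
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L || length(end) != 1L ||
      start != floor(start) || end != floor(end)) {
    stop_data("start and end must be single integers")
  }
  if (start < 1 || end > L || start > end) {
    stop_data("subfragment coordinates %d-%d out of bounds for length %d (need 1 <= start <= end <= length)",
              as.integer(start), as.integer(end), L)
  }
  substr(seq, start, end)
}

#' Reverse complement of a DNA sequence, returned as RNA
#'
#' Minus-strand transcription units (such as the Eleanor2 unit on chr6) are
#' specified by their genomic plus-strand DNA; the transcript is the reverse
#' complement with `T` replaced by `U`. Complementing is delegated to
#' Biostrings; the DNA-to-DNA analogue of this operation is an involution.
#'
#' @param dna Character vector of DNA sequences over `A/C/G/T` (case
#'   insensitive).
#' @return Character vector of RNA sequences.
#' @examples
#' reverse_complement_rna("ATGC") # "GCAU"
#' @export
reverse_complement_rna <- function(dna) {
  if (!is.character(dna)) stop_data("dna must be character")
  up <- toupper(dna)
  bad <- grepl("[^ACGT]", up)
  if (any(bad)) {
    ch <- regmatches(up[bad][1], regexpr("[^ACGT]", up[bad][1]))
    stop_data("invalid DNA residue '%s' (alphabet is A/C/G/T)", ch)
  }
  vapply(up, function(s) {
    if (!nzchar(s)) return("")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    chartr("T", "U", rc)
  }, character(1), USE.NAMES = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file into a tibble.
#' In RNA mode (the default) residues are normalized with [rna_residues()],
#' so DNA-style `T`/lower case input becomes upper-case `U`.
#'
#' @param path Path to a FASTA file.
#' @param rna Normalize residues to the RNA alphabet? Default `TRUE`.
#' @return A tibble with columns `id`, `residues` and `width`.
#' @export
read_fasta <- function(path, rna = TRUE) {
  if (!file.exists(path)) stop_usage("FASTA file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty)) {
    first <- nonempty[1]
    if (!startsWith(trimws(lines[first]), ">")) {
      stop_data("malformed FASTA '%s': line %d contains sequence before any '>' header",
                path, first)
    }
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop_data("malformed FASTA '%s': no records", path)
  ids <- sub("\\s.*$", "", names(set))
  res <- unname(as.character(set))
  if (rna) res <- rna_residues(res)
  tibble(id = unname(ids), residues = res, width = nchar(res))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble/data frame with `id` and `residues` columns (as returned
#'   by [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    res <- unname(x)
  } else if (is.data.frame(x)) {
    if (!all(c("id", "residues") %in% names(x))) {
      stop_data("FASTA data frame must have 'id' and 'residues' columns")
    }
    ids <- x$id
    res <- x$residues
  } else {
    stop_data("cannot write FASTA from object of class '%s'", class(x)[1])
  }
  set <- Biostrings::BStringSet(res)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
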