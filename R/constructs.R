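#' Build an in-vitro T7 transcript construct
#'
#' Run-off transcription from a T7 promoter on a plasmid linearized by a
#' blunt-cutting enzyme adds fixed residues to the insert: `GGG` at the
#' 5' terminus (from the promoter) and, at the 3' terminus, `GAC` when the
#' template was linearized with EcoRV or `UCG` with NruI. The transcript is
#' therefore always 6 nt longer than the insert: a 656-nt insert yields the
#' 662-nt full-length transcript.
#'
#' @param insert A single RNA (or DNA, normalized) insert sequence, or a data
#'   frame with `id` and `residues` columns; each row is processed.
#' @param enzyme `"EcoRV"` or `"NruI"` (case insensitive).
#' @return A tibble with columns `id`, `insert`, `five_prime`, `three_prime`,
#'   `residues` (the full transcript), `insert_width` and `width`.
#' @examples
#' build_t7_construct("A", "NruI")$residues # "GGGAUCG"
#' @export
build_t7_construct <- function(insert, enzyme = c("EcoRV", "NruI")) {
  if (is.data.frame(insert)) {
    ids <- insert$id %||% paste0("insert", seq_len(nrow(insert)))
    seqs <- insert$residues
  } else {
    if (!is.character(insert)) stop_data("insert must be character or a data frame")
    ids <- names(insert) %||% paste0("insert", seq_along(insert))
    seqs <- unname(insert)
  }
  if (length(seqs) == 0 || any(!nzchar(seqs))) stop_data("insert must be non-empty")
  seqs <- rna_residues(seqs)
  if (!is.character(enzyme) || length(enzyme) < 1) {
    stop_usage("enzyme must be 'EcoRV' or 'NruI'")
  }
  key <- tolower(enzyme[1])
  three <- switch(key,
    "ecorv" = "GAC",
    "nrui" = "UCG",
    stop_usage("unknown enzyme '%s' (expected 'EcoRV' or 'NruI')", enzyme[1])
  )
  full <- paste0("GGG", seqs, three)
  tibble(
    id = ids,
    insert = seqs,
    five_prime = "GGG",
    three_prime = three,
    residues = full,
    insert_width = nchar(seqs),
    width = nchar(full)
  )
}

#' Concentration giving an equivalent amount of RNA
#'
#' When RNAs of different lengths are compared in a stoichiometric assay,
#' "the same amount" can mean the same number of nucleotide residues
#' (equimolar in moles of nucleotides) or the same mass. Under a common mean
#' residue mass both reduce to a length ratio, so the molar concentration of
#' the target RNA that matches `reference_concentration` of the reference RNA
#' is
#' \deqn{c_\mathrm{target} = c_\mathrm{ref} \cdot L_\mathrm{ref} / L_\mathrm{target}.}
#' For example, matching a 662-nt transcript at 1.25 uM with a 59-nt
#' transcript requires 1.25 x 662 / 59 = 14.0 uM.
#'
#' @param target_length Length(s) of the target RNA(s), nucleotides.
#' @param reference_length Length of the reference RNA, nucleotides.
#' @param reference_concentration Molar concentration of the reference (uM).
#' @param mode `"equimolar_nucleotides"` or `"equal_mass"`. Both use the same
#'   length-ratio formula; they are kept distinct so reports state which
#'   equivalence was intended (equal mass additionally assumes equal mean
#'   residue mass between the two RNAs).
#' @return Numeric vector of target concentrations in uM. The product
#'   `concentration x length` is conserved exactly.
#' @examples
#' equivalent_concentration(59, 662, 1.25) # 14.03 uM
#' equivalent_concentration(3720, 656, 1.25, mode = "equal_mass") # 0.22 uM
#' @seealso [mass_concentration()] for the ng/ul equivalent used with
#'   unstructured homopolymers sold by weight.
#' @export
equivalent_concentration <- function(target_length, reference_length,
                                     reference_concentration,
                                     mode = c("equimolar_nucleotides", "equal_mass")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_length) || any(target_length < 1)) {
    stop_data("target_length must be >= 1 nucleotide")
  }
  if (!is.numeric(reference_length) || length(reference_length) != 1L ||
      reference_length < 1) {
    stop_data("reference_length must be a single value >= 1 nucleotide")
  }
  if (!is.numeric(reference_concentration) || length(reference_concentration) != 1L ||
      reference_concentration <= 0) {
    stop_data("reference_concentration must be a single positive value (uM)")
  }
  reference_concentration * reference_length / target_length
}

#' Mass concentration equivalent of a molar RNA dose
#'
#' Converts a molar RNA concentration to the matching mass concentration,
#' `conc (uM) x length (nt) x residue_mass (g/mol) / 1000`, in ng/ul. This is
#' how a dose of a defined transcript is translated for material supplied by
#' weight (e.g. poly(U)): 1.25 uM of a 662-nt RNA corresponds to about
#' 265 ng/ul at the default mean residue mass.
#'
#' @param reference_length Reference RNA length, nucleotides.
#' @param reference_concentration Reference molar concentration, uM.
#' @param residue_mass Mean residue mass, g/mol per nucleotide. Default 320.5,
#'   a conventional mean for single-stranded RNA.
#' @return Mass concentration in ng/ul.
#' @examples
#' mass_concentration(662, 1.25) # ~265 ng/ul
#' @export
mass_concentration <- function(reference_length, reference_concentration,
                               residue_mass = 320.5) {
  if (!is.numeric(reference_length) || any(reference_length < 1)) {
    stop_data("reference_length must be >= 1 nucleotide")
  }
  if (!is.numeric(reference_concentration) || any(reference_concentration <= 0)) {
    stop_data("reference_concentration must be positive (uM)")
  }
  if (!is.numeric(residue_mass) || any(residue_mass <= 0)) {
    stop_data("residue_mass must be positive (g/mol)")
  }
  # uM * nt * g/mol = 1e-6 mol/L * g/mol * nt = 1e-6 g/L * nt = ug/L * nt;
  # ng/ul = ug/ml = 1e-3 ug/L  =>  divide by 1000.
  reference_concentration * reference_length * residue_mass / 1000
}

#' Dose table for a panel of RNAs against a reference
#'
#' Convenience wrapper that applies [equivalent_concentration()] to a tibble
#' of target RNAs, returning one row per target.
#'
#' @param targets Data frame with columns `id` and `width` (nt), e.g. from
#'   [read_fasta()] or [build_t7_construct()].
#' @param reference_length,reference_concentration,mode As in
#'   [equivalent_concentration()].
#' @return The input tibble with an added `concentration_uM` column.
#' @export
dose_table <- function(targets, reference_length, reference_concentration,
                       mode = c("equimolar_nucleotides", "equal_mass")) {
  mode <- match.arg(mode)
  if (!is.data.frame(targets) || !all(c("id", "width") %in% names(targets))) {
    stop_data("targets must be a data frame with 'id' and 'width' columns")
  }
  as_tibble(targets) |>
    mutate(concentration_uM = equivalent_concentration(
      .data$width, reference_length, reference_concentration, mode
    ))
}
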