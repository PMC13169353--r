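#' hBD-3 mature-peptide sequence
#'
#' One-letter sequence of the 45-residue human beta-defensin 3 mature
#' peptide (PDB entry 1KJ6, chain A; UniProt P81534 mature region).
#'
#' @format character scalar of length-45 sequence.
#' @export
hbd3_sequence <- "GIINTLQKYYCRVRGGRCAVLSCLPKEEQIGKCSTRGRKCCRRKK"

#' Bundled hBD-3 reference structure (synthetic coordinates)
#'
#' Reads the packaged CA-only model of hBD-3: residue identities follow the
#' real 45-residue mature-peptide sequence of PDB entry 1KJ6 chain A, while
#' the coordinates are synthetic idealized extended-chain placeholders (the
#' file is built offline, not downloaded). Residue counts and sequence-derived
#' quantities such as the formal charge are faithful; geometry is not.
#'
#' @return a `StructureModel` with 45 residues.
#' @export
hbd3_structure <- function() {
  read_structure(system.file("extdata", "hbd3_1kj6_ca_synthetic.pdb",
                             package = "contactmodes"))
}

#' Formal side-chain charge of a residue set
#'
#' Standard-state formal charges: Arg and Lys +1, Asp and Glu -1, His 0 (and
#' every other standard residue 0).
#'
#' @param x a `StructureModel` or a character vector of 3-letter residue
#'   names (one entry per residue).
#' @return integer total formal side-chain charge.
#' @export
formal_sidechain_charge <- function(x) {
  resnames <- if (inherits(x, "StructureModel"))
    residue_table(x)$residue_name else x
  charges <- c(ARG = 1L, LYS = 1L, ASP = -1L, GLU = -1L, HIS = 0L)
  sum(charges[toupper(resnames)], na.rm = TRUE)
}
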