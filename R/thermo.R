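# Seed-pairing stability from an embedded RNA nearest-neighbor stack table.
#
# Helix propagation free energies (kcal/mol, 37 degC) for Watson-Crick
# nearest-neighbor stacks (Xia-style values), indexed by the miRNA-strand
# dinucleotide 5'->3'; the complementary target dinucleotide is implied.
# No helix-initiation term is included: the feature only needs to rank and
# spread seeds, and the percentile scaling absorbs any constant offset.
.NN_STACK <- c(
  AA = -0.93, AU = -1.10, AG = -2.08, AC = -2.24,
  UA = -1.33, UU = -0.93, UG = -2.11, UC = -2.35,
  GA = -2.35, GU = -2.24, GG = -3.26, GC = -3.42,
  CA = -2.11, CU = -2.08, CG = -2.36, CC = -3.26)

#' Predicted seed-pairing stability (SPS)
#'
#' Free energy of the perfect seed:target helix, summed over
#' nearest-neighbor stacks of the embedded table: miRNA nucleotides 2-8 for
#' 8mer and 7mer-m8 sites (which pair position 8), nucleotides 2-7 for
#' 7mer-A1 and 6mer sites.  More negative values indicate more stable seed
#' pairing.
#'
#' @param member mature miRNA sequence (5'->3', >= 8 nt) or a
#'   `MirnaFamily` (its first member is used).
#' @param site_type one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @return Helix free energy in kcal/mol.
#' @export
seed_pairing_stability <- function(member, site_type = "8mer") {
  if (inherits(member, "MirnaFamily")) member <- member$members[[1L]]
  member <- .dna_to_rna(member)
  site_type <- match.arg(site_type, SITE_TYPES)
  if (nchar(member) < 8L) stop("mature sequence must be >= 8 nt")
  span_end <- if (site_type %in% c("8mer", "7mer-m8")) 8L else 7L
  helix <- substr(member, 2L, span_end)
  .check_rna(helix, "seed region", allow_n = FALSE)
  chars <- strsplit(helix, "", fixed = TRUE)[[1L]]
  dinucs <- paste0(chars[-length(chars)], chars[-1L])
  sum(.NN_STACK[dinucs])
}
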