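# Standard genetic code and junction translation.

# The standard (NCBI table 1) codon -> amino acid map. '*' marks stop.
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AA_ALPHABET <- sort(unique(GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]))

# codons per amino acid (including '*'), used by the amino-acid level pgen.
codons_for_aa <- function() split(names(GENETIC_CODE_STD), GENETIC_CODE_STD)

#' Translate nucleotide junctions in reading frame 1
#'
#' The junction reading frame starts at the first nucleotide (V segment
#' suffixes are supplied codon-aligned). Sequences whose length is not a
#' multiple of three translate to `NA`.
#'
#' @param nt character vector of nucleotide strings over `A`, `C`, `G`, `T`.
#' @return Character vector of amino-acid strings; stop codons appear as `*`.
#' @export
#' @examples
#' translate_junction(c("TGTGCC", "TGA"))
translate_junction <- function(nt) {
  nt <- toupper(nt)
  out <- rep(NA_character_, length(nt))
  len <- nchar(nt)
  ok <- !is.na(nt) & len > 0L & len %% 3L == 0L
  if (any(ok)) out[ok] <- translate_cpp(nt[ok], GENETIC_CODE_STD)
  out
}

is_productive_aa <- function(aa) {
  !is.na(aa) & nchar(aa) > 0L & !grepl("[*X]", aa)
}
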