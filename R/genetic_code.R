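# Standard nuclear genetic code (translation table 1) and the synonymous
# family structure used throughout: 18 degenerate amino-acid families,
# Met/Trp single-codon, three stops.

BASES <- c("A", "C", "G", "T")

#' The 64 codons in the DNA alphabet
#'
#' Lexicographic order over A, C, G, T.
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

# codon -> one-letter amino acid, * for stop (standard code)
.genetic_code <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"

# one-letter -> three-letter amino-acid labels
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' Translate a codon to its amino acid
#'
#' @param codon Character vector of codons (DNA alphabet).
#' @return One-letter amino-acid codes, `"*"` for stop codons.
#' @export
codon_to_aa <- function(codon) {
  unname(.genetic_code[toupper(codon)])
}

#' Synonymous codon families of the standard genetic code
#'
#' The 18 degenerate families (nine 2-fold, one 3-fold, five 4-fold and
#' three 6-fold); Met and Trp are single-codon and excluded, as are stops.
#'
#' @return Named list mapping one-letter amino-acid codes to their codons.
#' @export
synonymous_families <- function() {
  aa <- codon_to_aa(all_codons())
  fams <- split(all_codons(), aa)
  fams <- fams[!names(fams) %in% c("*", "M", "W")]
  fams[order(names(fams))]
}

#' Degeneracy (family size) per degenerate amino acid
#' @return Named integer vector over the 18 degenerate amino acids.
#' @export
family_degeneracy <- function() {
  vapply(synonymous_families(), length, integer(1))
}

#' Sense codons used for codon-bias indices
#'
#' The 59-codon universe: all sense codons excluding Met (ATG), Trp (TGG)
#' and the three stops.
#' @return Character vector of length 59.
#' @export
sense_codons <- function() {
  unlist(synonymous_families(), use.names = FALSE)
}

# normalize a codon/sequence to the internal DNA alphabet
.to_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Render DNA codons in the RNA alphabet (T to U)
#' @param x Character vector.
#' @return `x` with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))
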