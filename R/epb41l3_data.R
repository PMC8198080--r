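# Bundled study tables for the EPB41L3 gene (34 coding transcripts from
# five mammalian species): per-species RSCU columns, pooled dinucleotide
# frequencies and odds ratios, and the five species' tRNA gene-count
# tables with the preferred codon noted per amino-acid family.

EPB41L3_SPECIES <- c("homo_sapiens", "rattus_norvegicus", "bos_taurus",
                     "mus_musculus", "pongo_abelii")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cubtools")
  if (path == "") stop("bundled data file not found: ", file)
  path
}

#' Published per-species RSCU values for EPB41L3
#'
#' RSCU over the 59 sense codons for each of the five mammalian species
#' plus the published cross-species average column.
#'
#' @return Named list of `rscu_table` objects (five species plus
#'   `"average"`).
#' @export
epb41l3_rscu_tables <- function() {
  df <- utils::read.delim(.extdata("epb41l3_rscu.tsv"),
                          stringsAsFactors = FALSE)
  cols <- c(EPB41L3_SPECIES, "average")
  out <- lapply(cols, function(sp) {
    rscu_from_values(stats::setNames(df[[sp]], df$codon), label = sp)
  })
  stats::setNames(out, cols)
}

#' Published pooled dinucleotide frequencies for EPB41L3
#'
#' Observed relative frequencies of the 16 dinucleotides across the 34
#' transcripts, with the published odds ratios (uniform 1/16 expectation).
#'
#' @return Data frame with columns `dinucleotide`, `observed`,
#'   `odds_ratio`.
#' @export
epb41l3_dinucleotides <- function() {
  utils::read.delim(.extdata("epb41l3_dinucleotides.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published tRNA gene-count tables for the five species
#'
#' GtRNAdb-derived isotype gene counts per amino acid, with the preferred
#' EPB41L3 codon per family as published. The house-mouse Met row is read
#' in non-strict mode: its stated total (13) disagrees with its itemized
#' counts (9 + 8); the itemized counts are kept.
#'
#' @param species One of `"homo_sapiens"`, `"rattus_norvegicus"`,
#'   `"bos_taurus"`, `"mus_musculus"`, `"pongo_abelii"`, or `"all"`.
#' @return A `trna_table`, or a named list of them for `"all"`.
#' @export
epb41l3_trna_tables <- function(species = "all") {
  read_one <- function(sp) {
    suppressWarnings(
      read_trna_counts(.extdata(paste0("trna_", sp, ".tsv")),
                       species = sp, strict = FALSE))
  }
  if (identical(species, "all")) {
    stats::setNames(lapply(EPB41L3_SPECIES, read_one), EPB41L3_SPECIES)
  } else {
    species <- match.arg(species, EPB41L3_SPECIES)
    read_one(species)
  }
}
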