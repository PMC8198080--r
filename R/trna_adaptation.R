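# Matching preferred codons to isoacceptor tRNA pools: each amino acid's
# highest-RSCU codon is paired with its strict Watson-Crick cognate
# anticodon (reverse complement, DNA alphabet, 5'->3' as in GtRNAdb) and
# tested against the most abundant isotype in the species' gene table.
# Wobble decoding (G:U, inosine) is deliberately not modeled.

#' Watson-Crick cognate anticodon of a codon
#'
#' Reverse complement in the DNA alphabet. An involution: applying it
#' twice returns the input.
#'
#' @param codon Character vector of length-3 codons over A, C, G, T.
#' @return Anticodons, 5'->3'.
#' @export
anticodon_for <- function(codon) {
  codon <- .to_dna(codon)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    stop("codons must be length 3 over A, C, G, T")
  }
  comp <- chartr("ACGT", "TGCA", codon)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Per-amino-acid totals of a tRNA gene table
#'
#' @param trna A `trna_table` from [read_trna_counts()] or
#'   [generate_trna_table()].
#' @return Named numeric vector of gene-count totals per amino acid
#'   (one-letter codes). Empty families total 0 with a warning.
#' @export
isotype_totals <- function(trna) {
  tot <- tapply(trna$count, trna$amino_acid, sum)
  if (any(tot == 0)) {
    warning("amino acid(s) with zero tRNA genes: ",
            paste(names(tot)[tot == 0], collapse = ", "))
  }
  out <- stats::setNames(as.numeric(tot), names(tot))
  out[unique(trna$amino_acid)]
}

#' Codon-anticodon adaptation report
#'
#' For each degenerate amino acid, the preferred codon (maximum RSCU;
#' ties resolved to the lexicographically first codon and noted), its
#' cognate anticodon and gene count, the most abundant isotype(s), and
#' whether the cognate is optimal (its count equals the family maximum
#' and is positive). Met and Trp are reported descriptively but excluded
#' from optimality statistics.
#'
#' @param rscu_table An `rscu_table` for the species.
#' @param trna A `trna_table` for the same species.
#' @return Object of class `adaptation_report`: data frame with columns
#'   `amino_acid`, `preferred_codon`, `preferred_rscu`, `tied_preference`,
#'   `cognate_anticodon`, `cognate_count`, `max_isotype`, `max_count`,
#'   `is_optimal`, `family_total`, `in_statistics`.
#' @export
adaptation_report <- function(rscu_table, trna) {
  vals <- stats::setNames(rscu_table$rscu, rscu_table$codon)
  fams <- synonymous_families()
  single <- list(M = "ATG", W = "TGG")
  one_row <- function(aa, cods, in_stats) {
    sub <- trna[trna$amino_acid == aa, , drop = FALSE]
    if (nrow(sub) == 0L) stop("amino acid ", aa, " missing from tRNA table")
    if (in_stats) {
      v <- vals[cods]
      if (all(is.na(v))) return(NULL)
      top <- cods[which(v == max(v, na.rm = TRUE))]
      pref <- sort(top)[1L]
      tied <- length(top) > 1L
      prscu <- unname(v[pref])
    } else {
      pref <- cods
      tied <- FALSE
      prscu <- NA_real_
    }
    cog <- anticodon_for(pref)
    cnt <- sub$count[match(cog, sub$anticodon)]
    if (is.na(cnt)) cnt <- 0L
    mx <- max(sub$count)
    data.frame(
      amino_acid = aa,
      preferred_codon = pref,
      preferred_rscu = prscu,
      tied_preference = tied,
      cognate_anticodon = cog,
      cognate_count = as.integer(cnt),
      max_isotype = paste(sub$anticodon[sub$count == mx], collapse = "/"),
      max_count = as.integer(mx),
      is_optimal = cnt > 0L && cnt == mx,
      family_total = sum(sub$count),
      in_statistics = in_stats,
      stringsAsFactors = FALSE
    )
  }
  rows <- c(
    lapply(names(fams), function(aa) one_row(aa, fams[[aa]], TRUE)),
    lapply(names(single), function(aa) {
      if (aa %in% trna$amino_acid) one_row(aa, single[[aa]], FALSE) else NULL
    })
  )
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  if (any(out$tied_preference)) {
    message("tied preferred codon for: ",
            paste(out$amino_acid[out$tied_preference], collapse = ", "))
  }
  structure(out, class = c("adaptation_report", "data.frame"))
}
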