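# Relative synonymous codon usage: RSCU_ij = x_ij * n_i / sum_j x_ij where
# n_i is the degeneracy of family i. Defined over the 59 sense codons
# (Met, Trp and stops excluded). Family values sum to the degeneracy.

#' RSCU from a codon count table
#'
#' Families with zero total have undefined RSCU and are flagged `ABSENT`.
#'
#' @param counts A `codon_counts` object (stop counts are ignored).
#' @param label Optional label (species or dataset name).
#' @return Object of class `rscu_table`: data frame with columns `codon`,
#'   `amino_acid`, `count`, `rscu`, `flag`; attribute `label`.
#' @export
rscu <- function(counts, label = NA_character_) {
  fams <- synonymous_families()
  rows <- lapply(names(fams), function(aa) {
    cods <- fams[[aa]]
    x <- counts$counts[cods]
    n <- sum(x)
    val <- if (n == 0L) rep(NA_real_, length(cods)) else
      as.numeric(x) * length(cods) / n
    data.frame(codon = cods, amino_acid = aa, count = as.integer(x),
               rscu = val, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$flag <- classify_rscu(df$rscu)
  structure(df, class = c("rscu_table", "data.frame"), label = label)
}

#' Build an RSCU table from precomputed values
#'
#' For published per-codon RSCU columns where raw counts are unavailable.
#'
#' @param values Named numeric vector of RSCU values keyed by codon
#'   (DNA or RNA alphabet); must cover the 59 sense codons.
#' @param label Optional label.
#' @return Object of class `rscu_table` (counts are `NA`).
#' @export
rscu_from_values <- function(values, label = NA_character_) {
  nm <- .to_dna(names(values))
  missing <- setdiff(sense_codons(), nm)
  if (length(missing) > 0L) {
    stop("RSCU values missing for: ", paste(missing, collapse = ", "))
  }
  v <- as.numeric(values)[match(sense_codons(), nm)]
  df <- data.frame(
    codon = sense_codons(),
    amino_acid = codon_to_aa(sense_codons()),
    count = NA_integer_,
    rscu = v,
    stringsAsFactors = FALSE
  )
  df$flag <- classify_rscu(df$rscu)
  structure(df, class = c("rscu_table", "data.frame"), label = label)
}

#' Classify RSCU values
#'
#' Strict inequalities: `UNDERREPRESENTED` below 0.6, `OVERREPRESENTED`
#' above 1.6, `PREFERRED` above 1 (and at most 1.6), otherwise `UNBIASED`.
#' Boundary values fall to the non-extreme class; `NA` maps to `ABSENT`.
#'
#' @param rscu Numeric RSCU values (or an `rscu_table`).
#' @return Character vector of flags.
#' @export
classify_rscu <- function(rscu) {
  if (is.data.frame(rscu)) rscu <- rscu$rscu
  out <- ifelse(rscu < 0.6, "UNDERREPRESENTED",
         ifelse(rscu > 1.6, "OVERREPRESENTED",
         ifelse(rscu > 1, "PREFERRED", "UNBIASED")))
  out[is.na(rscu)] <- "ABSENT"
  as.character(out)
}

.rscu_matrix <- function(tables) {
  labels <- vapply(seq_along(tables), function(i) {
    lb <- attr(tables[[i]], "label")
    if (is.null(lb) || is.na(lb)) paste0("table", i) else lb
  }, character(1))
  m <- vapply(tables, function(t) {
    t$rscu[match(sense_codons(), t$codon)]
  }, numeric(length(sense_codons())))
  dimnames(m) <- list(sense_codons(), labels)
  m
}

#' Average RSCU across tables
#'
#' `mode = "mean"` is the unweighted arithmetic mean of per-table values
#' (codons absent in a table are dropped from that codon's mean with a
#' note). `mode = "pooled"` recomputes RSCU from the summed codon counts,
#' which weights tables by their codon totals; it requires count-bearing
#' tables.
#'
#' @param tables List of `rscu_table` objects over the same codon set.
#' @param mode `"mean"` or `"pooled"`.
#' @param label Label for the output table.
#' @return An `rscu_table`.
#' @export
average_rscu <- function(tables, mode = c("mean", "pooled"),
                         label = "average") {
  mode <- match.arg(mode)
  if (length(tables) < 2L) stop("need at least two RSCU tables")
  if (mode == "pooled") {
    cnt <- vapply(tables, function(t) {
      if (anyNA(t$count)) stop("pooled mode requires count-bearing tables")
      as.numeric(t$count[match(sense_codons(), t$codon)])
    }, numeric(length(sense_codons())))
    pooled <- codon_count_table(
      stats::setNames(rowSums(cnt), sense_codons()))
    return(rscu(pooled, label = label))
  }
  m <- .rscu_matrix(tables)
  if (anyNA(m)) {
    message("codons absent in some tables are averaged over defined values")
  }
  v <- rowMeans(m, na.rm = TRUE)
  rscu_from_values(v, label = label)
}

#' Codons preferred in every table
#'
#' The cross-species shared-preference set. `inclusive = TRUE` (default)
#' admits codons with RSCU >= 1 in every table, which is the reading under
#' which the published 14-codon shared set for mammalian EPB41L3
#' transcripts is reproduced; `inclusive = FALSE` applies the strict > 1
#' rule used for per-table preferred flags.
#'
#' @param tables List of `rscu_table` objects.
#' @param inclusive Use >= 1 rather than > 1.
#' @return Character vector of codons.
#' @export
shared_preferred <- function(tables, inclusive = TRUE) {
  if (length(tables) == 0L) stop("no RSCU tables supplied")
  m <- .rscu_matrix(tables)
  keep <- if (inclusive) {
    apply(m >= 1, 1L, function(r) all(!is.na(r)) && all(r))
  } else {
    apply(m > 1, 1L, function(r) all(!is.na(r)) && all(r))
  }
  rownames(m)[keep]
}

#' Hierarchical clustering of RSCU tables for heatmap ordering
#'
#' Agglomerative clustering (average linkage, Euclidean distance) over
#' codon rows and species columns. Deterministic given input order;
#' `stats::hclust` breaks ties by lowest index.
#'
#' @param tables List of at least two `rscu_table` objects.
#' @return List with `matrix` (codons x species), `row_hclust`,
#'   `col_hclust`, `codon_order`, `species_order`.
#' @export
rscu_cluster <- function(tables) {
  if (length(tables) < 2L) stop("need at least two RSCU tables")
  m <- .rscu_matrix(tables)
  if (anyNA(m)) stop("cannot cluster with undefined RSCU values")
  rh <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  ch <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "average")
  list(matrix = m,
       row_hclust = rh, col_hclust = ch,
       codon_order = rownames(m)[rh$order],
       species_order = colnames(m)[ch$order])
}
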