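# Nucleotide composition by codon position: overall base percentages,
# third-position percentages, GC1/GC2/GC3/GC12, and dataset summaries.

#' Composition profile of one coding sequence
#'
#' Percentages are computed over the whole CDS; the terminal stop codon is
#' included by default (whole-transcript convention). Third-position
#' metrics use one base per codon.
#'
#' @param bases A single nucleotide string whose length is a multiple of 3.
#' @param id Optional identifier carried into the output.
#' @param include_stop Keep the terminal stop codon in the tallies.
#' @return One-row data frame with columns `id`, `pct_A`, `pct_T`, `pct_G`,
#'   `pct_C`, `pct_A3`, `pct_T3`, `pct_G3`, `pct_C3`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc_overall`, `au_overall`. All values are percentages.
#' @export
composition_profile <- function(bases, id = NA_character_, include_stop = TRUE) {
  cods <- codon_split(bases)
  if (length(cods) == 0L) stop("zero-length sequence")
  if (!include_stop && cods[length(cods)] %in% STOP_CODONS) {
    cods <- cods[-length(cods)]
    if (length(cods) == 0L) stop("sequence is a bare stop codon")
  }
  pos <- lapply(1:3, function(p) substr(cods, p, p))
  allb <- unlist(pos, use.names = FALSE)
  pct <- function(x, b) 100 * sum(x %in% b) / length(x)
  gc_at <- function(p) pct(pos[[p]], c("G", "C"))
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  data.frame(
    id = id,
    pct_A = pct(allb, "A"), pct_T = pct(allb, "T"),
    pct_G = pct(allb, "G"), pct_C = pct(allb, "C"),
    pct_A3 = pct(pos[[3]], "A"), pct_T3 = pct(pos[[3]], "T"),
    pct_G3 = pct(pos[[3]], "G"), pct_C3 = pct(pos[[3]], "C"),
    gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
    gc_overall = pct(allb, c("G", "C")),
    au_overall = pct(allb, c("A", "T")),
    stringsAsFactors = FALSE
  )
}

#' Composition profiles for every record of a coding-sequence set
#'
#' @param cds A coding-sequence set data frame.
#' @param include_stop Passed to [composition_profile()].
#' @return Data frame, one row per sequence, with a `species` column.
#' @export
composition_profiles <- function(cds, include_stop = TRUE) {
  out <- do.call(rbind, Map(composition_profile, cds$bases, cds$id,
                            include_stop = include_stop))
  rownames(out) <- NULL
  cbind(out[, "id", drop = FALSE], species = cds$species,
        out[, setdiff(names(out), "id")])
}

#' Summarize composition profiles across a dataset
#'
#' Per field: mean, sample standard deviation (n-1 denominator), minimum
#' and maximum. With a single profile the SD is `NA`.
#'
#' @param profiles Data frame of profiles from [composition_profiles()].
#' @return Data frame with columns `field`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_profiles <- function(profiles) {
  if (nrow(profiles) == 0L) stop("no profiles to summarize")
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  data.frame(
    field = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = if (nrow(profiles) >= 2L) vapply(num, stats::sd, numeric(1))
         else rep(NA_real_, ncol(num)),
    min = vapply(num, min, numeric(1)),
    max = vapply(num, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
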