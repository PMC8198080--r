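# Dinucleotide relative abundance: observed frequencies over overlapping
# windows, odds ratios against an expected model, and the conventional
# under/over-representation classes (< 0.78 under, > 1.23 over).

DINUCLEOTIDES <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                   "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

#' Observed dinucleotide frequencies of a sequence set
#'
#' Overlapping windows of width 2, step 1, counted within each record
#' (windows never span record boundaries), pooled over all records and
#' normalized by the pooled window count.
#'
#' @param x A coding-sequence set data frame or character vector of
#'   nucleotide strings.
#' @return Named numeric vector over the 16 dinucleotides, summing to 1.
#' @export
dinucleotide_frequencies <- function(x) {
  bases <- if (is.data.frame(x)) x$bases else .to_dna(x)
  if (length(bases) == 0L) stop("no sequences")
  if (any(nchar(bases) < 2L)) stop("sequence shorter than 2 bases")
  counts <- stats::setNames(numeric(16), DINUCLEOTIDES)
  for (b in bases) {
    n <- nchar(b)
    w <- substring(b, 1:(n - 1L), 2:n)
    tab <- table(factor(w, levels = DINUCLEOTIDES))
    counts <- counts + as.numeric(tab)
  }
  counts / sum(counts)
}

#' Dinucleotide odds ratios and representation classes
#'
#' `expected_mode = "uniform"` takes every expected frequency as 1/16;
#' `"mono_product"` uses the product of pooled mononucleotide frequencies
#' f(X)f(Y), the conventional relative-abundance denominator. With an
#' expected frequency of zero the ratio is undefined and flagged `NA`.
#'
#' @param observed Named frequencies over the 16 dinucleotides (sum 1), as
#'   from [dinucleotide_frequencies()].
#' @param expected_mode `"uniform"` or `"mono_product"`.
#' @param mono_freqs Named frequencies over A, C, G, T; required for
#'   `"mono_product"`.
#' @return Object of class `dinuc_profile`: data frame with columns
#'   `dinucleotide`, `observed`, `expected`, `odds_ratio`, `class`.
#' @export
odds_ratios <- function(observed,
                        expected_mode = c("uniform", "mono_product"),
                        mono_freqs = NULL) {
  expected_mode <- match.arg(expected_mode)
  observed <- observed[DINUCLEOTIDES]
  if (any(is.na(observed))) stop("observed must cover all 16 dinucleotides")
  if (abs(sum(observed) - 1) > 1e-6) {
    stop("observed frequencies must sum to 1")
  }
  expected <- if (expected_mode == "uniform") {
    stats::setNames(rep(1 / 16, 16), DINUCLEOTIDES)
  } else {
    if (is.null(mono_freqs)) stop("mono_freqs required for mono_product mode")
    f <- mono_freqs[BASES]
    stats::setNames(
      f[substr(DINUCLEOTIDES, 1, 1)] * f[substr(DINUCLEOTIDES, 2, 2)],
      DINUCLEOTIDES)
  }
  ratio <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(
    data.frame(
      dinucleotide = DINUCLEOTIDES,
      observed = as.numeric(observed),
      expected = as.numeric(expected),
      odds_ratio = as.numeric(ratio),
      class = classify_dinucleotides(ratio),
      stringsAsFactors = FALSE
    ),
    class = c("dinuc_profile", "data.frame"),
    expected_mode = toupper(expected_mode)
  )
}

#' Classify dinucleotide odds ratios
#'
#' Strict inequalities: UNDER below 0.78, OVER above 1.23, the boundary
#' values themselves are NORMAL.
#'
#' @param ratio Numeric odds ratios (or a `dinuc_profile`).
#' @return Character vector among UNDER, NORMAL, OVER (`NA` propagates).
#' @export
classify_dinucleotides <- function(ratio) {
  if (is.data.frame(ratio)) ratio <- ratio$odds_ratio
  out <- ifelse(ratio < 0.78, "UNDER", ifelse(ratio > 1.23, "OVER", "NORMAL"))
  as.character(out)
}
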