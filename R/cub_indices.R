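# Codon-usage-bias indices: Wright's effective number of codons (ENc),
# the expected ENc-GC3 curve, the codon adaptation index (CAI), and the
# P2 translational-selection index.

#' Wright's effective number of codons
#'
#' Per synonymous family with total count n >= 2, the homozygosity
#' estimator is F = (n * sum(p_j^2) - 1) / (n - 1) with p_j the within-
#' family codon proportions. Class means over the degeneracy classes
#' (nine 2-fold, one 3-fold, five 4-fold, three 6-fold families) give
#' ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to the definitional
#' range [20, 61] (20 = one codon per amino acid, 61 = uniform usage).
#'
#' Families with n < 2 or a non-positive F estimate are excluded from
#' their class mean. A missing 3-fold class (Ile unused) is imputed as
#' (F2 + F4)/2; any other empty class is an error (the gene is too short
#' or degenerate to score).
#'
#' @param counts A `codon_counts` object; stop, Met and Trp codons are
#'   never used.
#' @return Object of class `enc_result`: list with `enc`, `class_means`,
#'   `per_family_F`, `missing_classes`.
#' @export
enc <- function(counts) {
  fams <- synonymous_families()
  deg <- family_degeneracy()
  Fhat <- vapply(names(fams), function(aa) {
    x <- as.numeric(counts$counts[fams[[aa]]])
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }, numeric(1))
  classes <- c(2, 3, 4, 6)
  class_means <- vapply(classes, function(k) {
    vals <- Fhat[deg == k]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(class_means) <- paste0("F", classes)
  missing <- names(class_means)[is.na(class_means)]
  if (is.na(class_means["F3"]) &&
      !is.na(class_means["F2"]) && !is.na(class_means["F4"])) {
    class_means["F3"] <- (class_means["F2"] + class_means["F4"]) / 2
  }
  if (anyNA(class_means)) {
    stop("cannot compute ENc: empty degeneracy class ",
         paste(names(class_means)[is.na(class_means)], collapse = ", "))
  }
  value <- 2 + 9 / class_means["F2"] + 1 / class_means["F3"] +
    5 / class_means["F4"] + 3 / class_means["F6"]
  structure(
    list(enc = unname(min(max(value, 20), 61)),
         class_means = class_means,
         per_family_F = Fhat,
         missing_classes = missing),
    class = "enc_result"
  )
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENc = %.3f (class means: %s)\n", x$enc,
              paste(sprintf("%s=%.3f", names(x$class_means), x$class_means),
                    collapse = ", ")))
  invisible(x)
}

#' Expected ENc under GC3 composition alone
#'
#' The null curve ENc(s) = 2 + s + 29 / (s^2 + (1 - s)^2), where s is the
#' GC fraction at third codon positions. Genes whose codon usage is shaped
#' only by compositional (mutational) pressure fall on this curve; points
#' substantially below it indicate selection.
#'
#' @param s GC3 fraction(s) in [0, 1].
#' @return Expected ENc value(s).
#' @export
enc_expected <- function(s) {
  if (any(s < 0 | s > 1)) stop("GC3 fraction must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon adaptation index
#'
#' Relative adaptiveness w_ij = f_ij / max_j f_ij within each synonymous
#' family, from a reference usage table; CAI is the geometric mean of w
#' over all sense codons of the query excluding Met, Trp and stops,
#' weighted by the query's codon counts. Zero reference counts are
#' replaced by a 0.5-count pseudo-frequency before computing w.
#'
#' @param counts A `codon_counts` object for the query.
#' @param reference A `ref_usage` table covering all 64 codons.
#' @return Object of class `cai_result`: list with `cai`, `per_codon_w`,
#'   `codons_used`.
#' @export
cai <- function(counts, reference) {
  stopifnot(inherits(reference, "ref_usage"))
  raw <- stats::setNames(as.numeric(reference$count), reference$codon)
  fams <- synonymous_families()
  for (aa in names(fams)) {
    if (all(raw[fams[[aa]]] == 0)) {
      stop("reference has no usage for amino-acid family ", aa)
    }
  }
  adj <- ifelse(raw == 0, 0.5, raw)
  freq <- 1000 * adj / sum(adj)
  w <- stats::setNames(rep(NA_real_, length(sense_codons())), sense_codons())
  for (aa in names(fams)) {
    cods <- fams[[aa]]
    w[cods] <- freq[cods] / max(freq[cods])
  }
  x <- counts$counts[sense_codons()]
  used <- sum(x)
  if (used == 0) stop("query has no sense codons in degenerate families")
  logcai <- sum(x * log(w)) / used
  structure(
    list(cai = exp(logcai), per_codon_w = w, codons_used = unname(used)),
    class = "cai_result"
  )
}

# codon classes for P2: W = A/T, S = G/C at positions 1-2; third base T or C
P2_CLASSES <- list(
  WWU = c("AAT", "ATT", "TAT", "TTT"),
  WWC = c("AAC", "ATC", "TAC", "TTC"),
  SSU = c("CCT", "CGT", "GCT", "GGT"),
  SSC = c("CCC", "CGC", "GCC", "GGC")
)

#' P2 translational-selection index
#'
#' P2 = (WWC + SSU) / (WWY + SSY), where each symbol is the class mean
#' over its four codons (W = A/T and S = G/C at codon positions 1-2, the
#' third base U or C; Y = U or C) and WWY, SSY are means over the 8-codon
#' unions, so that P2 = 2 (WWC + SSU) / (WWU + WWC + SSU + SSC). A value
#' above 0.5 is read as translational-selection bias. `mode = "rscu"`
#' takes class means of RSCU values (the reading under which published
#' per-species tables for EPB41L3 are reproduced); `mode = "counts"` is
#' the classic count-based variant.
#'
#' @param table An `rscu_table` (count-bearing for `mode = "counts"`).
#' @param mode `"rscu"` or `"counts"`.
#' @return Object of class `p2_result`: list with `sSU`, `wWU`, `sSC`,
#'   `wWC`, `p2`, `mode`.
#' @export
p2 <- function(table, mode = c("rscu", "counts")) {
  mode <- match.arg(mode)
  vals <- if (mode == "rscu") {
    stats::setNames(table$rscu, table$codon)
  } else {
    if (anyNA(table$count)) stop("counts mode requires count-bearing table")
    stats::setNames(as.numeric(table$count), table$codon)
  }
  cls <- vapply(P2_CLASSES, function(cods) mean(vals[cods]), numeric(1))
  if (anyNA(cls)) stop("undefined values in P2 codon classes")
  denom <- sum(cls)
  if (denom == 0) stop("P2 denominator is zero")
  structure(
    list(sSU = unname(cls["SSU"]), wWU = unname(cls["WWU"]),
         sSC = unname(cls["SSC"]), wWC = unname(cls["WWC"]),
         p2 = unname(2 * (cls["WWC"] + cls["SSU"]) / denom),
         mode = toupper(mode)),
    class = "p2_result"
  )
}
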