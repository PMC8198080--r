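# Evolutionary-force diagnostics: the neutrality regression of GC12 on
# GC3, PR2 parity coordinates at third codon positions, deviations from
# the expected ENc-GC3 curve, and correlation/regression tables.

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1-2) on GC3
#' across sequences. A slope near 1 indicates mutational (compositional)
#' pressure acting uniformly across positions; a slope near 0 indicates
#' selection constraining positions 1-2. The slope, times 100, is
#' reported as the mutational contribution in percent; its complement as
#' the selection contribution.
#'
#' @param gc12 Numeric vector (percent), or a profile data frame with
#'   `gc12` and `gc3` columns.
#' @param gc3 Numeric vector (percent); ignored when `gc12` is a data frame.
#' @return Object of class `neutrality_result`: list with `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`, `mutation_pct`,
#'   `selection_pct`.
#' @export
neutrality <- function(gc12, gc3 = NULL) {
  if (is.data.frame(gc12)) {
    gc3 <- gc12$gc3
    gc12 <- gc12$gc12
  }
  ok <- stats::complete.cases(gc12, gc3)
  gc12 <- gc12[ok]; gc3 <- gc3[ok]
  n <- length(gc12)
  if (n < 3L) stop("need at least 3 points")
  if (stats::sd(gc3) == 0) stop("DEGENERATE_X: GC3 is constant")
  fit <- stats::lm(gc12 ~ gc3)
  ct <- stats::cor.test(gc3, gc12, method = "pearson")
  slope <- unname(stats::coef(fit)[2L])
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         n = n,
         mutation_pct = 100 * slope,
         selection_pct = 100 * (1 - slope)),
    class = "neutrality_result"
  )
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf(
    "Neutrality: slope %.4f (r = %.4f, p = %.3g, n = %d)\n  mutation %.2f%% / selection %.2f%%\n",
    x$slope, x$pearson_r, x$p_value, x$n, x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' PR2 parity coordinates at third codon positions
#'
#' AT bias A3/(A3+T3) against GC bias G3/(G3+C3); (0.5, 0.5) is the
#' parity point expected with no strand or selection asymmetry. Computed
#' per sequence and overall from the dataset mean third-position
#' percentages. All third positions are used, not only four-fold
#' degenerate families (`fourfold_only = TRUE` restricts to third bases
#' of four-fold family codons).
#'
#' @param profiles Profile data frame from [composition_profiles()], or a
#'   coding-sequence set when `fourfold_only = TRUE`.
#' @param fourfold_only Restrict to third positions of four-fold
#'   degenerate codons (requires a coding-sequence set).
#' @return List with `per_sequence` (data frame `id`, `at_bias`,
#'   `gc_bias`) and `overall` (named vector).
#' @export
pr2 <- function(profiles, fourfold_only = FALSE) {
  if (fourfold_only) {
    if (!"bases" %in% names(profiles)) {
      stop("fourfold_only mode needs a coding-sequence set with bases")
    }
    four <- names(family_degeneracy())[family_degeneracy() == 4]
    third <- lapply(profiles$bases, function(b) {
      cods <- codon_split(b)
      cods <- cods[codon_to_aa(cods) %in% four]
      substr(cods, 3, 3)
    })
    pcts <- t(vapply(third, function(tp) {
      if (length(tp) == 0L) return(rep(NA_real_, 4))
      100 * vapply(BASES, function(b) mean(tp == b), numeric(1))
    }, numeric(4)))
    profiles <- data.frame(id = profiles$id,
                           pct_A3 = pcts[, 1], pct_C3 = pcts[, 2],
                           pct_G3 = pcts[, 3], pct_T3 = pcts[, 4])
  }
  bias <- function(a, t, g, c) {
    at <- ifelse(a + t > 0, a / (a + t), NA_real_)
    gc <- ifelse(g + c > 0, g / (g + c), NA_real_)
    c(at_bias = at, gc_bias = gc)
  }
  per <- data.frame(
    id = profiles$id,
    at_bias = with(profiles, ifelse(pct_A3 + pct_T3 > 0,
                                    pct_A3 / (pct_A3 + pct_T3), NA_real_)),
    gc_bias = with(profiles, ifelse(pct_G3 + pct_C3 > 0,
                                    pct_G3 / (pct_G3 + pct_C3), NA_real_)),
    stringsAsFactors = FALSE
  )
  mn <- colMeans(profiles[, c("pct_A3", "pct_T3", "pct_G3", "pct_C3")],
                 na.rm = TRUE)
  overall <- bias(mn[["pct_A3"]], mn[["pct_T3"]],
                  mn[["pct_G3"]], mn[["pct_C3"]])
  list(per_sequence = per, overall = overall)
}

#' Deviations from the expected ENc-GC3 curve
#'
#' @param enc_values Observed ENc per sequence.
#' @param gc3_values GC3 fractions in [0, 1] (percentages are accepted
#'   and divided by 100).
#' @return List with `points` (data frame `gc3`, `enc_observed`,
#'   `enc_expected`, `deviation`) and `fraction_below_curve`.
#' @export
enc_gc3_points <- function(enc_values, gc3_values) {
  if (length(enc_values) != length(gc3_values)) {
    stop("enc_values and gc3_values must have equal length")
  }
  s <- ifelse(gc3_values > 1, gc3_values / 100, gc3_values)
  expd <- enc_expected(s)
  dev <- enc_values - expd
  list(
    points = data.frame(gc3 = s, enc_observed = enc_values,
                        enc_expected = expd, deviation = dev),
    fraction_below_curve = mean(dev < 0)
  )
}

.star <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise Pearson correlation table with significance stars
#'
#' Two-tailed p-values from the t transform of r on n - 2 degrees of
#' freedom; no multiple-testing correction. Constant columns yield `NA`.
#'
#' @param features Data frame of per-sequence numeric variables.
#' @return Object of class `correlation_table`: list with matrices `r`,
#'   `p`, `stars`, and `n`.
#' @export
correlation_table <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  k <- ncol(num)
  if (nrow(num) < 3L) stop("need at least 3 rows")
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(names(num), names(num))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 0; next }
    x <- num[[i]]; y <- num[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i, j] <- NA_real_
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- matrix(.star(p), k, k, dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nrow(num)),
            class = "correlation_table")
}

#' OLS regressions of ENc on each compositional feature
#'
#' One fitted line per feature, regressing ENc on that feature, with the
#' sign of the slope reported.
#'
#' @param features Data frame of per-sequence numeric variables.
#' @param enc_col Name of the column holding observed ENc.
#' @return Data frame with columns `feature`, `slope`, `intercept`,
#'   `sign`.
#' @export
enc_regressions <- function(features, enc_col = "enc") {
  if (!enc_col %in% names(features)) stop("no column ", enc_col)
  y <- features[[enc_col]]
  others <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                    enc_col)
  rows <- lapply(others, function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0) stop("constant feature: ", f)
    co <- stats::coef(stats::lm(y ~ x))
    data.frame(feature = f, slope = unname(co[2L]),
               intercept = unname(co[1L]),
               sign = ifelse(co[2L] > 0, "positive",
                             ifelse(co[2L] < 0, "negative", "zero")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
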