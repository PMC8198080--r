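# Synthetic coding-sequence generation with known codon-usage structure.
# Every generator is driven by a single integer seed through a local RNG
# scope (the caller's RNG state is untouched) and emits sequences that
# always pass validate_cds: bodies carry zero stop-codon weight, each CDS
# is ATG + body + one stop codon.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

.default_aa_probs <- function() {
  # uniform over the 18 degenerate families; Met/Trp at low weight so
  # every RSCU family is exercised without single-codon families
  # dominating
  w <- stats::setNames(rep(1, 18), names(synonymous_families()))
  w <- c(w, M = 0.2, W = 0.2)
  w / sum(w)
}

.codon_probs <- function(amino_acid_probs, family_codon_probs) {
  fams <- c(synonymous_families(), list(M = "ATG", W = "TGG"))
  p <- numeric(0)
  for (aa in names(amino_acid_probs)) {
    if (amino_acid_probs[[aa]] == 0) next
    cods <- fams[[aa]]
    fp <- if (!is.null(family_codon_probs[[aa]])) {
      v <- family_codon_probs[[aa]]
      if (abs(sum(v) - 1) > 1e-9) stop("codon probabilities for ", aa,
                                       " do not sum to 1")
      if (is.null(names(v))) stats::setNames(v, cods) else v
    } else {
      stats::setNames(rep(1 / length(cods), length(cods)), cods)
    }
    p <- c(p, amino_acid_probs[[aa]] * fp)
  }
  p / sum(p)
}

#' Generate synthetic coding sequences
#'
#' Each sequence is ATG, then `codons_per_sequence` codons sampled i.i.d.
#' from the amino-acid and within-family codon distributions, then a stop
#' codon drawn uniformly from TAA/TAG/TGA. Deterministic given `seed`.
#'
#' @param n_sequences Number of sequences.
#' @param codons_per_sequence Body length in codons (start/stop excluded).
#' @param amino_acid_probs Named probabilities over amino acids (one-letter
#'   codes; may include M and W). Default: uniform over the 18 degenerate
#'   families with Met/Trp at low weight.
#' @param family_codon_probs Named list: amino acid -> probability vector
#'   over its codons (named or in family order). Default uniform.
#' @param seed Integer seed.
#' @param species Species label for the output records.
#' @return A coding-sequence set data frame.
#' @export
generate_cds <- function(n_sequences, codons_per_sequence,
                         amino_acid_probs = NULL,
                         family_codon_probs = NULL,
                         seed = 1L, species = "synthetic") {
  if (n_sequences < 1L || codons_per_sequence < 1L) {
    stop("n_sequences and codons_per_sequence must be positive")
  }
  if (is.null(amino_acid_probs)) amino_acid_probs <- .default_aa_probs()
  if (abs(sum(amino_acid_probs) - 1) > 1e-9) {
    stop("amino_acid_probs must sum to 1")
  }
  probs <- .codon_probs(as.list(amino_acid_probs), family_codon_probs)
  .with_seed(seed, {
    bases <- vapply(seq_len(n_sequences), function(i) {
      body <- sample(names(probs), codons_per_sequence,
                     replace = TRUE, prob = probs)
      paste0(START_CODON, paste(body, collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    cds_set(id = sprintf("%s_%03d", species, seq_len(n_sequences)),
            bases = bases, species = species)
  })
}

#' Generate a set with tunable codon-usage bias
#'
#' Within every synonymous family the codon probabilities interpolate
#' linearly between uniform (`theta = 0`) and one-hot on the family's
#' first codon (`theta = 1`), so observed ENc decreases monotonically
#' from the 61 cap toward exactly 20 as `theta` rises.
#'
#' @param theta Bias strength in [0, 1].
#' @param n_sequences,codons_per_sequence,seed,species As [generate_cds()].
#' @return A coding-sequence set data frame.
#' @export
generate_biased_set <- function(theta, n_sequences = 10L,
                                codons_per_sequence = 300L,
                                seed = 1L, species = "synthetic") {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  fams <- synonymous_families()
  fcp <- lapply(fams, function(cods) {
    k <- length(cods)
    p <- (1 - theta) / k + theta * c(1, rep(0, k - 1L))
    stats::setNames(p, cods)
  })
  generate_cds(n_sequences, codons_per_sequence,
               family_codon_probs = fcp, seed = seed, species = species)
}

#' Generate a set with a GC12-GC3 gradient (neutrality geometry)
#'
#' Per sequence a latent GC3 target t is drawn uniformly from
#' `gc3_range`; codon sampling weights are tilted independently by GC
#' content at positions 1-2 (toward `0.5 + m * (t - midpoint)` plus
#' Gaussian noise) and at position 3 (toward t). An OLS fit of realized
#' GC12 on realized GC3 recovers the mutation fraction `m` up to
#' sampling error.
#'
#' @param m Mutation fraction in [0, 1]: the target slope of GC12 on GC3.
#' @param gc3_range Low/high GC3 fractions; must satisfy low < high for a
#'   non-degenerate regression.
#' @param noise_sd Gaussian noise on the position-1/2 GC target, in
#'   percentage points.
#' @param n_sequences,codons_per_sequence,seed,species As [generate_cds()].
#' @return A coding-sequence set data frame.
#' @export
generate_neutrality_set <- function(m, gc3_range = c(0.3, 0.7),
                                    noise_sd = 1,
                                    n_sequences = 200L,
                                    codons_per_sequence = 500L,
                                    seed = 1L, species = "synthetic") {
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (gc3_range[1] > gc3_range[2]) stop("gc3_range must be (low, high)")
  if (gc3_range[1] == gc3_range[2]) {
    warning("degenerate gc3_range: GC3 will be constant and the ",
            "neutrality regression undefined")
  }
  cods <- sense_codons()
  g12 <- vapply(strsplit(cods, "", fixed = TRUE),
                function(x) sum(x[1:2] %in% c("G", "C")), numeric(1))
  g3 <- vapply(strsplit(cods, "", fixed = TRUE),
               function(x) as.numeric(x[3] %in% c("G", "C")), numeric(1))
  mid <- mean(gc3_range)
  .with_seed(seed, {
    bases <- vapply(seq_len(n_sequences), function(i) {
      t_i <- stats::runif(1, gc3_range[1], gc3_range[2])
      p12 <- 0.5 + m * (t_i - mid) + stats::rnorm(1, 0, noise_sd / 100)
      if (p12 < 0.05 || p12 > 0.95) {
        warning("position-1/2 GC propensity clipped to [0.05, 0.95]")
        p12 <- min(max(p12, 0.05), 0.95)
      }
      w <- p12^g12 * (1 - p12)^(2 - g12) * ifelse(g3 == 1, t_i, 1 - t_i)
      body <- sample(cods, codons_per_sequence, replace = TRUE, prob = w)
      paste0(START_CODON, paste(body, collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    cds_set(id = sprintf("%s_%03d", species, seq_len(n_sequences)),
            bases = bases, species = species)
  })
}

#' Generate a synthetic codon-usage reference table
#'
#' All 64 codons receive positive integer counts; frequencies are per
#' thousand. Byte-identical output for a fixed seed.
#'
#' @param seed Integer seed.
#' @param species Label stored with the table.
#' @return A `ref_usage` object.
#' @export
generate_reference_table <- function(seed = 1L, species = "synthetic") {
  .with_seed(seed, {
    count <- sample(50:2000, 64, replace = TRUE)
    df <- data.frame(codon = all_codons(),
                     freq_per_1000 = 1000 * count / sum(count),
                     count = count, stringsAsFactors = FALSE)
    structure(df, class = c("ref_usage", "data.frame"), species = species)
  })
}

#' Generate a synthetic tRNA gene-count table
#'
#' Isotypes are the reverse-complement anticodons of each amino acid's
#' codons (including Met and Trp) with random non-negative counts, at
#' least one positive per family.
#'
#' @param seed Integer seed.
#' @param species Label stored with the table.
#' @return A `trna_table` object.
#' @export
generate_trna_table <- function(seed = 1L, species = "synthetic") {
  fams <- c(synonymous_families(), list(M = "ATG", W = "TGG"))
  .with_seed(seed, {
    rows <- lapply(names(fams), function(aa) {
      anti <- anticodon_for(fams[[aa]])
      cnt <- sample(0:30, length(anti), replace = TRUE)
      if (all(cnt == 0)) cnt[1L] <- 1L
      data.frame(amino_acid = aa, anticodon = anti, count = as.integer(cnt),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    totals <- tapply(df$count, df$amino_acid, sum)
    structure(df, class = c("trna_table", "data.frame"),
              species = species,
              preferred_codon = NULL,
              stated_totals = stats::setNames(as.numeric(totals),
                                              names(totals)))
  })
}

#' Write a coding-sequence set as FASTA
#'
#' @param cds A coding-sequence set data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cds))) {
    writeLines(c(paste0(">", cds$id[i]), cds$bases[i]), con)
  }
  invisible(path)
}

#' Write a reference usage table in the countcodon text layout
#'
#' @param ref A `ref_usage` object.
#' @param path Output path.
#' @param rna Render codons in the RNA alphabet.
#' @return `path`, invisibly.
#' @export
write_reference_usage <- function(ref, path, rna = FALSE) {
  cod <- if (rna) as_rna(ref$codon) else ref$codon
  lines <- sprintf("%s %.1f (%6d)", cod, ref$freq_per_1000, ref$count)
  writeLines(lines, path)
  invisible(path)
}

#' Write a tRNA gene-count table
#'
#' Tab-separated rows: amino-acid label, isotype list, total; the layout
#' accepted by [read_trna_counts()].
#'
#' @param trna A `trna_table` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_counts <- function(trna, path) {
  aas <- unique(trna$amino_acid)
  lines <- c("amino_acid\tisotypes\ttotal",
             vapply(aas, function(aa) {
               sub <- trna[trna$amino_acid == aa, ]
               iso <- paste(sprintf("%s (%d)", sub$anticodon, sub$count),
                            collapse = ", ")
               sprintf("%s (%s)\t%s\t%d", AA_THREE[[aa]], aa, iso,
                       sum(sub$count))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
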