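test_that("family homozygosity matches the hand-evaluated estimator", {
  # two-fold family with counts (3, 1): F = (4*(9/16 + 1/16) - 1)/3 = 0.5
  # other families get skewed counts so every class mean is defined
  cc <- codon_count_table(c(
    TTT = 3, TTC = 1,                       # Phe, the family under test
    TAT = 3, TAC = 1, CAT = 1, CAC = 3, CAA = 3, CAG = 1,
    AAT = 3, AAC = 1, AAA = 3, AAG = 1, GAT = 3, GAC = 1,
    GAA = 3, GAG = 1, TGT = 3, TGC = 1,
    ATT = 2, ATC = 1, ATA = 1,
    GTT = 2, GTC = 1, GTA = 1,
    CCT = 2, CCC = 1, CCA = 1,
    ACT = 2, ACC = 1, ACA = 1,
    GCT = 2, GCC = 1, GCA = 1,
    GGT = 2, GGC = 1, GGA = 1,
    TTA = 2, TTG = 1, CTT = 1, CTC = 1, CTA = 1,
    TCT = 2, TCC = 1, TCA = 1, TCG = 1, AGT = 1,
    CGT = 2, CGC = 1, CGA = 1, CGG = 1, AGA = 1))
  r <- enc(cc)
  expect_equal(unname(r$per_family_F["F"]), 0.5)
  # Ile with (2, 1, 1): F = (4*(6/16) - 1)/3 = 1/6
  expect_equal(unname(r$per_family_F["I"]), 1 / 6)
  expect_true(r$enc >= 20 && r$enc <= 61)
})

test_that("ENc endpoints: one codon per family scores 20, uniform usage 61", {
  one_hot <- generate_biased_set(1, n_sequences = 5,
                                 codons_per_sequence = 300, seed = 1)
  expect_equal(enc(count_codons(one_hot))$enc, 20)

  eq <- codon_count_table(setNames(rep(100L, 59), sense_codons()))
  expect_equal(enc(eq)$enc, 61)
})

test_that("ENc handles scale covariance and missing Ile imputation", {
  s <- small_cds_set(n = 4, len = 150)
  cc <- count_codons(s)
  e1 <- enc(cc)
  cc3 <- codon_count_table(cc$counts * 3L)
  e3 <- enc(cc3)
  # same proportions, larger n: F = (n*S - 1)/(n - 1) rises toward S
  expect_true(all(na.omit(e3$per_family_F >= e1$per_family_F - 1e-12)))
  S <- vapply(synonymous_families(), function(cods) {
    x <- cc$counts[cods]; if (sum(x) == 0) NA_real_ else sum((x / sum(x))^2)
  }, numeric(1))
  expect_true(all(na.omit(e3$per_family_F <= S + 1e-12)))

  no_ile <- cc$counts
  no_ile[c("ATT", "ATC", "ATA")] <- 0L
  r <- enc(codon_count_table(no_ile))
  expect_true("F3" %in% r$missing_classes)
  expect_equal(unname(r$class_means["F3"]),
               unname((r$class_means["F2"] + r$class_means["F4"]) / 2))

  empty_twofold <- cc$counts
  empty_twofold[unlist(synonymous_families()[c("F", "Y", "H", "Q", "N",
                                               "K", "D", "E", "C")])] <- 0L
  expect_error(enc(codon_count_table(empty_twofold)), "empty degeneracy class")
})

test_that("expected ENc curve has the closed-form spot values and symmetry", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s))
  expect_error(enc_expected(1.2), "\\[0, 1\\]")
})

test_that("CAI is the count-weighted geometric mean of relative adaptiveness", {
  # reference with Phe TTT:30, TTC:10; query of a single TTC codon
  counts <- setNames(rep(20L, 64), all_codons())
  counts[c("TTT", "TTC")] <- c(30L, 10L)
  ref <- structure(
    data.frame(codon = all_codons(),
               freq_per_1000 = 1000 * counts / sum(counts),
               count = as.integer(counts), stringsAsFactors = FALSE),
    class = c("ref_usage", "data.frame"))
  q <- codon_count_table(c(TTC = 1))
  expect_equal(cai(q, ref)$cai, 1 / 3, tolerance = 1e-12)

  # all-optimal query scores exactly 1
  ref2 <- generate_reference_table(seed = 5)
  opt <- vapply(synonymous_families(), function(cods) {
    cods[which.max(ref2$count[match(cods, ref2$codon)])]
  }, character(1))
  q2 <- codon_count_table(setNames(rep(2L, length(opt)), opt))
  expect_equal(cai(q2, ref2)$cai, 1)
  expect_true(all(tapply(cai(q2, ref2)$per_codon_w,
                         codon_to_aa(sense_codons()), max) == 1))
})

test_that("CAI guards zero-usage references with a pseudo-count", {
  counts <- setNames(rep(10L, 64), all_codons())
  counts["TTT"] <- 0L
  ref <- structure(
    data.frame(codon = all_codons(),
               freq_per_1000 = 1000 * counts / sum(counts),
               count = as.integer(counts), stringsAsFactors = FALSE),
    class = c("ref_usage", "data.frame"))
  r <- cai(codon_count_table(c(TTT = 1)), ref)
  expect_equal(unname(r$per_codon_w["TTT"]), 0.05)  # 0.5 / 10
  counts[c("TTT", "TTC")] <- 0L
  ref$count <- as.integer(counts)
  expect_error(cai(codon_count_table(c(TTT = 1)), ref), "no usage")
})

test_that("CAI favors a query's own modal codons over a demoting reference", {
  s <- small_cds_set(n = 3, len = 200)
  cc <- count_codons(s)
  own <- structure(
    data.frame(codon = all_codons(),
               freq_per_1000 = 1000 * (cc$counts + 1) / sum(cc$counts + 1),
               count = as.integer(cc$counts + 1), stringsAsFactors = FALSE),
    class = c("ref_usage", "data.frame"))
  demoted <- own
  demoted$count <- rev(demoted$count)
  demoted$freq_per_1000 <- rev(demoted$freq_per_1000)
  expect_gte(cai(cc, own)$cai, cai(cc, demoted)$cai)
})

test_that("P2 class means and index reproduce the published species table", {
  tabs <- epb41l3_rscu_tables()
  expected <- data.frame(
    species = c("homo_sapiens", "rattus_norvegicus", "bos_taurus",
                "mus_musculus", "pongo_abelii"),
    SSU = c(0.71, 0.69, 0.66, 0.69, 0.69),
    WWU = c(1.00, 0.76, 0.82, 0.84, 0.94),
    SSC = c(1.07, 1.23, 1.32, 1.15, 1.06),
    WWC = c(1.09, 1.37, 1.32, 1.27, 1.12),
    P2  = c(0.93, 1.02, 0.96, 0.99, 0.95))
  for (i in seq_len(nrow(expected))) {
    r <- p2(tabs[[expected$species[i]]])
    got <- c(r$sSU, r$wWU, r$sSC, r$wWC, r$p2)
    printed <- unlist(expected[i, c("SSU", "WWU", "SSC", "WWC", "P2")],
                      use.names = FALSE)
    # agreement to the printed two-decimal precision (half-ulp bound)
    expect_lt(max(abs(got - printed)), 0.005 + 1e-9)
  }
  overall <- mean(vapply(expected$species,
                         function(sp) p2(tabs[[sp]])$p2, numeric(1)))
  expect_equal(round(overall, 2), 0.97)
})

test_that("P2 of a uniform RSCU table is exactly 1", {
  u <- rscu_from_values(setNames(rep(1, 59), sense_codons()))
  expect_equal(p2(u)$p2, 1)
})

test_that("count-based P2 mode uses codon counts in the same formula", {
  cc <- count_codons(small_cds_set(n = 3, len = 150))
  t <- rscu(cc)
  r <- p2(t, mode = "counts")
  cls <- sapply(list(WWU = c("AAT", "ATT", "TAT", "TTT"),
                     WWC = c("AAC", "ATC", "TAC", "TTC"),
                     SSU = c("CCT", "CGT", "GCT", "GGT"),
                     SSC = c("CCC", "CGC", "GCC", "GGC")),
                function(cods) mean(cc$counts[cods]))
  expect_equal(r$p2,
               unname(2 * (cls["WWC"] + cls["SSU"]) / sum(cls)))
})
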