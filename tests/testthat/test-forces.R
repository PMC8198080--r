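test_that("neutrality recovers an exact linear relation", {
  gc3 <- c(40, 45, 50, 55, 60)
  gc12 <- 0.3 * gc3 + 10
  r <- neutrality(gc12, gc3)
  expect_equal(r$slope, 0.3)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$mutation_pct, 30)
  expect_equal(r$selection_pct, 70)
  expect_equal(r$mutation_pct + r$selection_pct, 100)
})

test_that("independent GC12 yields a near-zero slope (simulation oracle)", {
  set.seed(13)
  gc3 <- runif(200, 30, 70)
  gc12 <- rnorm(200, 45, 2)
  r <- neutrality(gc12, gc3)
  expect_lt(abs(r$slope), 0.1)
  expect_gt(r$selection_pct, 90)
})

test_that("neutrality obeys the OLS identity and rejects degenerate input", {
  s <- generate_neutrality_set(0.5, n_sequences = 30,
                               codons_per_sequence = 100, seed = 3)
  prof <- composition_profiles(s)
  r <- neutrality(prof)
  expect_equal(r$slope,
               r$pearson_r * sd(prof$gc12) / sd(prof$gc3),
               tolerance = 1e-12)
  expect_error(neutrality(c(1, 2, 3), c(50, 50, 50)), "DEGENERATE_X")
  expect_error(neutrality(c(1, 2), c(1, 2)), "at least 3")
})

test_that("PR2 coordinates sit at (0.5, 0.5) under Chargaff balance", {
  prof <- data.frame(id = "x", pct_A3 = 25, pct_T3 = 25,
                     pct_G3 = 25, pct_C3 = 25)
  r <- pr2(prof)
  expect_equal(unname(r$overall), c(0.5, 0.5))

  # all third positions G: gc_bias 1, at_bias undefined
  prof2 <- data.frame(id = "y", pct_A3 = 0, pct_T3 = 0,
                      pct_G3 = 100, pct_C3 = 0)
  r2 <- pr2(prof2)
  expect_equal(r2$per_sequence$gc_bias, 1)
  expect_true(is.na(r2$per_sequence$at_bias))
})

test_that("PR2 from the published third-position means matches the reported biases", {
  prof <- data.frame(id = "means", pct_A3 = 25.45, pct_T3 = 46.05 - 25.45,
                     pct_G3 = 29.65, pct_C3 = 53.95 - 29.65)
  r <- pr2(prof)
  expect_equal(unname(r$overall["at_bias"]), 0.552, tolerance = 0.002)
  expect_equal(unname(r$overall["gc_bias"]), 0.549, tolerance = 0.002)
})

test_that("PR2 overall equals the pooled point for equal-length sequences", {
  s <- generate_cds(6, 100, seed = 21)
  prof <- composition_profiles(s)
  r <- pr2(prof)
  third <- unlist(lapply(s$bases, function(b) {
    cods <- codon_split(b)
    substr(cods, 3, 3)
  }))
  pooled_at <- sum(third == "A") / sum(third %in% c("A", "T"))
  expect_equal(unname(r$overall["at_bias"]), pooled_at, tolerance = 1e-12)
})

test_that("ENc-GC3 deviations flag points below the null curve", {
  gc3 <- c(0.3, 0.5, 0.7)
  on_curve <- enc_gc3_points(enc_expected(gc3), gc3)
  expect_equal(on_curve$points$deviation, rep(0, 3))
  expect_equal(on_curve$fraction_below_curve, 0)

  biased <- generate_biased_set(1, n_sequences = 4,
                                codons_per_sequence = 300, seed = 2)
  prof <- composition_profiles(biased)
  encs <- vapply(biased$bases,
                 function(b) enc(count_codons(b))$enc, numeric(1))
  r <- enc_gc3_points(encs, prof$gc3)
  expect_equal(r$fraction_below_curve, 1)
  expect_true(all(r$points$deviation < -30))
  expect_error(enc_gc3_points(1:3, 1:2), "equal length")
})

test_that("correlation table is symmetric, starred, and permutation invariant", {
  set.seed(5)
  df <- data.frame(a = rnorm(30))
  df$b <- -df$a
  df$c <- rnorm(30)
  ct <- correlation_table(df)
  expect_equal(ct$r["a", "b"], -1)
  expect_equal(ct$stars["a", "b"], "***")
  expect_equal(diag(ct$r), c(a = 1, b = 1, c = 1))
  expect_equal(ct$r, t(ct$r))
  perm <- correlation_table(df[sample(30), ])
  expect_equal(perm$r, ct$r)

  df$k <- 1
  expect_true(is.na(correlation_table(df)$r["a", "k"]))
})

test_that("ENc regressions report closed-form slopes and signs", {
  set.seed(6)
  enc_vals <- runif(20, 40, 61)
  df <- data.frame(enc = enc_vals,
                   self = enc_vals,
                   neg = -2 * enc_vals + 5)
  r <- enc_regressions(df)
  expect_equal(r$slope[r$feature == "self"], 1)
  expect_equal(r$intercept[r$feature == "self"], 0, tolerance = 1e-9)
  expect_equal(r$slope[r$feature == "neg"], -0.5)
  expect_equal(r$sign[r$feature == "neg"], "negative")
})

test_that("bias tied to GC3 yields a negative GC3 regression slope", {
  # stronger bias toward each family's G/C-ending codon raises GC3 while
  # lowering ENc, so the fitted ENc ~ GC3 slope must be negative
  fams <- synonymous_families()
  cds <- do.call(rbind, lapply(seq(0, 0.9, length.out = 12), function(th) {
    fcp <- lapply(fams, function(cods) {
      gc_end <- cods[substr(cods, 3, 3) %in% c("G", "C")][1]
      p <- rep((1 - th) / length(cods), length(cods))
      names(p) <- cods
      p[gc_end] <- p[gc_end] + th
      p
    })
    generate_cds(1, 200, family_codon_probs = fcp,
                 seed = 100 + round(100 * th))
  }))
  prof <- composition_profiles(cds)
  encs <- vapply(cds$bases, function(b) enc(count_codons(b))$enc, numeric(1))
  r <- enc_regressions(data.frame(enc = encs, gc3 = prof$gc3))
  expect_equal(r$sign[r$feature == "gc3"], "negative")
  expect_lt(r$slope[r$feature == "gc3"], 0)
})
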