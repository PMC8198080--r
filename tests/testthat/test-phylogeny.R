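test_that("K2P distance matches the closed form and handles edge cases", {
  a <- strrep("ACGT", 25)
  expect_equal(k2p(a, a), list(d = 0, P = 0, Q = 0, sites_used = 100))

  # 100 sites, 10 transitions (A->G), 5 transversions (A->C)
  x <- rep("A", 100)
  y <- x
  y[1:10] <- "G"
  y[11:15] <- "C"
  r <- k2p(paste(x, collapse = ""), paste(y, collapse = ""))
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(r$d, 0.1701812, tolerance = 1e-6)

  # gap/ambiguity sites are dropped pairwise
  r2 <- k2p("ACG-N", "ACGTT")
  expect_equal(r2$sites_used, 3)
  expect_error(k2p("---", "ACG"), "NO_SITES")
  expect_error(k2p("AC", "ACG"), "not aligned")

  # saturation is an error, not a number
  expect_error(k2p(strrep("A", 50), strrep("G", 50)), "SATURATION")
})

test_that("K2P reduces to Jukes-Cantor at 1:2 transition:transversion ratio", {
  # JC: d = -3/4 log(1 - 4/3 p) with p = P + Q
  for (p in c(0.015, 0.03, 0.045)) {
    n <- 2000
    nts <- round(n * p / 3)
    x <- rep("A", n)
    y <- x
    y[seq_len(nts)] <- "G"
    y[nts + seq_len(2 * nts)] <- "C"
    r <- k2p(paste(x, collapse = ""), paste(y, collapse = ""))
    jc <- -0.75 * log(1 - 4 / 3 * (r$P + r$Q))
    expect_equal(r$d, jc, tolerance = 1e-3)
  }
})

test_that("K2P matrix agrees with an independent implementation", {
  skip_if_not_installed("ape")
  s <- simulate_alignment(4, 200, seed = 31)
  km <- k2p_matrix(s)
  bin <- ape::as.DNAbin(lapply(strsplit(s$bases, "", fixed = TRUE), tolower))
  names(bin) <- s$id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(km$d, ref[rownames(km$d), colnames(km$d)], tolerance = 1e-9)
})

test_that("K2P matrix is symmetric, zero-diagonal, and order invariant", {
  s <- simulate_alignment(4, 150, seed = 17)
  m1 <- k2p_matrix(s)
  expect_equal(m1$d, t(m1$d))
  expect_equal(unname(diag(m1$d)), rep(0, 4))
  m2 <- k2p_matrix(s[c(3, 1, 4, 2), ])
  expect_equal(m2$d[s$id, s$id], m1$d)
  expect_equal(k2p_matrix(rep(strrep("ACGT", 10), 3))$d,
               matrix(0, 3, 3, dimnames = list(paste0("seq", 1:3),
                                               paste0("seq", 1:3))))
})

test_that("three-taxon NJ resolves exact branch lengths in closed form", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tree <- neighbor_joining(d)
  expect_equal(sort(tree_tips(tree)), c("A", "B", "C"))
  # b_A = (3 + 4 - 5)/2 = 1, b_B = (3 + 5 - 4)/2 = 2, b_C = (4 + 5 - 3)/2 = 3
  expect_equal(tree$lengths, c(1, 2, 3))
  expect_match(write_newick(tree), "^\\(A:1,B:2,C:3\\);$")
})

test_that("NJ recovers the generating 4-taxon topology among all three", {
  # additive matrix for ((A,B),(C,D)) with internal branch 2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 1, B = 3, C = 2, D = 4)
  d["A", "B"] <- d["B", "A"] <- bl["A"] + bl["B"]
  d["C", "D"] <- d["D", "C"] <- bl["C"] + bl["D"]
  for (i in c("A", "B")) for (j in c("C", "D")) {
    d[i, j] <- d[j, i] <- bl[i] + bl[j] + 2
  }
  tree <- neighbor_joining(d)
  nwk <- write_newick(tree)
  # brute force: the split {A,B}|{C,D} must be the one in the tree
  expect_true("A|B" %in% split_set(nwk))
  expect_false("A|C" %in% split_set(nwk))
  expect_false("A|D" %in% split_set(nwk))
})

test_that("NJ reproduces random additive matrices up to 8 taxa", {
  skip_if_not_installed("ape")
  for (case in list(c(5, 101), c(6, 202), c(7, 303), c(8, 404))) {
    n <- case[1]
    ram <- random_additive_matrix(n, seed = case[2])
    tree <- neighbor_joining(ram$d, quiet = TRUE)
    nwk <- write_newick(tree)
    # topology: splits equal those of the generating tree (via ape NJ on
    # the same matrix as an independent cross-check)
    ref <- ape::nj(stats::as.dist(ram$d))
    expect_setequal(split_set(nwk),
                    split_set(ape::write.tree(ref)))
    # path lengths: NJ on an additive matrix reproduces the input exactly
    parsed <- ape::read.tree(text = nwk)
    pd <- ape::cophenetic.phylo(parsed)
    expect_equal(pd[rownames(ram$d), colnames(ram$d)], ram$d,
                 tolerance = 1e-8)
  }
})

test_that("NJ validates input and clamps negative branch lengths", {
  bad <- matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(bad), "not symmetric")
  expect_error(neighbor_joining(matrix(-1, 3, 3)), "negative")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")

  # a matrix violating the triangle inequality forces a negative estimate
  d <- matrix(c(0, 10, 1,
                10, 0, 2,
                1, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_message(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$lengths >= 0))
})

test_that("Newick output is deterministic, quoted, and round-trips", {
  skip_if_not_installed("ape")
  s <- simulate_alignment(5, 120, seed = 77)
  s$id <- c("b", "a tip", "e", "c", "d")
  tree <- neighbor_joining(k2p_matrix(s), quiet = TRUE)
  nwk <- write_newick(tree)
  expect_match(nwk, "'a tip'", fixed = TRUE)
  expect_identical(nwk, write_newick(tree))
  parsed <- ape::read.tree(text = nwk)
  # ape keeps the quotes on quoted labels; strip before comparing
  expect_setequal(gsub("^'|'$", "", parsed$tip.label), s$id)
  # lengths survive the round-trip
  pd <- ape::cophenetic.phylo(parsed)
  km <- k2p_matrix(s)
  nj_ref <- ape::nj(stats::as.dist(km$d))
  expect_equal(sum(parsed$edge.length), sum(pmax(nj_ref$edge.length, 0)),
               tolerance = 1e-8)
})
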