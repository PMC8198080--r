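# Shared fixtures built in code.

# minimal valid CDS: ATG + GCA + GAA + TAA
MINIMAL_CDS <- "ATGGCAGAATAA"

# assemble a CDS string from body codons
make_cds <- function(..., stop = "TAA") {
  paste0("ATG", paste0(..., collapse = ""), stop)
}

# a small deterministic valid sequence set
small_cds_set <- function(n = 4, len = 120, seed = 42) {
  generate_cds(n_sequences = n, codons_per_sequence = len, seed = seed)
}

# star-related aligned sequences: one ancestor, each taxon mutated
# site-wise with fixed substitution probability (transitions twice as
# likely as each transversion)
simulate_alignment <- function(n_taxa, len_codons, seed, sub_rate = 0.03) {
  anc <- generate_cds(1, len_codons, seed = seed)$bases
  chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  set.seed(seed + 1000L)
  seqs <- vapply(seq_len(n_taxa), function(i) {
    x <- chars
    hit <- runif(length(x)) < sub_rate
    x[hit] <- vapply(x[hit], function(b) {
      if (runif(1) < 0.5) ts_map[[b]] else
        sample(setdiff(c("A", "C", "G", "T"), c(b, ts_map[[b]])), 1)
    }, character(1))
    paste(x, collapse = "")
  }, character(1))
  cds_set(id = paste0("taxon", seq_len(n_taxa)), bases = seqs)
}

# random additive (tree-generated) distance matrix over n taxa:
# a random recursive bifurcating topology with positive branch lengths,
# returning the matrix and the generating tree's path lengths
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n))
  # build a random unrooted binary tree by sequential taxon addition;
  # represent as edge list on nodes; compute path distances
  # start from a 3-star
  nodes <- n + 1L  # internal node ids start at n+1
  edges <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  lens <- stats::runif(3, 0.05, 1)
  next_internal <- n + 2L
  for (tip in seq_len(n)[-(1:3)]) {
    e <- sample(nrow(edges), 1L)
    a <- edges[e, 1L]; b <- edges[e, 2L]; l <- lens[e]
    cut <- stats::runif(1, 0.2, 0.8) * l
    v <- next_internal; next_internal <- next_internal + 1L
    edges <- edges[-e, , drop = FALSE]; lens <- lens[-e]
    edges <- rbind(edges, c(a, v), c(v, b), c(v, tip))
    lens <- c(lens, cut, l - cut, stats::runif(1, 0.05, 1))
  }
  # all-pairs path lengths via adjacency
  nv <- max(edges)
  adj <- lapply(seq_len(nv), function(i) list())
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], list(c(b, lens[k])))
    adj[[b]] <- c(adj[[b]], list(c(a, lens[k])))
  }
  dist_from <- function(s) {
    d <- rep(NA_real_, nv); d[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[u]]) {
        v <- nb[1L]
        if (is.na(d[v])) { d[v] <- d[u] + nb[2L]; queue <- c(queue, v) }
      }
    }
    d
  }
  m <- t(vapply(seq_len(n), function(i) dist_from(i)[seq_len(n)],
                numeric(n)))
  dimnames(m) <- list(labels, labels)
  list(d = m, edges = edges, lens = lens)
}

# unrooted-topology comparison via the split (bipartition) set of a
# Newick string, using ape as an independent parser
split_set <- function(newick) {
  tr <- ape::unroot(ape::read.tree(text = newick))
  sp <- ape::prop.part(tr)
  tips <- sort(tr$tip.label)
  canon <- lapply(sp, function(idx) {
    s <- sort(attr(sp, "labels")[idx])
    a <- paste(s, collapse = "|")
    b <- paste(setdiff(tips, s), collapse = "|")
    min(a, b)
  })
  sort(unique(unlist(canon)))
}
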