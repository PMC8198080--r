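# Kimura two-parameter distances on aligned sequences and neighbor-joining
# tree construction with Newick output. Input must be pre-aligned (equal
# length); gap/ambiguity sites are dropped pairwise.

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguous character
#' are excluded (pairwise deletion). With transition proportion P and
#' transversion proportion Q over the retained sites,
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q).
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return List with `d`, `P`, `Q`, `sites_used`.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- strsplit(.to_dna(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(.to_dna(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences are not aligned (unequal length)")
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop("NO_SITES: no comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & .TRANSITIONS[a] == b)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("SATURATION: K2P distance undefined (P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), ")")
  }
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       P = P, Q = Q, sites_used = n)
}

#' Pairwise K2P distance matrix over an aligned sequence set
#'
#' @param aligned A coding-sequence set data frame (columns `id`,
#'   `bases`) or a named character vector of aligned sequences.
#' @return Object of class `k2p_matrix`: list with `labels`, `d`
#'   (symmetric matrix), `P`, `Q`, `sites_used` matrices.
#' @export
k2p_matrix <- function(aligned) {
  if (is.data.frame(aligned)) {
    seqs <- stats::setNames(aligned$bases, aligned$id)
  } else {
    seqs <- aligned
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  labels <- names(seqs)
  mk <- function() matrix(0, n, n, dimnames = list(labels, labels))
  d <- mk(); P <- mk(); Q <- mk(); S <- mk()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    res <- tryCatch(k2p(seqs[[i]], seqs[[j]]), error = function(e) {
      stop("pair (", labels[i], ", ", labels[j], "): ",
           conditionMessage(e), call. = FALSE)
    })
    d[i, j] <- d[j, i] <- res$d
    P[i, j] <- P[j, i] <- res$P
    Q[i, j] <- Q[j, i] <- res$Q
    S[i, j] <- S[j, i] <- res$sites_used
  }
  structure(list(labels = labels, d = d, P = P, Q = Q, sites_used = S),
            class = "k2p_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' Q_ij = (n - 2) d_ij - r_i - r_j; ties broken by the lowest label-index
#' pair. Negative branch lengths are clamped to zero with a message. The
#' result is an unrooted tree (trifurcating root node).
#'
#' @param m A `k2p_matrix`, or a symmetric numeric matrix with dimnames.
#' @param quiet Suppress the clamping message.
#' @return Object of class `nj_tree`: nested list of nodes, each either a
#'   tip (`label`) or an internal node (`children`, `lengths`).
#' @export
neighbor_joining <- function(m, quiet = FALSE) {
  d <- if (inherits(m, "k2p_matrix")) m$d else as.matrix(m)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(d < 0)) stop("negative input distances")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  nodes <- lapply(labels, function(l) list(label = l))
  while (length(nodes) > 3L) {
    k <- nrow(d)
    r <- rowSums(d)
    qm <- (k - 2) * d - outer(r, r, `+`)
    diag(qm) <- Inf
    # lowest-index pair among minima (row-major scan of the upper triangle)
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (qm[i, j] < bq - 1e-12) { bq <- qm[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    bi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2)))
    bj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))))
    new_node <- list(children = list(nodes[[i]], nodes[[j]]),
                     lengths = c(bi, bj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    d <- d2
  }
  # resolve the final three lineages around the central node
  b1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  b2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  b3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  if (clamped && !quiet) message("negative branch length(s) clamped to 0")
  structure(list(children = nodes, lengths = c(b1, b2, b3)),
            class = "nj_tree")
}

.min_tip <- function(node) {
  if (!is.null(node$label)) return(node$label)
  min(vapply(node$children, .min_tip, character(1)))
}

.newick_label <- function(l) {
  # ] must come first inside the class to be literal
  if (grepl("[][\t ():,;']", l)) {
    paste0("'", gsub("'", "''", l), "'")
  } else l
}

.newick_node <- function(node) {
  if (!is.null(node$label)) return(.newick_label(node$label))
  ord <- order(vapply(node$children, .min_tip, character(1)))
  parts <- vapply(ord, function(i) {
    paste0(.newick_node(node$children[[i]]),
           ":", format(node$lengths[i], digits = 10))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Serialize a neighbor-joining tree to Newick text
#'
#' Child ordering is deterministic (lexicographic by the smallest tip
#' label in each subtree); labels containing Newick metacharacters are
#' quoted.
#'
#' @param tree An `nj_tree`.
#' @return A single Newick string terminated with a semicolon.
#' @export
write_newick <- function(tree) {
  paste0(.newick_node(tree), ";")
}

#' Tip labels of a neighbor-joining tree
#' @param tree An `nj_tree` (or internal node).
#' @return Character vector of tip labels.
#' @export
tree_tips <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, tree_tips), use.names = FALSE)
}
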