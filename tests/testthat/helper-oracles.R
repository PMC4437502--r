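# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

oracle_polymorphic <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  cnt <- 0L
  for (j in seq_len(ncol(m)))
    if (length(unique(m[, j])) > 1L) cnt <- cnt + 1L
  cnt
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  tot <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1L
  }
  tot / np / ncol(m)
}

oracle_hamming <- function(a, b) {
  cnt <- 0L
  for (k in seq_along(a)) if (a[k] != b[k]) cnt <- cnt + 1L
  cnt
}

# Kruskal's algorithm: minimum spanning weight of a complete graph given a
# distance matrix
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  edges <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    edges <- rbind(edges, c(i, j, d[i, j]))
  edges <- edges[order(edges[, 3L]), , drop = FALSE]
  comp <- seq_len(n)
  w <- 0
  for (e in seq_len(nrow(edges))) {
    a <- comp[edges[e, 1L]]
    b <- comp[edges[e, 2L]]
    if (a != b) {
      w <- w + edges[e, 3L]
      comp[comp == b] <- a
    }
  }
  w
}

# direct evaluation of the Bandelt-Dress isolation index of bipartition
# given by `side` (indices), and full enumeration of all d-splits
oracle_alpha <- function(d, side) {
  n <- nrow(d)
  B <- side
  A <- setdiff(seq_len(n), side)
  best <- Inf
  for (a in A) for (a2 in A) for (b in B) for (b2 in B) {
    v <- max(d[a, b] + d[a2, b2], d[a, b2] + d[a2, b],
             d[a, a2] + d[b, b2]) - d[a, a2] - d[b, b2]
    if (v < best) best <- v
  }
  best / 2
}

oracle_dsplits <- function(d, tol = 1e-9) {
  n <- nrow(d)
  out <- list()
  for (code in seq_len(2L^(n - 1L) - 1L)) {
    side <- which(as.logical(bitwAnd(code, 2L^(0:(n - 2L))))) + 1L
    a <- oracle_alpha(d, side)
    if (a > tol)
      out[[length(out) + 1L]] <- list(side = sort(rownames(d)[side]),
                                      weight = a)
  }
  out
}

# canonical string form of a split side for set comparison
split_key <- function(side) paste(sort(side), collapse = "|")

# random additive (tree) metric with its generating tree
random_tree_metric <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.05, 1), 3)
  d <- stats::cophenetic(tr)
  list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
}

# quick builder for locus alignments from unnamed sequences
aln <- function(seqs, locus = "locusA") {
  names(seqs) <- paste0("iso", seq_along(seqs))
  locus_alignment(seqs, locus)
}

# small two-locus scheme for typing tests
toy_scheme <- function() mlst_scheme(c("locA", "locB"), c(4L, 4L))
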