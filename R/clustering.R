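#' Hamming distance between two allelic profiles
#'
#' Number of loci at which the two profiles carry different allele numbers:
#' 0 for identical profiles, 1 for a single-locus variant (SLV), 2 for a
#' DLV, 3 for a TLV.
#'
#' @param p1,p2 integer vectors of equal length.
#' @return integer count of differing loci.
#' @export
profile_distance <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles differ in length")
  sum(p1 != p2)
}

#' All pairwise profile distances
#' @param profiles integer matrix (rows = STs, columns = loci) or an
#'   \code{\link{mlst_typing}} (its ST profile matrix is used).
#' @return symmetric integer matrix of Hamming distances.
#' @export
profile_dist_matrix <- function(profiles) {
  m <- if (inherits(profiles, "mlst_typing")) profiles$profiles
       else as.matrix(profiles)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m)))
    d <- d + outer(m[, j], m[, j], "!=")
  storage.mode(d) <- "integer"
  d
}

typing_or_matrix <- function(x) {
  if (inherits(x, "mlst_typing"))
    list(profiles = x$profiles,
         counts = x$st_counts[rownames(x$profiles)])
  else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
    list(profiles = m,
         counts = stats::setNames(rep(1L, nrow(m)), rownames(m)))
  }
}

#' Classify the locus variants of a sequence type
#'
#' Partitions all other STs by Hamming distance from the query profile:
#' single-locus variants (distance 1), double-locus (2) and triple-locus
#' variants (3).
#'
#' @param st ST number (rowname in the profile matrix).
#' @param typing an \code{\link{mlst_typing}} or ST profile matrix.
#' @return list with integer vectors \code{slv}, \code{dlv}, \code{tlv} of
#'   ST numbers.
#' @export
classify_variants <- function(st, typing) {
  tm <- typing_or_matrix(typing)
  st <- as.character(st)
  if (!st %in% rownames(tm$profiles)) stop("unknown ST: ", st)
  d <- profile_dist_matrix(tm$profiles)[st, ]
  d <- d[names(d) != st]
  list(slv = as.integer(names(d)[d == 1L]),
       dlv = as.integer(names(d)[d == 2L]),
       tlv = as.integer(names(d)[d == 3L]))
}

#' Find clonal complexes by single-linkage profile sharing
#'
#' A clonal complex (CC) groups STs whose profiles share at least
#' \code{shared_loci} of the L scheme loci, i.e. single-linkage connected
#' components of the graph joining STs at Hamming distance at most
#' \code{L - shared_loci}.  The default 9-of-11 sharing admits single- and
#' double-locus variants into the same complex; \code{shared_loci = L - 1}
#' gives the classic SLV-only eBURST grouping.  Components of size 1 are
#' singletons, not CCs.
#'
#' @param typing an \code{\link{mlst_typing}} or ST profile matrix.
#' @param shared_loci minimum number of shared loci (default
#'   \code{n_loci - 2}, i.e. 9 of 11 for the standard scheme).
#' @return An object of class \code{cc_result}: list with
#'   \code{complexes} (list of \code{clonal_complex} objects, ordered by
#'   decreasing isolate count), \code{singletons} (integer vector of ST
#'   numbers), \code{shared_loci}, \code{threshold}.
#' @export
find_clonal_complexes <- function(typing, shared_loci = NULL) {
  tm <- typing_or_matrix(typing)
  L <- ncol(tm$profiles)
  if (is.null(shared_loci)) shared_loci <- L - 2L
  if (shared_loci > L || shared_loci < 1L)
    stop("shared_loci must be between 1 and ", L)
  threshold <- L - shared_loci
  d <- profile_dist_matrix(tm$profiles)
  n <- nrow(d)
  ## union-find over STs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    if (d[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  root <- vapply(seq_len(n), find, 0L)
  sts <- as.integer(rownames(tm$profiles))
  comps <- split(seq_len(n), root)
  singles <- integer(0)
  ccs <- list()
  for (comp in comps) {
    if (length(comp) == 1L) { singles <- c(singles, sts[comp]); next }
    members <- sts[comp]
    dd <- d[comp, comp, drop = FALSE]
    slv <- rowSums(dd == 1L)
    dlv <- rowSums(dd == 2L)
    counts <- tm$counts[as.character(members)]
    cc <- structure(list(members = members,
                         n_isolates = sum(counts),
                         member_counts = counts,
                         slv_counts = stats::setNames(as.integer(slv), members),
                         dlv_counts = stats::setNames(as.integer(dlv), members),
                         founder = NA_integer_),
                    class = "clonal_complex")
    cc$founder <- predict_founder(cc)
    ccs[[length(ccs) + 1L]] <- cc
  }
  ord <- order(-vapply(ccs, function(cc) cc$n_isolates, 0),
               vapply(ccs, function(cc) min(cc$members), 0L))
  ccs <- ccs[ord]
  for (i in seq_along(ccs)) ccs[[i]]$id <- i
  structure(list(complexes = ccs, singletons = sort(singles),
                 shared_loci = as.integer(shared_loci),
                 threshold = as.integer(threshold)),
            class = "cc_result")
}

#' Predict the founder (ancestral genotype) of a clonal complex
#'
#' eBURST-style founder prediction: the member with the most single-locus
#' variants within the complex; ties broken by double-locus variant count,
#' then by isolate count, then by lowest ST number.  Deterministic.
#'
#' @param cc a \code{clonal_complex} (element of
#'   \code{\link{find_clonal_complexes}} output).
#' @return integer ST number of the predicted founder.
#' @export
predict_founder <- function(cc) {
  if (length(cc$members) < 2L) stop("a clonal complex has >= 2 members")
  ord <- order(-cc$slv_counts, -cc$dlv_counts,
               -as.integer(cc$member_counts), cc$members)
  cc$members[ord[1L]]
}

#' @export
print.clonal_complex <- function(x, ...) {
  cat("CC", if (!is.null(x$id)) x$id else "", ": ", length(x$members),
      " STs, ", x$n_isolates, " isolates; founder ST-", x$founder,
      " (", x$slv_counts[as.character(x$founder)], " SLVs)\n", sep = "")
  invisible(x)
}

#' @export
print.cc_result <- function(x, ...) {
  cat("Clonal complexes at >=", x$shared_loci, "shared loci (distance <=",
      x$threshold, "):", length(x$complexes), "CCs,",
      length(x$singletons), "singleton STs\n")
  for (cc in x$complexes) print(cc)
  invisible(x)
}

#' Minimum spanning tree over allelic profiles
#'
#' Prim's algorithm on the complete graph of STs weighted by profile Hamming
#' distance.  Ties between equal-weight candidate edges are resolved
#' deterministically, preferring attachment to the tree node with the most
#' SLVs in the whole dataset, then the greatest isolate count, then the
#' lowest ST number (and the same keys for the candidate outside node).
#'
#' @param typing an \code{\link{mlst_typing}} or ST profile matrix.
#' @return An object of class \code{mlst_mst}: list with \code{nodes} (data
#'   frame \code{st}, \code{n_isolates}), \code{edges} (data frame
#'   \code{from}, \code{to}, \code{weight}), \code{total_weight}.
#' @export
build_mst <- function(typing) {
  tm <- typing_or_matrix(typing)
  d <- profile_dist_matrix(tm$profiles)
  sts <- as.integer(rownames(tm$profiles))
  n <- length(sts)
  counts <- as.integer(tm$counts[as.character(sts)])
  slv_tot <- if (n > 1L) rowSums(d == 1L) else 0L
  nodes <- data.frame(st = sts, n_isolates = counts)
  if (n == 1L)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             weight = integer(0)),
                          total_weight = 0L), class = "mlst_mst"))
  ## start from the "best" node under the tie keys
  start <- order(-slv_tot, -counts, sts)[1L]
  in_tree <- rep(FALSE, n)
  in_tree[start] <- TRUE
  edges <- matrix(0L, nrow = n - 1L, ncol = 3L)
  for (k in seq_len(n - 1L)) {
    tree_idx <- which(in_tree)
    out_idx <- which(!in_tree)
    sub <- d[tree_idx, out_idx, drop = FALSE]
    wmin <- min(sub)
    cand <- which(sub == wmin, arr.ind = TRUE)
    ti <- tree_idx[cand[, 1L]]
    oi <- out_idx[cand[, 2L]]
    pick <- order(-slv_tot[ti], -counts[ti], sts[ti],
                  -slv_tot[oi], -counts[oi], sts[oi])[1L]
    edges[k, ] <- c(sts[ti[pick]], sts[oi[pick]], wmin)
    in_tree[oi[pick]] <- TRUE
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges[, 1L], to = edges[, 2L],
                                    weight = edges[, 3L]),
                 total_weight = sum(edges[, 3L])),
            class = "mlst_mst")
}

#' @export
print.mlst_mst <- function(x, ...) {
  cat("Minimum spanning tree:", nrow(x$nodes), "STs,",
      nrow(x$edges), "edges, total weight", x$total_weight, "\n")
  invisible(x)
}

#' Export a minimum spanning tree as GraphML
#'
#' Node attributes: ST number, isolate count, and any extra per-ST metadata
#' supplied; edge attribute: weight (number of differing loci).  The file is
#' readable by yEd, Gephi, igraph and PHYLOViZ-adjacent tools.
#'
#' @param mst an \code{\link{build_mst}} result.
#' @param path output path.
#' @param node_meta optional data frame with an \code{st} column and extra
#'   annotation columns (e.g. source, geography).
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(mst, path, node_meta = NULL) {
  nodes <- mst$nodes
  if (!is.null(node_meta)) nodes <- merge(nodes, node_meta, by = "st",
                                          all.x = TRUE, sort = FALSE)
  keys <- setdiff(names(nodes), "st")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  for (k in keys)
    w('  <key id="', k, '" for="node" attr.name="', k,
      '" attr.type="string"/>')
  w('  <key id="weight" for="edge" attr.name="weight" attr.type="int"/>')
  w('  <graph id="mst" edgedefault="undirected">')
  for (i in seq_len(nrow(nodes))) {
    w('    <node id="ST', nodes$st[i], '">')
    for (k in keys)
      w('      <data key="', k, '">', esc(nodes[[k]][i]), '</data>')
    w('    </node>')
  }
  for (i in seq_len(nrow(mst$edges)))
    w('    <edge source="ST', mst$edges$from[i], '" target="ST',
      mst$edges$to[i], '"><data key="weight">', mst$edges$weight[i],
      '</data></edge>')
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}
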