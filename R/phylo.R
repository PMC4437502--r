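#' Concatenate per-locus alignments in scheme order
#'
#' Joins each taxon's fragments across all scheme loci into one sequence of
#' total length equal to the scheme length.  With \code{typing} supplied and
#' \code{one_per_st = TRUE}, one representative concatenated sequence is kept
#' per sequence type (isolates of the same ST have identical concatenated
#' sequences by construction) and taxa are labelled \code{ST<k>}.
#'
#' @param sequence_sets list of \code{\link{locus_alignment}} objects
#'   covering every scheme locus, with a common isolate set.
#' @param scheme an \code{mlst_scheme}.
#' @param typing optional \code{\link{mlst_typing}} (required for
#'   \code{one_per_st}).
#' @param one_per_st collapse to one taxon per ST (default \code{FALSE}).
#' @return a \code{\link{locus_alignment}} with locus name
#'   \code{"concatenated"}.
#' @export
concatenate_alignments <- function(sequence_sets, scheme, typing = NULL,
                                   one_per_st = FALSE) {
  names(sequence_sets) <- vapply(sequence_sets, function(x) x$locus, "")
  missing <- setdiff(scheme$locus, names(sequence_sets))
  if (length(missing))
    stop("missing locus/loci: ", paste(missing, collapse = ", "))
  sequence_sets <- sequence_sets[scheme$locus]
  ids <- names(sequence_sets[[1L]]$sequences)
  for (ss in sequence_sets) {
    gone <- setdiff(ids, names(ss$sequences))
    if (length(gone))
      stop("taxon/taxa missing at locus '", ss$locus, "': ",
           paste(gone, collapse = ", "))
  }
  cat_seq <- vapply(ids, function(id)
    paste0(vapply(sequence_sets, function(ss) ss$sequences[[id]], "")
           , collapse = ""), "")
  names(cat_seq) <- ids
  if (one_per_st) {
    if (is.null(typing)) stop("one_per_st requires a typing result")
    st <- typing$isolates$ST[match(ids, typing$isolates$isolate)]
    if (any(is.na(st))) stop("isolates missing from the typing result")
    keep <- !duplicated(st)
    cat_seq <- cat_seq[keep]
    names(cat_seq) <- paste0("ST", st[keep])
    cat_seq <- cat_seq[order(as.integer(sub("^ST", "", names(cat_seq))))]
  }
  locus_alignment(cat_seq, "concatenated")
}

#' Pairwise distance matrix from an alignment
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param model \code{"p"} (uncorrected proportion of differing sites, the
#'   default), \code{"JC69"} or \code{"K2P"}.
#' @return symmetric numeric matrix with taxa dimnames and zero diagonal.
#'   JC69/K2P are undefined (error) when divergence reaches the model's
#'   saturation bound.
#' @export
compute_distance_matrix <- function(alignment, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  if (n_seqs(alignment) < 2L) stop("need at least 2 sequences")
  dna <- ape::as.DNAbin(lapply(strsplit(tolower(alignment$sequences), ""),
                               identity))
  mod <- switch(model, p = "raw", JC69 = "JC69", K2P = "K80")
  d <- ape::dist.dna(dna, model = mod, pairwise.deletion = FALSE,
                     as.matrix = TRUE)
  if (any(!is.finite(d)))
    stop(model, " distance undefined for at least one pair ",
         "(divergence beyond the model's saturation bound)")
  d
}

validate_dist <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- seq_len(nrow(d))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a distance matrix, with taxa ordered by
#' label for deterministic tie-breaking.  Negative branch lengths (an
#' artefact of the NJ least-squares step) are clamped to zero and the
#' deficit transferred to the adjacent sibling branch, preserving path
#' lengths through the parent node.
#'
#' @param dm symmetric distance matrix with taxa labels.
#' @return an \code{ape} \code{phylo} object (unrooted).
#' @export
neighbor_joining <- function(dm) {
  d <- validate_dist(dm)
  n <- nrow(d)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  labs <- rownames(d)
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = rep(d[1L, 2L] / 2, 2L),
                 tip.label = labs, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  if (n == 3L) {
    bl <- c((d[1,2] + d[1,3] - d[2,3]) / 2,
            (d[1,2] + d[2,3] - d[1,3]) / 2,
            (d[1,3] + d[2,3] - d[1,2]) / 2)
    tree <- list(edge = matrix(c(4L,1L, 4L,2L, 4L,3L), 3L, 2L, byrow = TRUE),
                 edge.length = bl, tip.label = labs, Nnode = 1L)
    class(tree) <- "phylo"
    return(clamp_negative_branches(tree))
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

## zero out negative branch lengths, moving the deficit to a sibling edge
## (an edge sharing the same parent node) so distances through the parent
## are preserved where possible
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sib))
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] +
        tree$edge.length[e]
    tree$edge.length[e] <- 0
    ## a sibling may now be negative; loop until clean, flooring any
    ## residual negatives (possible when the sibling had length ~0)
    if (all(tree$edge.length[tree$edge.length < 0] > -1e-12)) {
      tree$edge.length[tree$edge.length < 0] <- 0
      break
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

## canonical string keys for the non-trivial bipartitions of a tree:
## for each internal edge, the sorted labels of the side NOT containing the
## alphabetically first taxon
tree_bipartitions <- function(tree) {
  ## an internal edge of length ~0 is a polytomy, not a resolved split
  ## (NJ resolves star-like data arbitrarily); collapse before extraction
  if (!is.null(tree$edge.length))
    tree <- ape::di2multi(tree, tol = 1e-10)
  labs <- sort(tree$tip.label)
  first <- labs[1L]
  pp <- ape::prop.part(tree)
  out <- character(0)
  ntip <- length(tree$tip.label)
  for (cl in pp) {
    if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
    side <- sort(tree$tip.label[cl])
    if (first %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Site-resampling bootstrap: alignment columns are resampled with
#' replacement \code{n_replicates} times, a NJ tree is built from each
#' replicate, and the support of every internal edge of the reference tree
#' is the percentage of replicate trees containing the same bipartition.
#' Supports are stored as integer percentages in \code{node.label}.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer RNG seed (mandatory).
#' @param model distance model, see \code{\link{compute_distance_matrix}}.
#' @return list with \code{tree} (the reference \code{phylo}, node labels =
#'   support percentages) and \code{support} (named numeric vector keyed by
#'   bipartition).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed,
                              model = "p") {
  if (missing(seed)) stop("a seed is required")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  ref <- neighbor_joining(compute_distance_matrix(alignment, model))
  keys <- tree_bipartitions(ref)
  hits <- stats::setNames(numeric(length(keys)), keys)
  m <- aln_matrix(alignment)
  rng <- local_rng(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    boot <- m[, cols, drop = FALSE]
    seqs <- apply(boot, 1L, paste0, collapse = "")
    aln_b <- locus_alignment(stats::setNames(seqs, rownames(m)),
                             alignment$locus)
    tr_b <- try(neighbor_joining(compute_distance_matrix(aln_b, model)),
                silent = TRUE)
    if (inherits(tr_b, "try-error")) next
    bk <- tree_bipartitions(tr_b)
    hits[keys %in% bk] <- hits[keys %in% bk] + 1
  }
  rng$restore()
  support <- round(100 * hits / n_replicates)
  tree <- annotate_support(ref, support)
  list(tree = tree, support = support)
}

## write supports into node.label, matching internal nodes to bipartitions
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  first <- labs[1L]
  pp <- ape::prop.part(tree)
  node.label <- rep("", tree$Nnode)
  for (i in seq_along(pp)) {
    cl <- pp[[i]]
    if (length(cl) <= 1L || length(cl) >= ntip - 1L) next
    side <- sort(tree$tip.label[cl])
    if (first %in% side) side <- setdiff(labs, side)
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) node.label[i] <- as.character(support[key])
  }
  tree$node.label <- node.label
  tree
}
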