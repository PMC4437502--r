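## Bandelt-Dress split decomposition -------------------------------------
##
## A bipartition A|B of the taxa is a d-split when its isolation index
##   alpha(A,B) = 1/2 * min over a,a' in A; b,b' in B of
##     max(d(a,b)+d(a',b'), d(a,b')+d(a',b), d(a,a')+d(b,b'))
##       - d(a,a') - d(b,b')
## is strictly positive.  On a tree metric the d-splits are exactly the
## tree's edges (alpha = branch length); incompatible d-splits draw as
## parallelograms in a splits graph, the classic signature of
## recombination.

## min over a' in Aside (and pairs b,b' in Bside) of the quadruple term
## beta(x, a', b, b'); vectorised over the B side.  x, Aside, Bside are
## integer taxon indices into d.
beta_min <- function(d, x, Aside, Bside) {
  dBB <- d[Bside, Bside, drop = FALSE]
  best <- Inf
  for (a2 in Aside) {
    u <- d[x, Bside]
    v <- d[a2, Bside]
    X <- outer(u, v, "+")            # d(x,b) + d(a2,b')
    daa <- d[x, a2]
    M <- pmax(X, t(X), daa + dBB)
    best <- min(best, min(M - daa - dBB))
  }
  best
}

## isolation index contribution of quadruples involving new taxon x when x
## joins side A of split A|B (a' ranges over A plus x itself)
alpha_increment <- function(d, x, Aside, Bside) {
  0.5 * beta_min(d, x, c(Aside, x), Bside)
}

#' Split decomposition of a distance matrix
#'
#' Computes all d-splits of Bandelt and Dress by incremental taxon
#' insertion: starting from two taxa, each further taxon is added to either
#' side of every current split (and as a new trivial split), and candidates
#' are retained while their isolation index \eqn{\alpha} stays positive.
#' The isolation index is maintained incrementally, which is exact because
#' \eqn{\alpha} on the enlarged taxon set is the minimum of the old value
#' and the quadruples involving the new taxon.
#'
#' The fit statistic is the percentage of the total pairwise distance
#' explained by the split metric, \eqn{100 \sum_{i<j} \sum_S \alpha_S
#' [S \mathrm{ separates } i,j] / \sum_{i<j} d_{ij}}; it is 100 for tree
#' metrics.  The number of d-splits is at most \eqn{n(n-1)/2}, but the
#' candidate set can grow quickly on noisy data, so a configurable cap
#' guards against blow-up.
#'
#' @param dm symmetric distance matrix with taxa labels.
#' @param max_splits error out if the retained split count exceeds this cap
#'   (default 5000).
#' @param tol isolation indices at or below this threshold count as zero,
#'   suppressing floating-point ghost splits; default
#'   \code{1e-9 * max(dm)} (with an absolute floor of 1e-12).
#' @return An object of class \code{split_set}: list with \code{taxa},
#'   \code{splits} (each a list with \code{side} = taxa labels of the side
#'   not containing the first taxon, and \code{weight} = \eqn{\alpha}), and
#'   \code{fit} (percent).
#' @examples
#' d <- matrix(c(0, 3, 3, 3, 0, 2, 3, 2, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' split_decomposition(d)
#' @export
split_decomposition <- function(dm, max_splits = 5000L, tol = NULL) {
  d <- validate_dist(dm)
  taxa <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(tol)) tol <- max(1e-12, 1e-9 * max(d))
  ## splits are stored as logical membership vectors over taxa 1..k (TRUE =
  ## same side as NOT taxon 1), with their current alpha
  sides <- list(2L)                       # split {1}|{2}
  alphas <- d[1L, 2L]
  if (n > 2L) for (k in 3L:n) {
    new_sides <- list()
    new_alphas <- numeric(0)
    prev <- seq_len(k - 1L)
    for (s in seq_along(sides)) {
      B <- sides[[s]]                     # side not containing taxon 1
      A <- setdiff(prev, B)
      a0 <- alphas[s]
      ## candidate: x joins A (the taxon-1 side)
      a_inc <- alpha_increment(d, k, A, B)
      a_new <- min(a0, a_inc)
      if (a_new > tol) {
        new_sides[[length(new_sides) + 1L]] <- B
        new_alphas <- c(new_alphas, a_new)
      }
      ## candidate: x joins B
      b_inc <- alpha_increment(d, k, B, A)
      b_new <- min(a0, b_inc)
      if (b_new > tol) {
        new_sides[[length(new_sides) + 1L]] <- c(B, k)
        new_alphas <- c(new_alphas, b_new)
      }
    }
    ## trivial split {x} | rest
    triv <- 0.5 * beta_min(d, k, k, prev)
    if (triv > tol) {
      new_sides[[length(new_sides) + 1L]] <- k
      new_alphas <- c(new_alphas, triv)
    }
    if (length(new_sides) > max_splits)
      stop("split count exceeded cap (", max_splits,
           ") at taxon ", k, "; raise max_splits if this is intended")
    sides <- new_sides
    alphas <- new_alphas
  }
  splits <- Map(function(side, a) list(side = taxa[side], weight = a),
                sides, alphas)
  ## fit: share of pairwise distance explained by the split metric
  sd_mat <- matrix(0, n, n)
  for (i in seq_along(sides)) {
    memb <- seq_len(n) %in% sides[[i]]
    sep <- outer(memb, memb, "!=")
    sd_mat <- sd_mat + alphas[i] * sep
  }
  tot <- sum(d[upper.tri(d)])
  fit <- if (tot > 0) 100 * sum(sd_mat[upper.tri(sd_mat)]) / tot else 100
  structure(list(taxa = taxa, splits = splits, fit = fit),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("Split decomposition:", length(x$splits), "d-splits over",
      length(x$taxa), "taxa; fit", sprintf("%.1f%%", x$fit), "\n")
  triv <- vapply(x$splits, function(s)
    length(s$side) == 1L || length(s$side) == length(x$taxa) - 1L, TRUE)
  cat("  trivial:", sum(triv), " non-trivial:", sum(!triv), "\n")
  invisible(x)
}

#' Split metric distance implied by a split set
#'
#' Sum of isolation indices of the splits separating each pair; always a
#' lower bound on the input metric.
#'
#' @param splits a \code{split_set}.
#' @return symmetric numeric matrix.
#' @export
split_metric <- function(splits) {
  n <- length(splits$taxa)
  out <- matrix(0, n, n, dimnames = list(splits$taxa, splits$taxa))
  for (s in splits$splits) {
    memb <- splits$taxa %in% s$side
    out <- out + s$weight * outer(memb, memb, "!=")
  }
  out
}
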