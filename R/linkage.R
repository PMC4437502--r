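## profiles input normaliser: accepts an mlst_typing, a data frame from
## read_profile_table, or an integer matrix (rows = units, cols = loci)
as_profile_matrix <- function(profiles, unique_sts = FALSE) {
  if (inherits(profiles, "mlst_typing")) {
    m <- if (unique_sts) profiles$profiles else isolate_profiles(profiles)
  } else if (is.data.frame(profiles)) {
    cols <- setdiff(names(profiles), c("isolate", "ST"))
    m <- as.matrix(profiles[, cols, drop = FALSE])
    if (!is.null(profiles$isolate)) rownames(m) <- profiles$isolate
    if (unique_sts) m <- unique(m)
  } else {
    m <- as.matrix(profiles)
    if (unique_sts) m <- unique(m)
  }
  storage.mode(m) <- "integer"
  m
}

#' Pairwise mismatch distribution of allelic profiles
#'
#' For every unordered pair of profiles, the number of loci at which the two
#' differ (0..L).  This distribution underlies the index of association:
#' under free recombination its variance matches the independent-loci
#' expectation, while clonality inflates it.
#'
#' @param profiles an \code{\link{mlst_typing}}, a profile data frame, or an
#'   integer matrix (rows = isolates, columns = loci).
#' @return integer vector of length n(n-1)/2.
#' @export
mismatch_distribution <- function(profiles) {
  m <- as_profile_matrix(profiles)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 profiles")
  idx <- pair_indices(n)
  mm <- integer(nrow(idx))
  for (j in seq_len(ncol(m)))
    mm <- mm + (m[idx[, 1L], j] != m[idx[, 2L], j])
  mm
}

pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

## core I_A computation on an integer matrix; returns the pieces
ia_core <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  idx <- pair_indices(n)
  mm <- integer(nrow(idx))
  h <- numeric(L)
  for (j in seq_len(L)) {
    aj <- m[, j]
    mm <- mm + (aj[idx[, 1L]] != aj[idx[, 2L]])
    p <- tabulate(match(aj, unique(aj))) / n
    h[j] <- (n / (n - 1)) * (1 - sum(p^2))
  }
  v_o <- mean(mm^2) - mean(mm)^2          # population variance over pairs
  v_e <- sum(h * (1 - h))
  list(v_o = v_o, v_e = v_e, h = h, mismatches = mm)
}

#' Index of association I_A and its standardized form
#'
#' Measures multilocus linkage disequilibrium from allelic profiles.  With
#' \eqn{V_O} the (population) variance of the pairwise mismatch distribution
#' and \eqn{V_E = \sum_j h_j (1 - h_j)} its expectation under independent
#' loci, where \eqn{h_j = \frac{n}{n-1}(1 - \sum_i p_i^2)} is the unbiased
#' gene diversity of locus \eqn{j},
#' \deqn{I_A = V_O / V_E - 1, \qquad I_A^S = I_A / (L - 1).}
#' \eqn{I_A^S = 0} is the expectation under free recombination (panmixia);
#' values above 0 indicate linkage disequilibrium, i.e. clonality.
#'
#' @param profiles an \code{\link{mlst_typing}}, profile data frame, or
#'   integer matrix.
#' @param unique_sts if \code{TRUE}, collapse to one profile per distinct ST
#'   before computing (both conventions are common in the literature;
#'   default \code{FALSE} uses every isolate).
#' @param unbiased_h use the \eqn{n/(n-1)} correction in \eqn{h_j}
#'   (default \code{TRUE}, the LIAN convention).
#' @return An object of class \code{linkage_result}: list with
#'   \code{n_isolates}, \code{n_loci}, \code{v_o}, \code{v_e}, \code{i_a},
#'   \code{i_a_s}, and \code{NA} p-value fields (see
#'   \code{\link{ia_permutation_test}}).
#' @examples
#' m <- rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2))
#' index_of_association(m)$i_a  # 1
#' @export
index_of_association <- function(profiles, unique_sts = FALSE,
                                 unbiased_h = TRUE) {
  m <- as_profile_matrix(profiles, unique_sts = unique_sts)
  if (nrow(m) < 3L) stop("need at least 3 profiles")
  core <- ia_core(m)
  if (!unbiased_h) {
    n <- nrow(m)
    h <- core$h * (n - 1) / n
    core$v_e <- sum(h * (1 - h))
  }
  if (core$v_e == 0)
    stop("V_E is zero (no allelic variation at any locus); I_A undefined")
  i_a <- core$v_o / core$v_e - 1
  structure(list(n_isolates = nrow(m), n_loci = ncol(m),
                 v_o = core$v_o, v_e = core$v_e,
                 i_a = i_a, i_a_s = standardize_ia(i_a, ncol(m)),
                 p_value = NA_real_, n_permutations = NA_integer_,
                 seed = NA_integer_),
            class = "linkage_result")
}

#' Standardize an index of association
#'
#' \eqn{I_A^S = I_A / (L - 1)}; the standardized index is comparable across
#' schemes with different numbers of loci.
#'
#' @param i_a index of association.
#' @param n_loci number of loci L.
#' @return numeric.
#' @examples
#' standardize_ia(2.1424, 11)  # 0.21424
#' @export
standardize_ia <- function(i_a, n_loci) {
  if (n_loci < 2L) stop("need at least 2 loci")
  i_a / (n_loci - 1)
}

#' Permutation test for linkage disequilibrium
#'
#' The null hypothesis of free recombination is simulated by independently
#' permuting the allele column of each locus across isolates, which
#' preserves allele frequencies but destroys associations.  The p-value uses
#' the add-one correction \eqn{p = (1 + \#\{I_{A,perm}^S \ge
#' I_{A,obs}^S\})/(1 + B)}, so the smallest reportable value is
#' \eqn{1/(B+1)} ("p = 0.000" is reported as p < 0.001 at B = 999).
#'
#' @param profiles as in \code{\link{index_of_association}}.
#' @param n_permutations number of permutations B (default 1000).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param unique_sts,unbiased_h as in \code{\link{index_of_association}}.
#' @return A \code{linkage_result} with \code{p_value},
#'   \code{n_permutations} and \code{seed} filled in.
#' @export
ia_permutation_test <- function(profiles, n_permutations = 1000L, seed,
                                unique_sts = FALSE, unbiased_h = TRUE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (missing(seed)) stop("a seed is required")
  res <- index_of_association(profiles, unique_sts = unique_sts,
                              unbiased_h = unbiased_h)
  m <- as_profile_matrix(profiles, unique_sts = unique_sts)
  n <- nrow(m)
  rng <- local_rng(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- m
    for (j in seq_len(ncol(m))) perm[, j] <- m[sample.int(n), j]
    core <- ia_core(perm)
    v_e <- core$v_e
    if (!unbiased_h) {
      h <- core$h * (n - 1) / n
      v_e <- sum(h * (1 - h))
    }
    ia_b <- if (v_e > 0) core$v_o / v_e - 1 else 0
    if (standardize_ia(ia_b, ncol(m)) >= res$i_a_s) exceed <- exceed + 1L
  }
  rng$restore()
  res$p_value <- (1 + exceed) / (1 + n_permutations)
  res$n_permutations <- as.integer(n_permutations)
  res$seed <- as.integer(seed)
  res
}

## seed the RNG locally, restoring the caller's state on $restore()
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Multilocus linkage disequilibrium (", x$n_isolates, " profiles, ",
      x$n_loci, " loci)\n", sep = "")
  cat(sprintf("  V_O = %.4f  V_E = %.4f\n", x$v_o, x$v_e))
  cat(sprintf("  I_A = %.4f  I_A^S = %.4f\n", x$i_a, x$i_a_s))
  if (!is.na(x$p_value)) {
    floor_p <- 1 / (1 + x$n_permutations)
    ptxt <- if (x$p_value <= floor_p)
      sprintf("p < %.3g", floor_p) else sprintf("p = %.4f", x$p_value)
    cat("  ", ptxt, " (", x$n_permutations, " permutations, seed ",
        x$seed, ")\n", sep = "")
  }
  invisible(x)
}
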