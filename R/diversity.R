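## Standard genetic code; "*" marks stop codons.
GENETIC_CODE1 <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

BASES <- c("A", "C", "G", "T")

#' Count polymorphic (segregating) sites
#'
#' Number of alignment columns at which at least two distinct bases occur.
#'
#' @param alignment a \code{\link{locus_alignment}} with at least two
#'   sequences.
#' @return integer count.
#' @examples
#' count_polymorphic_sites(locus_alignment(c(a = "AAAA", b = "AATT"), "x"))
#' @export
count_polymorphic_sites <- function(alignment) {
  m <- aln_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' Mean G+C content
#'
#' Per-sequence G+C percentage, averaged over all sequences in the set.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @return percentage in [0, 100].
#' @export
gc_content <- function(alignment) {
  s <- alignment$sequences
  if (!length(s)) stop("empty sequence set")
  gc <- vapply(s, function(x) {
    b <- strsplit(x, "", fixed = TRUE)[[1L]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, 0)
  mean(gc)
}

## distinct sequences in first-observation order
distinct_seqs <- function(alignment) unique(unname(alignment$sequences))

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise nucleotide differences per site, without any
#' distance correction:
#' \deqn{\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2} \, L_{bp}}}
#' where \eqn{d_{ij}} is the raw count of mismatching positions.  By default
#' the pairs range over \emph{distinct alleles} with equal weight (the
#' convention of allele-oriented MLST tools); \code{unit = "isolate"} uses
#' every isolate pair instead, weighting alleles by their frequency.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param unit \code{"allele"} (default) or \code{"isolate"}.
#' @return nucleotide diversity per site (dimensionless, >= 0).
#' @export
nucleotide_diversity <- function(alignment, unit = c("allele", "isolate")) {
  unit <- match.arg(unit)
  seqs <- if (unit == "allele") distinct_seqs(alignment)
          else unname(alignment$sequences)
  n <- length(seqs)
  if (n < 2L) {
    if (length(alignment$sequences) >= 2L) return(0)  # all identical alleles
    stop("need at least 2 sequences")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  lbp <- ncol(m)
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      total <- total + sum(m[i, ] != m[j, ])
  total / (n * (n - 1) / 2 * lbp)
}

## ---- Nei-Gojobori (1986) pathway counting -------------------------------

## fraction of the 3 possible changes at each codon position that are
## synonymous; returns total synonymous sites of the codon (0..3)
ng_syn_sites <- function(codon) {
  aa <- GENETIC_CODE1[[codon]]
  b <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(BASES, b[pos])) {
      mut <- b
      mut[pos] <- alt
      if (GENETIC_CODE1[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous differences between two codons over all
## minimal mutational pathways (1, 2 or 6 orderings); steps to or from a stop
## codon count as nonsynonymous, stop->stop as synonymous
ng_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  b2 <- strsplit(c2, "")[[1L]]
  sd <- nd <- 0
  for (ord in perms) {
    cur <- strsplit(c1, "")[[1L]]
    for (step in ord) {
      nxt <- cur
      nxt[pos[step]] <- b2[pos[step]]
      if (GENETIC_CODE1[[paste(cur, collapse = "")]] ==
          GENETIC_CODE1[[paste(nxt, collapse = "")]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
  }
  c(sd = sd / length(perms), nd = nd / length(perms))
}

split_codons <- function(seq, offset = 0L) {
  s <- substr(seq, offset + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Nei-Gojobori dN/dS for a locus alignment
#'
#' Pathway-counting estimate of synonymous and non-synonymous divergence
#' (Nei & Gojobori 1986).  For every pair of \emph{distinct alleles},
#' synonymous (S) and non-synonymous (N) sites are counted per sequence and
#' the observed synonymous/non-synonymous differences are averaged over all
#' minimal mutational pathways per codon.  The pairwise proportions
#' \eqn{p_S = S_d/S}, \eqn{p_N = N_d/N} are Jukes-Cantor corrected,
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}, and averaged over pairs;
#' the reported ratio is the ratio of those means (stable when individual
#' pairs have \eqn{S_d = 0}).
#'
#' Sentinels: \eqn{d_N = 0} gives ratio 0 (no amino-acid change, the common
#' housekeeping-gene outcome); \eqn{d_S = 0 < d_N} gives the character
#' sentinel \code{"UNDEFINED"}, never a number.  A pairwise \eqn{p_S \ge 3/4}
#' leaves that pair's \eqn{d_S} undefined (NA); this only becomes an error if
#' the ratio needs it (i.e. \eqn{d_N > 0}).
#'
#' @param alignment a \code{\link{locus_alignment}}; sequences must be in
#'   frame after removing \code{frame_offset} leading bases, with length
#'   divisible by 3.
#' @param frame_offset 0, 1 or 2 leading bases to skip (default 0).
#' @param incomplete handling of a trailing partial codon after the offset:
#'   \code{"trim"} (default; the 1-2 leftover bases are ignored, as codon
#'   tools do with declared frames -- housekeeping fragment sizes are rarely
#'   multiples of 3) or \code{"error"}.
#' @param on_stop what to do with internal stop codons: \code{"warn_skip"}
#'   (default; the codon column is excluded with a warning) or
#'   \code{"error"}.
#' @return list with \code{dn}, \code{ds} (mean pairwise corrected
#'   distances), \code{dnds} (numeric ratio, or 0, or \code{"UNDEFINED"}),
#'   and \code{n_pairs}.
#' @export
nei_gojobori_dnds <- function(alignment, frame_offset = 0L,
                              incomplete = c("trim", "error"),
                              on_stop = c("warn_skip", "error")) {
  on_stop <- match.arg(on_stop)
  incomplete <- match.arg(incomplete)
  alleles <- distinct_seqs(alignment)
  usable <- nchar(alleles[1L]) - frame_offset
  if (usable %% 3L != 0L && incomplete == "error")
    stop("sequence length ", usable, " after offset ", frame_offset,
         " is not divisible by 3")
  if (length(alleles) < 2L)
    return(list(dn = 0, ds = 0, dnds = 0, n_pairs = 0L))
  cod <- lapply(alleles, split_codons, offset = frame_offset)
  cod <- do.call(rbind, cod)  # alleles x codons
  is_stop <- apply(cod, 2L, function(cc) any(GENETIC_CODE1[cc] == "*"))
  if (any(is_stop)) {
    if (on_stop == "error")
      stop("internal stop codon at codon position(s): ",
           paste(which(is_stop), collapse = ", "))
    warning("skipping ", sum(is_stop), " codon column(s) containing stops")
    cod <- cod[, !is_stop, drop = FALSE]
  }
  if (!ncol(cod)) stop("no codons left after removing stop columns")
  syn <- matrix(vapply(cod, ng_syn_sites, 0), nrow = nrow(cod))
  s_per_seq <- rowSums(syn)
  total_sites <- 3 * ncol(cod)
  n <- nrow(cod)
  dn_list <- ds_list <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dif <- which(cod[i, ] != cod[j, ])
      sd <- nd <- 0
      for (k in dif) {
        d <- ng_pair_diffs(cod[i, k], cod[j, k])
        sd <- sd + d[["sd"]]
        nd <- nd + d[["nd"]]
      }
      s <- (s_per_seq[i] + s_per_seq[j]) / 2
      nsites <- total_sites - s
      ps <- if (s > 0) sd / s else 0
      pn <- if (nsites > 0) nd / nsites else 0
      ds_list <- c(ds_list, jc_correct(ps))
      dn_list <- c(dn_list, jc_correct(pn))
    }
  }
  dn <- mean(dn_list)
  ds <- mean(ds_list)
  if (is.na(dn))
    stop("Jukes-Cantor correction undefined for pN >= 3/4")
  dnds <- if (dn == 0) 0
          else if (is.na(ds)) stop("dS undefined (pS >= 3/4) with dN > 0")
          else if (ds == 0) "UNDEFINED"
          else dn / ds
  list(dn = dn, ds = ds, dnds = dnds,
       n_pairs = as.integer(n * (n - 1) / 2))
}

## Jukes-Cantor correction; NA when p >= 3/4 (correction undefined)
jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Per-locus diversity summary
#'
#' The Table-2-style row for one locus: distinct alleles, polymorphic sites,
#' mean G+C content, nucleotide diversity and Nei-Gojobori dN/dS.
#'
#' @param alignment a \code{\link{locus_alignment}}.
#' @param pi_unit passed to \code{\link{nucleotide_diversity}}.
#' @param frame_offset passed to \code{\link{nei_gojobori_dnds}}.
#' @return one-row data frame with columns \code{locus}, \code{n_alleles},
#'   \code{n_polymorphic_sites}, \code{gc_percent}, \code{pi}, \code{dn},
#'   \code{ds}, \code{dnds} (character: number or \code{"UNDEFINED"}),
#'   \code{fragment_length}.
#' @export
locus_diversity <- function(alignment, pi_unit = "allele",
                            frame_offset = 0L) {
  ng <- nei_gojobori_dnds(alignment, frame_offset = frame_offset)
  data.frame(
    locus = alignment$locus,
    n_alleles = length(distinct_seqs(alignment)),
    n_polymorphic_sites = count_polymorphic_sites(alignment),
    gc_percent = gc_content(alignment),
    pi = nucleotide_diversity(alignment, unit = pi_unit),
    dn = ng$dn, ds = ng$ds,
    dnds = as.character(ng$dnds),
    fragment_length = seq_length(alignment),
    stringsAsFactors = FALSE)
}

#' Diversity table for a whole scheme
#' @param sequence_sets list of \code{\link{locus_alignment}} objects.
#' @param scheme an \code{mlst_scheme}; rows are ordered by scheme order.
#' @param ... passed to \code{\link{locus_diversity}}.
#' @return data frame with one row per locus.
#' @export
diversity_table <- function(sequence_sets, scheme, ...) {
  names(sequence_sets) <- vapply(sequence_sets, function(x) x$locus, "")
  missing <- setdiff(scheme$locus, names(sequence_sets))
  if (length(missing))
    stop("missing locus/loci: ", paste(missing, collapse = ", "))
  do.call(rbind, lapply(sequence_sets[scheme$locus], locus_diversity, ...))
}

#' Scheme-level diversity totals
#'
#' Aggregates per-locus statistics: total polymorphic sites, total scheme
#' length, the polymorphism rate and the extreme-diversity loci.  The rate
#' is reported truncated (not rounded) to two decimals -- the convention of
#' published MLST diversity tables, e.g. 131/7592 = 1.7255\% is reported as
#' 1.72; the full-precision value is in \code{polymorphism_rate_exact}.
#'
#' @param stats data frame as returned by \code{\link{diversity_table}}
#'   (needs columns \code{locus}, \code{n_polymorphic_sites}, \code{pi} and
#'   \code{fragment_length}).
#' @param scheme an \code{mlst_scheme}; every scheme locus must be present.
#' @return list with \code{total_polymorphic_sites},
#'   \code{total_length}, \code{polymorphism_rate_percent},
#'   \code{min_pi}/\code{min_pi_locus}, \code{max_pi}/\code{max_pi_locus}.
#' @examples
#' # scheme totals from per-locus counts
#' sch <- lf_scheme()
#' st <- data.frame(locus = sch$locus,
#'                  n_polymorphic_sites = c(11,12,13,6,12,14,22,10,11,7,13),
#'                  pi = c(0.00634,0.01421,0.0061,0.00416,0.00393,0.00768,
#'                         0.00769,0.0056,0.00408,0.00514,0.00618),
#'                  fragment_length = sch$length)
#' summarize_scheme(st, sch)$polymorphism_rate_percent  # 1.72
#' @export
summarize_scheme <- function(stats, scheme) {
  missing <- setdiff(scheme$locus, stats$locus)
  if (length(missing))
    stop("missing locus/loci in stats: ", paste(missing, collapse = ", "))
  stats <- stats[match(scheme$locus, stats$locus), , drop = FALSE]
  total_sites <- sum(stats$n_polymorphic_sites)
  total_len <- sum(stats$fragment_length)
  imin <- which.min(stats$pi)
  imax <- which.max(stats$pi)
  list(total_polymorphic_sites = as.integer(total_sites),
       total_length = as.integer(total_len),
       polymorphism_rate_percent = trunc(1e4 * total_sites / total_len) / 100,
       polymorphism_rate_exact = 100 * total_sites / total_len,
       min_pi = stats$pi[imin], min_pi_locus = stats$locus[imin],
       max_pi = stats$pi[imax], max_pi_locus = stats$locus[imax])
}
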