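## deterministic small test populations with known truth ------------------

fixture_seeds <- c(star_cc = 1201L, two_groups = 1202L, panmictic = 1203L)

#' Emit a canned validation dataset
#'
#' Three deterministic small populations with full ground truth, used by the
#' test-suite and reproducible by anyone:
#' \describe{
#'   \item{\code{"star_cc"}}{a star-shaped clonal complex: one founder ST
#'     (10 isolates) surrounded by 5 single-locus variants (2 isolates
#'     each); founder prediction must recover the centre.}
#'   \item{\code{"two_groups"}}{a strictly clonal two-lineage population
#'     (no recombination, diverged founders); trees and split graphs must
#'     separate the lineages.}
#'   \item{\code{"panmictic"}}{independent loci: every isolate's allele at
#'     every locus drawn independently, so \eqn{I_A \approx 0} and the
#'     permutation test should reject at ~ the nominal rate.}
#' }
#'
#' @param suite_name one of \code{"star_cc"}, \code{"two_groups"},
#'   \code{"panmictic"}.
#' @param dir output directory; when \code{NULL} (default) nothing is
#'   written and the dataset is only returned.
#' @param seed RNG seed; defaults to a fixed per-suite seed so the canned
#'   data are byte-stable.
#' @return list with \code{sequence_sets}, \code{scheme}, \code{metadata},
#'   \code{truth} and (if written) \code{dir}.
#' @export
emit_fixtures <- function(suite_name = c("star_cc", "two_groups",
                                         "panmictic"),
                          dir = NULL, seed = NULL) {
  suite_name <- match.arg(suite_name)
  if (is.null(seed)) seed <- fixture_seeds[[suite_name]]
  fx <- switch(suite_name,
               star_cc = fixture_star_cc(seed),
               two_groups = fixture_two_groups(seed),
               panmictic = fixture_panmictic(seed))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ss in fx$sequence_sets)
      write_locus_fasta(ss, file.path(dir, paste0(ss$locus, ".fasta")))
    utils::write.table(fx$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(fx$truth, file.path(dir, "truth.json"))
    write_scheme(fx$scheme, file.path(dir, "scheme.yaml"))
    fx$dir <- dir
  }
  fx
}

## small 5-locus scheme used by the synthetic fixtures
fixture_scheme <- function() {
  mlst_scheme(paste0("loc", 1:5), c(120L, 150L, 120L, 135L, 150L))
}

## founder + 5 SLVs (one per locus... 5 loci) star complex
fixture_star_cc <- function(seed) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  sch <- fixture_scheme()
  L <- nrow(sch)
  base <- lapply(sch$length, random_seq, gc = 0.5)
  variant <- lapply(seq_len(L), function(j)
    mutate_seq(base[[j]], sample.int(sch$length[j], 1L)))
  ## profiles: founder (1,...,1) x10; SLV_j differs at locus j, x2 each
  profs <- rbind(matrix(1L, 10L, L),
                 do.call(rbind, lapply(seq_len(L), function(j) {
                   p <- rep(1L, L); p[j] <- 2L
                   rbind(p, p)
                 })))
  n <- nrow(profs)
  ids <- sprintf("iso%03d", seq_len(n))
  sequence_sets <- lapply(seq_len(L), function(j) {
    seqs <- ifelse(profs[, j] == 1L, base[[j]], variant[[j]])
    locus_alignment(stats::setNames(seqs, ids), sch$locus[j])
  })
  truth <- list(founder_st = 1L, n_st = L + 1L,
                st = stats::setNames(
                  match(apply(profs, 1L, paste, collapse = "-"),
                        unique(apply(profs, 1L, paste, collapse = "-"))),
                  ids),
                n_slv_of_founder = L)
  list(sequence_sets = sequence_sets, scheme = sch,
       metadata = data.frame(isolate = ids, lineage = "starCC",
                             stringsAsFactors = FALSE),
       truth = truth)
}

## strictly clonal two-lineage population via the Wright-Fisher simulator
fixture_two_groups <- function(seed) {
  sim <- simulate_population(sim_config(
    n_isolates = 40L, scheme = fixture_scheme(), generations = 120L,
    mu = 1e-4, r = 0, n_lineages = 2L, founder_divergence = 0.03,
    seed = seed))
  list(sequence_sets = sim$sequence_sets, scheme = sim$config$scheme,
       metadata = sim$metadata, truth = sim$truth)
}

#' Draw an independent-loci (panmictic) profile population
#'
#' Every isolate's allele at every locus is an independent draw from that
#' locus's allele pool, which is the null model of the linkage permutation
#' test; used both as a fixture and for Monte-Carlo calibration.
#'
#' @param n_isolates number of isolates.
#' @param n_alleles alleles per locus (uniform frequencies).
#' @param scheme an \code{mlst_scheme}.
#' @param seed RNG seed.
#' @param sequences if \code{TRUE} also fabricate allele sequences and
#'   return \code{sequence_sets}; if \code{FALSE} (cheap) only profiles.
#' @return list with \code{profiles} (integer matrix) and optionally
#'   \code{sequence_sets}.
#' @export
panmictic_profiles <- function(n_isolates = 50L, n_alleles = 5L,
                               scheme = fixture_scheme(), seed,
                               sequences = FALSE) {
  if (missing(seed)) stop("a seed is required")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  L <- nrow(scheme)
  profs <- matrix(sample.int(n_alleles, n_isolates * L, replace = TRUE),
                  n_isolates, L,
                  dimnames = list(sprintf("iso%03d", seq_len(n_isolates)),
                                  scheme$locus))
  out <- list(profiles = profs)
  if (sequences) {
    out$sequence_sets <- lapply(seq_len(L), function(j) {
      pool <- character(n_alleles)
      pool[1L] <- random_seq(scheme$length[j], 0.5)
      for (a in seq_len(n_alleles - 1L))
        pool[a + 1L] <- mutate_seq(pool[1L],
                                   sample.int(scheme$length[j], a))
      ## typing renumbers alleles by first appearance; that is a per-locus
      ## relabelling of these pool indices, so the ST partition and all
      ## label-invariant statistics are unaffected
      seqs <- pool[profs[, j]]
      locus_alignment(stats::setNames(seqs, rownames(profs)),
                      scheme$locus[j])
    })
  }
  out
}

fixture_panmictic <- function(seed) {
  sch <- fixture_scheme()
  pan <- panmictic_profiles(n_isolates = 50L, n_alleles = 5L, scheme = sch,
                            seed = seed, sequences = TRUE)
  ids <- rownames(pan$profiles)
  truth <- list(model = "independent_loci",
                st = stats::setNames(
                  match(apply(pan$profiles, 1L, paste, collapse = "-"),
                        unique(apply(pan$profiles, 1L, paste, collapse = "-"))),
                  ids))
  list(sequence_sets = pan$sequence_sets, scheme = sch,
       metadata = data.frame(isolate = ids, lineage = "panmictic",
                             stringsAsFactors = FALSE),
       truth = truth)
}
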