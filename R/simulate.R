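#' Configure a clonal population simulation
#'
#' Describes a forward-in-time Wright-Fisher simulation of a haploid clonal
#' bacterial population typed at several housekeeping loci.  The defaults
#' emulate the shape of a natural \emph{L. fermentum}-like collection: 203
#' isolates, the 11-locus scheme with its published fragment lengths
#' (589-748 bp), two long-diverged founder lineages that never exchange
#' alleles, and mutation tuned so that per-locus allele counts land in the
#' observed 7-19 range and nucleotide diversity in the observed
#' 0.004-0.014 band.
#'
#' @param n_isolates sampled population size (default 203).
#' @param scheme an \code{mlst_scheme} (default \code{\link{lf_scheme}()}).
#' @param generations Wright-Fisher generations after the founders
#'   (default 300, roughly 2N per lineage so diversity approaches the
#'   mutation-drift balance).
#' @param mu per-site per-generation mutation rate (default 1.2e-5; at
#'   lineage size ~100 this gives theta per site ~ 2N mu ~ 0.0024, which
#'   together with the founder divergence reproduces the observed
#'   within- and between-group diversity).
#' @param r per-locus per-generation recombination rate: probability that an
#'   offspring's allele at a locus is replaced by the corresponding allele
#'   of a random co-lineage donor (default 0, strictly clonal).
#' @param n_lineages number of founder lineages (default 2).
#' @param founder_divergence expected pairwise differences per site between
#'   lineage founders (default 0.007, the between-group scale of the
#'   observed data).
#' @param migration per-generation probability that an offspring picks its
#'   parent from another lineage (default 0: lineages stay disconnected,
#'   like the two observed groups).
#' @param gc_content founder base composition (default 0.5).
#' @param seed integer RNG seed; mandatory.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_isolates = 203L, scheme = lf_scheme(),
                       generations = 300L, mu = 1.2e-5, r = 0,
                       n_lineages = 2L, founder_divergence = 0.007,
                       migration = 0, gc_content = 0.5, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_isolates >= 2L, generations >= 0L,
            mu >= 0, mu <= 1, r >= 0, r <= 1,
            migration >= 0, migration <= 1,
            founder_divergence >= 0, founder_divergence <= 1,
            n_lineages >= 1L, gc_content > 0, gc_content < 1)
  structure(list(n_isolates = as.integer(n_isolates), scheme = scheme,
                 generations = as.integer(generations), mu = mu, r = r,
                 n_lineages = as.integer(n_lineages),
                 founder_divergence = founder_divergence,
                 migration = migration, gc_content = gc_content,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(len, gc) {
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, sites) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (s in sites) b[s] <- sample(setdiff(BASES, b[s]), 1L)
  paste(b, collapse = "")
}

#' Simulate a clonal bacterial population
#'
#' Forward Wright-Fisher simulation with whole-locus recombination.  Each
#' lineage starts from a founder haplotype (founders pairwise diverged by
#' \code{founder_divergence}); every generation each individual copies a
#' random parent (from its own lineage, or any lineage with probability
#' \code{migration}), then per locus: with probability \code{r} the allele
#' is replaced by the allele of a random co-lineage donor (recombination,
#' the natural MLST-scale event), and each site mutates with rate \code{mu}
#' to a uniformly random different base.  Alleles are tracked as integer
#' ids with a sequence registry, so only mutated sequences are materialised.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{mlst_simulation}: list with
#'   \describe{
#'     \item{sequence_sets}{list of \code{\link{locus_alignment}}s, one per
#'       scheme locus, isolate ids \code{iso001...}}
#'     \item{metadata}{data frame \code{isolate}, \code{lineage} (the
#'       source-category surrogate)}
#'     \item{truth}{ground truth: per-isolate lineage, true per-locus allele
#'       id matrix, true ST partition (integer vector), realized per-locus
#'       allele counts and pi, and the recombination event count}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' sim <- simulate_population(sim_config(n_isolates = 10, generations = 20,
#'                                       seed = 1))
#' sim$truth$n_st
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  on.exit(rng$restore())
  sch <- config$scheme
  L <- nrow(sch)
  n <- config$n_isolates
  ## lineage assignment: as equal as possible, in blocks
  lin <- rep(seq_len(config$n_lineages), length.out = n)
  lin <- sort(lin)
  ## per-locus allele registries; founders are alleles 1..n_lineages
  registry <- vector("list", L)
  allele <- vector("list", L)       # per locus: integer vector over isolates
  for (j in seq_len(L)) {
    base <- random_seq(sch$length[j], config$gc_content)
    founders <- character(config$n_lineages)
    founders[1L] <- base
    if (config$n_lineages > 1L) for (g in 2L:config$n_lineages) {
      k <- stats::rbinom(1L, sch$length[j], config$founder_divergence)
      founders[g] <- if (k > 0)
        mutate_seq(base, sample.int(sch$length[j], k)) else base
    }
    registry[[j]] <- unique(founders)
    allele[[j]] <- match(founders, registry[[j]])[lin]
  }
  n_recomb <- 0L
  for (gen in seq_len(config$generations)) {
    parent <- integer(n)
    for (g in seq_len(config$n_lineages)) {
      idx <- which(lin == g)
      pool <- idx
      migrate <- config$migration > 0 &
        stats::runif(length(idx)) < config$migration
      parent[idx] <- sample(pool, length(idx), replace = TRUE)
      if (any(migrate))
        parent[idx[migrate]] <- sample.int(n, sum(migrate), replace = TRUE)
    }
    for (j in seq_len(L)) {
      al <- allele[[j]][parent]
      ## whole-locus recombination: replace with a random co-lineage
      ## donor's (parental-generation) allele
      if (config$r > 0) {
        rec <- which(stats::runif(n) < config$r)
        for (i in rec) {
          donors <- which(lin == lin[i])
          donor <- donors[sample.int(length(donors), 1L)]
          al[i] <- allele[[j]][donor]
          n_recomb <- n_recomb + 1L
        }
      }
      ## mutation: per-site rate mu; only individuals with >= 1 hit
      ## materialise a new allele sequence
      nmut <- stats::rbinom(n, sch$length[j], config$mu)
      for (i in which(nmut > 0L)) {
        seq_new <- mutate_seq(registry[[j]][al[i]],
                              sample.int(sch$length[j], nmut[i]))
        hit <- match(seq_new, registry[[j]])
        if (is.na(hit)) {
          registry[[j]] <- c(registry[[j]], seq_new)
          hit <- length(registry[[j]])
        }
        al[i] <- hit
      }
      allele[[j]] <- al
    }
  }
  ids <- sprintf("iso%03d", seq_len(n))
  sequence_sets <- vector("list", L)
  true_alleles <- matrix(0L, n, L, dimnames = list(ids, sch$locus))
  for (j in seq_len(L)) {
    seqs <- registry[[j]][allele[[j]]]
    names(seqs) <- ids
    sequence_sets[[j]] <- locus_alignment(seqs, sch$locus[j])
    ## renumber observed alleles by first appearance (catalog convention)
    true_alleles[, j] <- match(allele[[j]], unique(allele[[j]]))
  }
  true_st <- match(apply(true_alleles, 1L, paste, collapse = "-"),
                   unique(apply(true_alleles, 1L, paste, collapse = "-")))
  truth <- list(
    lineage = stats::setNames(lin, ids),
    alleles = true_alleles,
    st = stats::setNames(as.integer(true_st), ids),
    n_st = length(unique(true_st)),
    alleles_per_locus = stats::setNames(
      vapply(seq_len(L), function(j) length(unique(allele[[j]])), 0L),
      sch$locus),
    pi_per_locus = stats::setNames(
      vapply(sequence_sets, function(ss)
        nucleotide_diversity(ss, unit = "isolate"), 0), sch$locus),
    n_recombination_events = n_recomb)
  metadata <- data.frame(isolate = ids,
                         lineage = paste0("lineage", lin),
                         stringsAsFactors = FALSE)
  structure(list(sequence_sets = sequence_sets, metadata = metadata,
                 truth = truth, config = config),
            class = "mlst_simulation")
}

#' @export
print.mlst_simulation <- function(x, ...) {
  cat("Simulated clonal population:", x$config$n_isolates, "isolates,",
      nrow(x$config$scheme), "loci,", x$config$n_lineages, "lineage(s)\n")
  cat("  true STs:", x$truth$n_st,
      " alleles/locus:", paste(range(x$truth$alleles_per_locus),
                               collapse = "-"),
      " recombination events:", x$truth$n_recombination_events, "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Per-locus FASTA files (\code{<locus>.fasta}), a metadata TSV and a
#' ground-truth JSON, all under \code{dir}.
#'
#' @param sim an \code{\link{mlst_simulation}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ss in sim$sequence_sets)
    write_locus_fasta(ss, file.path(dir, paste0(ss$locus, ".fasta")))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$alleles <- as.data.frame(truth$alleles)
  write_report(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
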