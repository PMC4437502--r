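#' Run the full MLST population-structure analysis
#'
#' One-command orchestration of the whole pipeline in the order of a
#' standard MLST population study: typing (alleles and STs), per-locus
#' diversity, multilocus linkage disequilibrium with a permutation test,
#' clonal complexes with founder prediction, a minimum spanning tree, a
#' neighbour-joining tree of the concatenated ST sequences (optionally
#' bootstrapped), and split decomposition of the ST distance matrix.
#' Re-running with the same inputs and seed reproduces the identical
#' report.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{scheme}{an \code{mlst_scheme}, or a path to a scheme YAML;
#'       optional when \code{simulate} is given (the simulation's scheme is
#'       used) and defaults to \code{\link{lf_scheme}()} otherwise.}
#'     \item{fasta_dir}{directory of per-locus FASTA files named
#'       \code{<locus>.fasta} (alternative to \code{simulate}).}
#'     \item{simulate}{a \code{\link{sim_config}} or list of arguments for
#'       one (alternative to \code{fasta_dir}).}
#'     \item{metadata}{optional data frame or TSV path with an
#'       \code{isolate} column.}
#'     \item{out_dir}{output directory; when \code{NULL} nothing is
#'       written.}
#'     \item{seed}{integer master seed for the stochastic stages
#'       (permutation test, bootstrap); mandatory.}
#'     \item{linkage}{list: \code{n_permutations} (default 1000),
#'       \code{unique_sts} (default FALSE).}
#'     \item{clustering}{list: \code{shared_loci} (default L - 2).}
#'     \item{phylo}{list: \code{model} (default "p"), \code{bootstrap}
#'       (replicates, default 0 = off), \code{one_per_st} (default TRUE).}
#'   }
#' @param quiet suppress progress messages (default \code{FALSE}).
#' @return An object of class \code{mlst_analysis}: list with
#'   \code{typing}, \code{diversity}, \code{scheme_summary},
#'   \code{linkage}, \code{clonal_complexes}, \code{mst}, \code{tree},
#'   \code{splits}, \code{report} (the serialisable report list) and
#'   \code{files} (paths written, if any).
#' @examples
#' fx <- emit_fixtures("star_cc")
#' res <- run_full_analysis(list(scheme = fx$scheme,
#'                               sequence_sets = fx$sequence_sets,
#'                               seed = 7), quiet = TRUE)
#' res$clonal_complexes$complexes[[1]]$founder
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message("[mlstpop ", format(Sys.time(),
                                           "%H:%M:%S"), "] ", ...)
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  files <- character(0)
  stage <- "setup"
  manifest <- function(done) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(c(paste("complete:", done), paste("failed_stage:", stage)),
                 file.path(out_dir, "MANIFEST"))
    }
  }
  res <- tryCatch({
    ## ---- inputs ----
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      simcfg <- if (inherits(config$simulate, "sim_config")) config$simulate
                else do.call(sim_config, config$simulate)
      say("simulating population (seed ", simcfg$seed, ")")
      sim <- simulate_population(simcfg)
      sequence_sets <- sim$sequence_sets
      scheme <- simcfg$scheme
      metadata <- sim$metadata
    } else {
      sim <- NULL
      scheme <- config$scheme
      if (is.character(scheme)) scheme <- read_scheme(scheme)
      if (is.null(scheme)) scheme <- lf_scheme()
      if (!is.null(config$sequence_sets)) {
        sequence_sets <- config$sequence_sets
      } else if (!is.null(config$fasta_dir)) {
        stage <- "read_fasta"
        say("reading per-locus FASTA from ", config$fasta_dir)
        sequence_sets <- lapply(scheme$locus, function(l)
          read_locus_fasta(file.path(config$fasta_dir,
                                     paste0(l, ".fasta")), locus = l))
      } else stop("config needs one of: simulate, fasta_dir, sequence_sets")
      metadata <- config$metadata
      if (is.character(metadata))
        metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    }

    ## ---- typing ----
    stage <- "typing"
    say("typing isolates")
    typing <- build_typing_database(sequence_sets, scheme,
                                    metadata = metadata)
    tsum <- summary(typing)

    ## ---- diversity ----
    stage <- "diversity"
    say("per-locus diversity statistics")
    ## simulated/random fragments legitimately contain stop-codon columns;
    ## those columns are skipped inside the dN/dS step
    div <- suppressWarnings(diversity_table(sequence_sets, scheme))
    ssum <- summarize_scheme(div, scheme)

    ## ---- linkage ----
    stage <- "linkage"
    lk_cfg <- config$linkage
    n_perm <- if (is.null(lk_cfg$n_permutations)) 1000L
              else as.integer(lk_cfg$n_permutations)
    uq <- isTRUE(lk_cfg$unique_sts)
    say("index of association (", n_perm, " permutations)")
    linkage <- ia_permutation_test(typing, n_permutations = n_perm,
                                   seed = seed, unique_sts = uq)

    ## ---- clustering ----
    stage <- "clustering"
    say("clonal complexes and minimum spanning tree")
    shared <- config$clustering$shared_loci
    ccs <- find_clonal_complexes(typing, shared_loci = shared)
    mst <- build_mst(typing)

    ## ---- phylogeny ----
    stage <- "phylogeny"
    ph <- config$phylo
    model <- if (is.null(ph$model)) "p" else ph$model
    one_per_st <- if (is.null(ph$one_per_st)) TRUE else isTRUE(ph$one_per_st)
    nboot <- if (is.null(ph$bootstrap)) 0L else as.integer(ph$bootstrap)
    concat <- concatenate_alignments(sequence_sets, scheme, typing = typing,
                                     one_per_st = one_per_st)
    dm <- compute_distance_matrix(concat, model = model)
    if (nboot > 0L) {
      say("neighbour joining with ", nboot, " bootstrap replicates")
      bs <- bootstrap_support(concat, n_replicates = nboot,
                              seed = seed + 1L, model = model)
      tree <- bs$tree
    } else {
      say("neighbour joining")
      tree <- neighbor_joining(dm)
      bs <- NULL
    }

    stage <- "splits"
    say("split decomposition")
    splits <- split_decomposition(dm)

    ## ---- report ----
    stage <- "report"
    report <- list(
      n_isolates = tsum$n_isolates,
      n_loci = n_loci(scheme),
      typing = list(n_st = tsum$n_st,
                    n_singleton_st = tsum$n_singleton_st,
                    largest_st = tsum$largest_st,
                    largest_st_count = tsum$largest_st_count,
                    st_counts = as.list(typing$st_counts),
                    alleles_per_locus = as.list(tsum$alleles_per_locus)),
      diversity = div,
      scheme_summary = ssum,
      linkage = unclass(linkage),
      clonal_complexes = list(
        n_cc = length(ccs$complexes),
        n_singleton_st = length(ccs$singletons),
        shared_loci = ccs$shared_loci,
        complexes = lapply(ccs$complexes, function(cc)
          list(id = cc$id, members = cc$members, founder = cc$founder,
               n_isolates = cc$n_isolates)),
        singletons = ccs$singletons),
      mst = list(total_weight = mst$total_weight, edges = mst$edges),
      splits = list(n_splits = length(splits$splits), fit = splits$fit),
      run = list(seed = seed, n_permutations = n_perm,
                 bootstrap_replicates = nboot, distance_model = model,
                 package_version = as.character(
                   utils::packageVersion("mlstpop"))))

    ## ---- outputs ----
    if (!is.null(out_dir)) {
      stage <- "write_outputs"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      say("writing outputs to ", out_dir)
      f <- function(name) file.path(out_dir, name)
      write_profile_table(typing$isolates[, c("isolate", scheme$locus)],
                          f("profiles.tsv"), st = typing$isolates$ST)
      write_newick(tree, f("tree.nwk"))
      write_nexus_splits(splits, f("splits.nex"))
      write_graphml(mst, f("mst.graphml"))
      write_report(report, f("report.json"))
      files <- f(c("profiles.tsv", "tree.nwk", "splits.nex",
                   "mst.graphml", "report.json"))
      writeLines("complete: true", f("MANIFEST"))
    }
    structure(list(typing = typing, diversity = div, scheme_summary = ssum,
                   linkage = linkage, clonal_complexes = ccs, mst = mst,
                   tree = tree, bootstrap = bs, splits = splits,
                   distance_matrix = dm, simulation = sim,
                   report = report, files = files),
              class = "mlst_analysis")
  }, error = function(e) {
    manifest(FALSE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.mlst_analysis <- function(x, ...) {
  cat("== MLST population-structure analysis ==\n")
  print(x$typing)
  cat(sprintf("polymorphic sites: %d / %d bp (%.2f%%)\n",
              x$scheme_summary$total_polymorphic_sites,
              x$scheme_summary$total_length,
              x$scheme_summary$polymorphism_rate_percent))
  print(x$linkage)
  cat("clonal complexes:", length(x$clonal_complexes$complexes),
      "CCs,", length(x$clonal_complexes$singletons), "singleton STs\n")
  cat("MST total weight:", x$mst$total_weight, "\n")
  print(x$splits)
  invisible(x)
}
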