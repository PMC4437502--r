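small_cfg <- function(seed, ...) {
  args <- list(n_isolates = 30L, scheme = mlstpop:::fixture_scheme(),
               generations = 80L, mu = 1e-4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("a mutation-free single lineage is perfectly uniform", {
  sim <- simulate_population(small_cfg(1, mu = 0, r = 0, n_lineages = 1L))
  ty <- build_typing_database(sim$sequence_sets, sim$config$scheme)
  expect_equal(nrow(ty$profiles), 1L)
  expect_equal(sim$truth$n_st, 1L)
  expect_true(all(sim$truth$alleles_per_locus == 1L))
  expect_true(all(sim$truth$pi_per_locus == 0))
})

test_that("the simulation is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_population(small_cfg(42)), d1)
  write_simulation(simulate_population(small_cfg(42)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and it must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_population(small_cfg(7))); after <- runif(3)
  expect_identical(before, after)
})

test_that("ground-truth ST partition equals end-to-end typing output", {
  for (s in c(3, 4)) {
    sim <- simulate_population(small_cfg(s, r = 0.02))
    ty <- build_typing_database(sim$sequence_sets, sim$config$scheme)
    expect_equal(unname(ty$isolates$ST), unname(sim$truth$st))
    expect_equal(unname(vapply(sim$config$scheme$locus, function(l)
      length(catalog_alleles(ty$catalog, l)), 0L)),
      unname(sim$truth$alleles_per_locus))
  }
})

test_that("the default configuration reproduces the target data shape", {
  # full-size run (203 isolates, 11 loci): allele counts and diversity must
  # land in the plausibility band around the published ranges
  sim <- simulate_population(sim_config(seed = 5))
  expect_true(all(sim$truth$alleles_per_locus >= 5 &
                    sim$truth$alleles_per_locus <= 25))
  expect_true(all(sim$truth$pi_per_locus >= 0.002 &
                    sim$truth$pi_per_locus <= 0.02))
  expect_equal(length(unique(sim$truth$lineage)), 2L)
})

test_that("recombination events are logged and respect lineage boundaries", {
  sim <- simulate_population(small_cfg(8, r = 0.05, n_lineages = 2L,
                                       founder_divergence = 0.05))
  expect_gt(sim$truth$n_recombination_events, 0L)
  # lineages never exchange alleles: at every locus the allele sets of the
  # two lineages must stay disjoint (founders differ and migration = 0)
  ty <- build_typing_database(sim$sequence_sets, sim$config$scheme)
  prof <- isolate_profiles(ty)
  lin <- sim$truth$lineage[rownames(prof)]
  for (j in seq_len(ncol(prof)))
    expect_length(intersect(prof[lin == 1, j], prof[lin == 2, j]), 0L)
})

test_that("fixture suites carry their planted truth", {
  star <- emit_fixtures("star_cc")
  ty <- build_typing_database(star$sequence_sets, star$scheme)
  expect_equal(nrow(ty$profiles), star$truth$n_st)
  expect_equal(unname(ty$isolates$ST), unname(star$truth$st))

  two <- emit_fixtures("two_groups")
  expect_equal(length(unique(two$truth$lineage)), 2L)

  pan <- emit_fixtures("panmictic")
  ty2 <- build_typing_database(pan$sequence_sets, pan$scheme)
  expect_equal(unname(ty2$isolates$ST), unname(pan$truth$st))

  d <- withr::local_tempdir()
  fx <- emit_fixtures("star_cc", dir = d)
  expect_true(all(file.exists(file.path(d, c("loc1.fasta", "metadata.tsv",
                                             "truth.json", "scheme.yaml")))))
  expect_error(emit_fixtures("unknown_suite"), "arg")
})

test_that("two divergent lineages separate in the NJ tree and split graph", {
  fx <- emit_fixtures("two_groups")
  ty <- build_typing_database(fx$sequence_sets, fx$scheme)
  concat <- concatenate_alignments(fx$sequence_sets, fx$scheme,
                                   typing = ty, one_per_st = TRUE)
  dm <- compute_distance_matrix(concat)
  # lineage of each ST (lineages are clonal, so this is well defined)
  st_lineage <- tapply(fx$truth$lineage[ty$isolates$isolate],
                       ty$isolates$ST, unique)
  expect_true(all(lengths(st_lineage) == 1L))
  grp2 <- paste0("ST", names(st_lineage)[st_lineage == 2])

  tree <- neighbor_joining(dm)
  keys <- mlstpop:::tree_bipartitions(tree)
  lineage_key <- paste(sort(intersect(grp2, paste0("ST", names(st_lineage)))),
                       collapse = "|")
  side1 <- sort(setdiff(tree$tip.label, grp2))
  expect_true(lineage_key %in% keys ||
                paste(side1, collapse = "|") %in% keys)

  sp <- split_decomposition(dm)
  sp_keys <- vapply(sp$splits, function(x) split_key(x$side), "")
  wts <- vapply(sp$splits, function(x) x$weight, 0)
  hit <- match(TRUE, sp_keys %in% c(lineage_key, paste(side1, collapse = "|")))
  expect_false(is.na(hit))
  # the lineage split is the dominant signal in the network
  expect_equal(which.max(wts), hit)
})
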