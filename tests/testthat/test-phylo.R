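test_that("concatenation follows scheme order and collapses per ST", {
  sch <- mlst_scheme(c("locA", "locB"), c(3L, 4L))
  ss <- list(locus_alignment(c(i1 = "AAA", i2 = "AAA", i3 = "CCC"), "locA"),
             locus_alignment(c(i1 = "GGGG", i2 = "GGGG", i3 = "GGGG"), "locB"))
  cc <- concatenate_alignments(ss, sch)
  expect_equal(seq_length(cc), 7L)
  expect_equal(unname(cc$sequences["i1"]), "AAAGGGG")

  ty <- build_typing_database(ss, sch)
  cc2 <- concatenate_alignments(ss, sch, typing = ty, one_per_st = TRUE)
  # i1 and i2 share an ST, so one taxon is retained per ST
  expect_equal(names(cc2$sequences), c("ST1", "ST2"))

  ss_bad <- list(ss[[1]], locus_alignment(c(i1 = "GGGG", i2 = "GGGG"), "locB"))
  expect_error(concatenate_alignments(ss_bad, sch), "i3")
})

test_that("the full scheme concatenates to 7592 nucleotides", {
  sch <- lf_scheme()
  ids <- c("x", "y")
  ss <- lapply(seq_len(nrow(sch)), function(j) {
    locus_alignment(setNames(rep(paste(rep("A", sch$length[j]),
                                       collapse = ""), 2), ids),
                    sch$locus[j])
  })
  expect_equal(seq_length(concatenate_alignments(ss, sch)), 7592L)
})

test_that("distance models give p, JC69 closed forms and saturate correctly", {
  a <- aln(c("AAAA", "AAAT"))
  expect_equal(compute_distance_matrix(a)["iso1", "iso2"], 0.25)
  expect_equal(compute_distance_matrix(aln(c("ACGT", "ACGT")))[1, 2], 0)
  expect_equal(compute_distance_matrix(a, model = "JC69")["iso1", "iso2"],
               -3 / 4 * log(1 - 4 / 3 * 0.25), tolerance = 1e-9)
  # p = 3/4 saturates JC69
  expect_error(compute_distance_matrix(aln(c("AAAA", "CCCG")), model = "JC69"),
               "undefined")
})

test_that("neighbour joining inverts additive tree metrics exactly", {
  # the closed forms for 2 and 3 taxa
  d2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  # 4-taxon additive matrix from a known tree: internal 1, external 2,3,4,5
  # ((A:2,B:3):1,C:4,D:5)
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 5
  d4["A", "C"] <- d4["C", "A"] <- 7
  d4["A", "D"] <- d4["D", "A"] <- 8
  d4["B", "C"] <- d4["C", "B"] <- 8
  d4["B", "D"] <- d4["D", "B"] <- 9
  d4["C", "D"] <- d4["D", "C"] <- 9
  t4 <- neighbor_joining(d4)
  expect_equal(stats::cophenetic(t4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9)

  # random additive metrics, n up to 12: topology and lengths recovered
  for (s in 1:15) {
    n <- sample(4:12, 1)
    rt <- random_tree_metric(n, seed = 200 + s)
    tr <- neighbor_joining(rt$d)
    expect_equal(stats::cophenetic(tr)[rownames(rt$d), colnames(rt$d)],
                 rt$d, tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt$tree), tr)), 0)
  }
})

test_that("NJ validates its input and never returns negative branches", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "symmetric")
  expect_error(neighbor_joining(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
  set.seed(141)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    m <- matrix(runif(n * n), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- neighbor_joining(d)
    expect_true(all(tr$edge.length >= 0))
    # clamping preserves total tree length
    expect_equal(sum(tr$edge.length),
                 sum(ape::nj(stats::as.dist(d))$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("bootstrap supports are deterministic and detect clear clades", {
  # two tight clades, between-clade divergence ~10x the within-clade level
  set.seed(151)
  mut <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    for (at in sample(length(b), k))
      b[at] <- sample(setdiff(c("A", "C", "G", "T"), b[at]), 1)
    paste(b, collapse = "")
  }
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  far <- mut(base, 60)
  seqs <- c(a1 = mut(base, 3), a2 = mut(base, 3), a3 = mut(base, 3),
            b1 = mut(far, 3), b2 = mut(far, 3), b3 = mut(far, 3))
  a <- locus_alignment(seqs, "concat")
  bs <- bootstrap_support(a, n_replicates = 100, seed = 9)
  bs2 <- bootstrap_support(a, n_replicates = 100, seed = 9)
  expect_identical(bs$support, bs2$support)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  # the clade split {a1,a2,a3} | {b1,b2,b3} must be strongly supported
  key_b <- paste(c("b1", "b2", "b3"), collapse = "|")
  expect_true(key_b %in% names(bs$support))
  expect_gte(bs$support[[key_b]], 95)
})

test_that("an alignment of identical sequences has no supported structure", {
  seqs <- setNames(rep(strrep("ACGT", 25), 4), paste0("t", 1:4))
  a <- locus_alignment(seqs, "concat")
  bs <- bootstrap_support(a, n_replicates = 10, seed = 3)
  expect_length(bs$support, 0L)
})

test_that("bipartition extraction agrees with an independent splits library", {
  for (s in 1:5) {
    rt <- random_tree_metric(sample(5:10, 1), seed = 700 + s)
    tr <- neighbor_joining(rt$d)
    ours <- sort(mlstpop:::tree_bipartitions(tr))
    sp <- phangorn::as.splits(tr)
    labs <- attr(sp, "labels")
    n <- length(labs)
    first <- sort(labs)[1]
    keys <- unique(vapply(sp, function(idx) {
      side <- sort(labs[idx])
      if (first %in% side) side <- sort(setdiff(labs, side))
      if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
      paste(side, collapse = "|")
    }, ""))
    expect_setequal(ours, sort(keys[!is.na(keys)]))
  }
})
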