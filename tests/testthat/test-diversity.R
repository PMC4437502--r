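test_that("polymorphic site counts match column-wise inspection", {
  expect_equal(count_polymorphic_sites(aln(c("AAAA", "AAAA"))), 0L)
  expect_equal(count_polymorphic_sites(aln(c("AAAA", "AAAT", "AATT"))), 2L)
  expect_error(count_polymorphic_sites(aln(c("AAAA"))), "2 sequences")
})

test_that("polymorphic sites equal the brute-force column scan on random data", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:20, 1)
    l <- sample(10:200, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
                   prob = c(.7, .1, .1, .1)), collapse = ""), "")
    expect_equal(count_polymorphic_sites(aln(seqs)), oracle_polymorphic(seqs))
  }
})

test_that("GC content is the per-sequence average percentage", {
  expect_equal(gc_content(aln(c("GGCC"))), 100)
  expect_equal(gc_content(aln(c("ATGC"))), 50)
  expect_equal(gc_content(aln(c("ATGC", "GGGG"))), 75)
})

test_that("nucleotide diversity matches hand enumeration and the oracle", {
  expect_equal(nucleotide_diversity(aln(c("ACGT", "ACGT", "ACGT"))), 0)
  # 3 distinct alleles, pairwise diffs 1 + 2 + 1 = 4 over 3 pairs x 4 sites
  expect_equal(nucleotide_diversity(aln(c("AAAA", "AAAT", "AATT"))), 4 / 12,
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    l <- sample(8:60, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), l, replace = TRUE), collapse = ""), "")
    a <- aln(seqs)
    expect_equal(nucleotide_diversity(a, unit = "isolate"), oracle_pi(seqs),
                 tolerance = 1e-12)
    # pi over distinct alleles equals the oracle on the distinct set
    expect_equal(nucleotide_diversity(a, unit = "allele"),
                 if (length(unique(seqs)) >= 2) oracle_pi(unique(seqs)) else 0,
                 tolerance = 1e-12)
    # invariants: reorder-invariance and the polymorphic-site bound
    expect_equal(nucleotide_diversity(aln(rev(seqs)), unit = "isolate"),
                 nucleotide_diversity(a, unit = "isolate"), tolerance = 1e-12)
    if (length(unique(seqs)) >= 2)
      expect_lte(nucleotide_diversity(a, unit = "isolate"),
                 oracle_polymorphic(seqs) / l + 1e-12)
  }
})

test_that("duplicating every sequence leaves isolate-pi within O(1/n)", {
  set.seed(41)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "G"), 40, replace = TRUE), collapse = ""), "")
  p1 <- nucleotide_diversity(aln(seqs), unit = "isolate")
  p2 <- nucleotide_diversity(aln(rep(seqs, each = 3)), unit = "isolate")
  # exact relation: sum of diffs scales by k^2, pairs by (kn choose 2)
  n <- 8; k <- 3
  expect_equal(p2, p1 * k^2 * choose(n, 2) / choose(k * n, 2),
               tolerance = 1e-12)
  expect_lt(abs(p2 - p1), p1 / n + 1e-12)
})

test_that("Nei-Gojobori classifies toy codon pairs correctly", {
  # identical alleles only: no substitutions at all
  r0 <- nei_gojobori_dnds(aln(c("AAAGGG", "AAAGGG")))
  expect_equal(r0$dn, 0)
  expect_equal(r0$dnds, 0)

  # AAA->AAG is Lys->Lys: one synonymous difference, dN = 0, ratio 0
  r1 <- nei_gojobori_dnds(aln(c("AAAGGG", "AAGGGG")))
  expect_equal(r1$dn, 0)
  expect_equal(r1$dnds, 0)

  # AAA->AGA is Lys->Arg: one nonsynonymous difference, dS = 0 -> UNDEFINED
  r2 <- nei_gojobori_dnds(aln(c("ATGAAA", "ATGAGA")))
  expect_equal(r2$ds, 0)
  expect_gt(r2$dn, 0)
  expect_identical(r2$dnds, "UNDEFINED")
  # site counting: S = mean(1/3, 2/3) = 0.5, N = 5.5, pN = 1/5.5, JC-corrected
  expect_equal(r2$dn, -3 / 4 * log(1 - 4 / 3 / 5.5), tolerance = 1e-12)
})

test_that("synonymous-only evolution gives dN = 0; nonsynonymous-only dS = 0", {
  # sparse third-position synonymous changes (Leu/Gly families), kept few
  # enough that pS stays below the Jukes-Cantor saturation bound
  syn <- c("CTAGGGAAAACT", "CTTGGGAAAACT", "CTAGGAAAAACT")
  rs <- nei_gojobori_dnds(aln(syn))
  expect_equal(rs$dn, 0)
  expect_equal(rs$dnds, 0)
  expect_gt(rs$ds, 0)

  # first-position changes among AAA (Lys), CAA (Gln), GAA (Glu): all nonsyn
  nonsyn <- c("AAAAAA", "CAAAAA", "GAACAA")
  rn <- nei_gojobori_dnds(aln(nonsyn))
  expect_equal(rn$ds, 0)
  expect_identical(rn$dnds, "UNDEFINED")
})

test_that("internal stop codons are skipped with a warning or error on demand", {
  s <- c("TAAAAA", "TAAAAG")  # first codon is a stop in both
  expect_warning(r <- nei_gojobori_dnds(aln(s)), "stop")
  expect_equal(r$dnds, 0)     # remaining codon AAA->AAG is synonymous
  expect_error(nei_gojobori_dnds(aln(s), on_stop = "error"), "stop")
})

test_that("frame handling: offsets shift, trailing bases trim, strict errors", {
  # with offset 1 the frame is AAG|GGG vs AAG|GGC: Gly->Gly synonymous
  s <- c("AAAGGGG", "AAAGGGC")
  expect_error(nei_gojobori_dnds(aln(s), incomplete = "error"), "divisible")
  r <- nei_gojobori_dnds(aln(s), frame_offset = 1L)
  expect_equal(r$dn, 0)
  expect_equal(r$dnds, 0)
})

test_that("scheme summary totals follow from the per-locus table", {
  sch <- lf_scheme()
  stats <- data.frame(
    locus = sch$locus,
    n_polymorphic_sites = c(11L, 12L, 13L, 6L, 12L, 14L, 22L, 10L, 11L, 7L, 13L),
    pi = c(0.00634, 0.01421, 0.0061, 0.00416, 0.00393, 0.00768, 0.00769,
           0.0056, 0.00408, 0.00514, 0.00618),
    fragment_length = sch$length)
  sm <- summarize_scheme(stats, sch)
  expect_equal(sm$total_polymorphic_sites, 131L)
  expect_equal(sm$total_length, 7592L)
  expect_equal(sm$polymorphism_rate_percent, 1.72)
  expect_equal(sm$min_pi_locus, "murC")
  expect_equal(sm$max_pi_locus, "dnaA")
  expect_error(summarize_scheme(stats[-1, ], sch), "missing")
})
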