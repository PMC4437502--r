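test_that("profile distance is the Hamming distance on allele vectors", {
  expect_equal(profile_distance(c(1, 2, 3), c(1, 2, 3)), 0L)
  expect_equal(profile_distance(c(1, 2, 3), c(1, 9, 3)), 1L)
  expect_equal(profile_distance(c(1, 2, 3), c(1, 5, 6)), 2L)
  expect_error(profile_distance(1:3, 1:4), "length")
  set.seed(101)
  for (rep in 1:30) {
    a <- sample.int(5, 8, replace = TRUE)
    b <- sample.int(5, 8, replace = TRUE)
    expect_equal(profile_distance(a, b), oracle_hamming(a, b))
  }
})

test_that("clonal complexes follow single linkage at the sharing threshold", {
  L <- 11L
  base <- rep(1L, L)
  mk <- function(...) { p <- base; d <- c(...); p[d] <- p[d] + 1L; p }
  # two STs differing at 2 of 11 loci share 9 loci -> one CC
  m <- rbind(`1` = base, `2` = mk(1, 2))
  cc <- find_clonal_complexes(m, shared_loci = 9)
  expect_length(cc$complexes, 1L)
  expect_equal(cc$complexes[[1]]$members, c(1L, 2L))
  # differing at 3 loci -> two singletons
  m2 <- rbind(`1` = base, `2` = mk(1, 2, 3))
  cc2 <- find_clonal_complexes(m2, shared_loci = 9)
  expect_length(cc2$complexes, 0L)
  expect_equal(cc2$singletons, c(1L, 2L))
  # chain A-B (d=1), B-C (d=2), A-C (d=3): one CC by single linkage
  A <- base; B <- mk(1); C <- B; C[2:3] <- 5L
  m3 <- rbind(`1` = A, `2` = B, `3` = C)
  expect_equal(profile_distance(A, B), 1L)
  expect_equal(profile_distance(B, C), 2L)
  expect_equal(profile_distance(A, C), 3L)
  cc3 <- find_clonal_complexes(m3, shared_loci = 9)
  expect_length(cc3$complexes, 1L)
  expect_equal(cc3$complexes[[1]]$members, 1:3)
  expect_error(find_clonal_complexes(m3, shared_loci = 12), "between")
})

test_that("founder prediction maximizes SLVs with documented tie-breaks", {
  fx <- emit_fixtures("star_cc")
  ty <- build_typing_database(fx$sequence_sets, fx$scheme)
  cc <- find_clonal_complexes(ty)
  expect_length(cc$complexes, 1L)
  expect_equal(cc$complexes[[1]]$founder, fx$truth$founder_st)

  # 2-member CC, tied SLV/DLV: the ST with more isolates wins
  cc2 <- structure(list(members = c(3L, 7L),
                        member_counts = c(`3` = 3L, `7` = 10L),
                        slv_counts = c(`3` = 1L, `7` = 1L),
                        dlv_counts = c(`3` = 0L, `7` = 0L)),
                   class = "clonal_complex")
  expect_equal(predict_founder(cc2), 7L)
  # fully tied: lower ST number
  cc3 <- cc2
  cc3$member_counts <- c(`3` = 2L, `7` = 2L)
  expect_equal(predict_founder(cc3), 3L)
})

test_that("variant classification partitions by distance 1, 2, 3", {
  m <- rbind(`1` = rep(1L, 5))
  v <- classify_variants(1, m)
  expect_equal(lengths(v), c(slv = 0L, dlv = 0L, tlv = 0L))

  fx <- emit_fixtures("star_cc")
  ty <- build_typing_database(fx$sequence_sets, fx$scheme)
  v1 <- classify_variants(fx$truth$founder_st, ty)
  expect_length(v1$slv, fx$truth$n_slv_of_founder)
  expect_length(v1$dlv, 0L)
  # each satellite sees the founder as its only SLV, the rest as DLVs
  v2 <- classify_variants(v1$slv[1], ty)
  expect_equal(v2$slv, fx$truth$founder_st)
  expect_length(v2$dlv, fx$truth$n_slv_of_founder - 1L)
  expect_error(classify_variants(99, ty), "unknown")
})

test_that("CC membership is invariant to ST relabelling and input order", {
  set.seed(111)
  m <- matrix(sample.int(3, 15 * 7, replace = TRUE), 15, 7)
  m <- unique(m)
  rownames(m) <- seq_len(nrow(m))
  cc <- find_clonal_complexes(m)
  memb <- lapply(cc$complexes, function(x) sort(x$members))
  perm <- sample(nrow(m))
  m2 <- m[perm, ]
  rownames(m2) <- seq_len(nrow(m2))   # relabel STs after reordering
  cc2 <- find_clonal_complexes(m2)
  # map new labels back to old ones
  memb2 <- lapply(cc2$complexes, function(x) sort(perm[x$members]))
  key <- function(l) sort(vapply(l, paste, "", collapse = ","))
  expect_equal(key(memb2), key(memb))
  expect_equal(sort(perm[cc2$singletons]), cc$singletons)
})

test_that("every SLV pair shares a complex whenever the threshold allows", {
  set.seed(121)
  m <- unique(matrix(sample.int(2, 12 * 6, replace = TRUE), 12, 6))
  rownames(m) <- seq_len(nrow(m))
  cc <- find_clonal_complexes(m, shared_loci = ncol(m) - 1L)
  comp_of <- integer(nrow(m))
  for (x in cc$complexes) comp_of[x$members] <- x$id
  d <- profile_dist_matrix(m)
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m))
    if (d[i, j] == 1L)
      expect_true(comp_of[i] == comp_of[j] && comp_of[i] > 0L)
})

test_that("Prim MST weight equals the Kruskal brute-force minimum", {
  # 3 STs with pairwise distances 1, 1, 2: two weight-1 edges
  m <- rbind(`1` = c(1L, 1L, 1L), `2` = c(2L, 1L, 1L), `3` = c(1L, 2L, 1L))
  mst <- build_mst(m)
  expect_equal(nrow(mst$edges), 2L)
  expect_equal(mst$total_weight, 2L)
  expect_equal(sort(mst$edges$weight), c(1L, 1L))

  # single ST: no edges
  expect_equal(nrow(build_mst(m[1, , drop = FALSE])$edges), 0L)

  set.seed(131)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    L <- sample(3:11, 1)
    mm <- matrix(sample.int(4, n * L, replace = TRUE), n, L)
    mm <- unique(mm)
    rownames(mm) <- seq_len(nrow(mm))
    if (nrow(mm) < 2) next
    mst <- build_mst(mm)
    expect_equal(nrow(mst$edges), nrow(mm) - 1L)
    expect_equal(mst$total_weight,
                 oracle_mst_weight(profile_dist_matrix(mm)))
  }
})

test_that("MST construction is deterministic under input shuffling", {
  fx <- emit_fixtures("star_cc")
  ty <- build_typing_database(fx$sequence_sets, fx$scheme)
  m <- ty$profiles
  mst1 <- build_mst(ty)
  # shuffling ST rows but keeping labels must give identical edges
  perm <- sample(nrow(m))
  m2 <- m[perm, ]
  mst2 <- build_mst(m2)
  e1 <- mst1$edges[order(mst1$edges$from, mst1$edges$to), ]
  e2 <- mst2$edges[order(mst2$edges$from, mst2$edges$to), ]
  expect_equal(e1, e2, ignore_attr = TRUE)
})

test_that("GraphML export lists every node and edge", {
  fx <- emit_fixtures("star_cc")
  ty <- build_typing_database(fx$sequence_sets, fx$scheme)
  mst <- build_mst(ty)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(mst, f)
  txt <- readLines(f)
  expect_length(grep("<node id=", txt), nrow(mst$nodes))
  expect_length(grep("<edge source=", txt), nrow(mst$edges))
})
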