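test_that("global alignment identities match hand-computed examples", {
  self <- pairwise_align("ACDE", "ACDE", "global")
  expect_equal(self$identity, 1.0)
  one_off <- pairwise_align("ACDE", "ACDF", "global")
  expect_equal(one_off$identity, 0.75)
  expect_equal(nchar(one_off$alignment[["a"]]), 4)
})

test_that("the Gotoh program reproduces the exhaustive enumeration score", {
  set.seed(101)
  aa <- rownames(blosum62_matrix())[1:20]
  S <- blosum62_matrix()
  for (k in 1:12) {
    a <- paste(sample(aa, sample(3:8, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:8, 1), TRUE), collapse = "")
    mine <- pairwise_align(a, b, "global")
    expect_equal(mine$score, brute_force_global_score(a, b, S),
                 info = paste(a, b))
  }
})

test_that("global and local scores agree with an independent implementation", {
  set.seed(55)
  aa <- rownames(blosum62_matrix())[1:20]
  for (k in 1:6) {
    a <- paste(sample(aa, 40, TRUE), collapse = "")
    b <- paste(sample(aa, 35, TRUE), collapse = "")
    for (mode in c("global", "local")) {
      mine <- pairwise_align(a, b, mode)
      oracle <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = blosum62_matrix(),
        gapOpening = 11, gapExtension = 1, type = mode)
      expect_equal(mine$score, Biostrings::score(oracle))
    }
  }
})

test_that("local identity of related family sequences is computed over the local span", {
  a <- simulate_lineage_panel("2.2.3.1", n = 1, seed = 2)$sequences[[1]]
  b <- simulate_lineage_panel("2.2.2.2", n = 1, seed = 3)$sequences[[1]]
  loc <- pairwise_align(a, b, "local")
  # homologs sharing exact blocks may align perfectly over a short span
  expect_true(loc$identity > 0 && loc$identity <= 1)
  expect_lt(pairwise_align(a, b, "global")$identity, 1)
  # deterministic
  expect_identical(loc, pairwise_align(a, b, "local"))
})

test_that("p and poisson distances follow their closed forms", {
  rows <- c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL")
  expect_true(all(msa_distance(rows) == 0))
  rows2 <- c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIYV")
  expect_equal(msa_distance(rows2)["s1", "s2"], 0.2)
  expect_equal(msa_distance(rows2, "poisson")["s1", "s2"], -log(0.8),
               tolerance = 1e-12)
  # gap columns excluded pairwise
  rows3 <- c(s1 = "AC-EFGHIKL", s2 = "ACDEFGHIYV")
  expect_equal(msa_distance(rows3)["s1", "s2"], 2 / 9)
  # saturated pair errors under poisson, naming the pair
  rows4 <- c(s1 = "AAAA", s2 = "CCCC")
  expect_error(msa_distance(rows4, "poisson"), "s1")
})

test_that("3-taxon NJ applies the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)   # (3+4-5)/2
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2[1, 2] <- 9
  expect_error(nj_tree(D2), "symmetric")
})

test_that("NJ recovers a 4-taxon tree with branch lengths 1..5 exactly", {
  # tree ((A:1,B:2):5,(C:3,D:4)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 9
  D["A", "D"] <- D["D", "A"] <- 10
  D["B", "C"] <- D["C", "B"] <- 10
  D["B", "D"] <- D["D", "B"] <- 11
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]] - D)),
               0, tolerance = 1e-12)
  bip <- pncctools:::tree_bipartitions(tr)
  expect_true("C|D" %in% bip$key || "A|B" %in% bip$key)
})

test_that("NJ exactly inverts tree-to-distance conversion on random trees", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n)
    D <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(D)
    back <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_equal(max(abs(back - D)), 0, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(9)
  pan <- simulate_lineage_panel("2.2.3.1", n = 8, seed = 12)
  D <- msa_distance(generate_truth_alignment(pan)$alignment)
  mine <- nj_tree(D)
  oracle <- ape::nj(stats::as.dist(D))
  expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(oracle))), 0)
})

test_that("negative branch estimates are clamped with a warning", {
  D <- matrix(c(0, 1, 5, 4,
                1, 0, 6, 5,
                5, 6, 0, 1,
                4, 5, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.01  # squeeze a cherry to force negativity
  D["a", "d"] <- D["d", "a"] <- 9
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports saturate on clean splits and respect determinism", {
  # two clearly separated clades: identical rows within, divergent between
  cladeA <- simulate_lineage_panel("2.2.3.1", n = 3, seed = 101,
                                   substitution_rate = 0.02)
  cladeB <- simulate_lineage_panel("2.2.3.1", n = 3, seed = 909,
                                   substitution_rate = 0.02)
  sa <- generate_truth_alignment(cladeA)$alignment
  sb <- generate_truth_alignment(cladeB)$alignment
  w <- min(nchar(sa[1]), nchar(sb[1]))
  aln <- c(substr(sa, 1, w), substr(sb, 1, w))
  names(aln) <- c(paste0("A", 1:3), paste0("B", 1:3))
  bs <- bootstrap_support(aln, n_replicates = 30, seed = 4)
  split_key <- paste(sort(c("B1", "B2", "B3")), collapse = "|")
  sep <- bs$supports$support[bs$supports$bipartition == split_key]
  expect_equal(sep, 100)
  # n = 1 gives only 0 or 100
  b1 <- bootstrap_support(aln, n_replicates = 1, seed = 4)
  expect_true(all(b1$supports$support %in% c(0, 100)))
  # same seed, same supports; taxon order irrelevant
  bs2 <- bootstrap_support(aln[c(4, 2, 6, 1, 3, 5)], n_replicates = 30,
                           seed = 4)
  expect_identical(bs$supports, bs2$supports)
})

test_that("trees serialize to Newick with supports as node labels", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 4, seed = 6)
  aln <- generate_truth_alignment(pan)$alignment
  bs <- bootstrap_support(aln, n_replicates = 5, seed = 2)
  path <- tempfile(fileext = ".nwk")
  write_newick(bs$tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, names(aln))
})
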