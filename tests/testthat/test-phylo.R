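test_that("k2p distance matches the closed form and detects saturation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # one A<->G transition over 4 sites: P = 0.25, Q = 0
  expect_equal(k2p_distance("ACGT", "GCGT"), -0.5 * log(0.5),
               tolerance = 1e-12)
  expect_error(k2p_distance("AAAA", "CCCC", c("x", "y")), "saturated.*x.*y")
  expect_error(k2p_distance("-GN", "C-N", c("x", "y")), "comparable")
  expect_error(k2p_distance("ACG", "ACGT"), "length")
  # constructed P, Q: 2 transitions + 1 transversion over 10 sites
  a <- "AAAAACCCCC"; b <- "GGAAACCCCA"
  expect_equal(k2p_distance(a, b),
               -0.5 * log(1 - 2 * 0.2 - 0.1) - 0.25 * log(1 - 2 * 0.1),
               tolerance = 1e-12)
})

test_that("k2p matrix agrees with the ape reference on random alignments", {
  set.seed(77)
  for (i in 1:5) {
    n <- sample(4:7, 1)
    len <- 300
    aln <- setNames(vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), len, TRUE,
                   prob = c(0.3, 0.2, 0.3, 0.2)), collapse = ""),
      ""), paste0("t", seq_len(n)))
    # mutate copies of a common ancestor for realistic distances
    anc <- strsplit(aln[[1]], "")[[1]]
    aln <- setNames(vapply(seq_len(n), function(j) {
      mut <- sample(len, round(len * 0.08 * j / n))
      v <- anc
      v[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
      paste(v, collapse = "")
    }, ""), paste0("t", seq_len(n)))
    mine <- k2p_matrix(aln)
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln), "")))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-9)
  }
})

test_that("pairwise identity uses pairwise deletion of gap/ambiguous sites", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "GCGT"), 75)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)
  expect_equal(pairwise_identity("ACNT", "ACGA"), 100 * 2 / 3)
})

test_that("nj on 3 taxa solves the three-point equations exactly", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(dm)
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
})

test_that("nj recovers topology and path lengths from additive matrices", {
  set.seed(55)
  for (n in 4:6) {
    for (i in 1:8) {
      truth <- ape::unroot(ape::rtree(n))
      dm <- ape::cophenetic.phylo(truth)
      mine <- nj_tree(dm)
      expect_equal(ape::dist.topo(ape::unroot(mine), truth), 0,
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(mine)[rownames(dm), colnames(dm)],
                   dm, tolerance = 1e-6)
      # independent reference implementation finds the same topology
      ref <- ape::nj(stats::as.dist(dm))
      expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("nj validates input and clamps negative branch estimates", {
  expect_error(nj_tree(matrix(c(0, 1, 2, 3, 0, 1, 1, 2, 0), 3, 3)),
               "symmetric")
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  # near-degenerate matrix forces a negative estimate somewhere
  dm <- matrix(c(0, 1, 1, 1.9,
                 1, 0, 0.1, 1,
                 1, 0.1, 0, 1,
                 1.9, 1, 1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(dm)
  expect_true(all(tree$edge.length >= 0))
})

test_that("equidistant taxa resolve by the documented lowest-index tie-break", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  tree <- nj_tree(dm)
  # all Q values tie; the first pair (rows 1,2) must be joined
  split <- ape::prop.part(tree)
  expect_equal(ape::Ntip(tree), 4)
  pairs <- lapply(split[-1], function(p) sort(attr(split, "labels")[p]))
  expect_true(list(c("a", "b")) %in% pairs || list(c("c", "d")) %in% pairs)
})

test_that("newick writing round-trips topology, lengths and supports", {
  set.seed(9)
  tree <- ape::rtree(6)
  tree$node.label <- as.character(c(NA, 99, 87, 62, 40))
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(back$edge.length, tree$edge.length, tolerance = 1e-9)
  expect_equal(back$node.label[-1], tree$node.label[-1])
})

test_that("bootstrap gives full support to a clean split and is seed-stable", {
  aln <- make_two_clade_alignment(len = 400, seed = 10)
  t1 <- bootstrap_nj(aln, replicates = 100, seed = 42)
  t2 <- bootstrap_nj(aln, replicates = 100, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_equal(max(sup, na.rm = TRUE), 100)
  # a single replicate can only produce all-or-nothing supports
  t3 <- bootstrap_nj(aln, replicates = 1, seed = 7)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
  expect_identical(display_supports(t1),
                   ifelse(!is.na(sup) & sup >= 60, as.character(sup), ""))
})

test_that("read_alignment enforces equal lengths and taxon count", {
  p1 <- write_tmp(c(">a", "ACGT", ">b", "ACG"), ".fa")
  expect_error(read_alignment(p1), "same length")
  p2 <- write_tmp(c(">a", "ACGT"), ".fa")
  expect_error(read_alignment(p2), "2 taxa")
})
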