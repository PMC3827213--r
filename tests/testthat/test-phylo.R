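test_that("Poisson correction follows its closed form", {
  aln <- new_alignment(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  expect_equal(unname(poisson_distance(aln)["a", "b"]), 0)
  # half the shared sites differ -> d = ln 2
  aln2 <- new_alignment(c(a = "AAAACCCC", b = "AAAADDDD"))
  expect_equal(unname(poisson_distance(aln2)["a", "b"]), log(2))
  # saturated pairs are capped
  aln3 <- new_alignment(c(a = "AAAAAAAAAA", b = "CCCCCCCCCC"))
  expect_equal(unname(poisson_distance(aln3)["a", "b"]), 10)
  # gaps reduce the shared-column denominator
  aln4 <- new_alignment(c(a = "AC--", b = "AD-D"))
  expect_equal(unname(poisson_distance(aln4)["a", "b"]), -log(1 - 0.5))
  expect_error(poisson_distance(new_alignment(c(a = "A-", b = "-A"))),
               "share no ungapped")
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    rows <- stats::setNames(vapply(1:n, function(i) random_protein(40),
                                   character(1)),
                            paste0("t", 1:n))
    d <- poisson_distance(new_alignment(rows))
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(is.finite(d)))
  }
})

test_that("the 3-taxon tree has the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- bionj_tree(d)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 4) / 2)
  expect_equal(bl[["b"]], (2 + 4 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 4 - 2) / 2)
})

test_that("BioNJ exactly recovers an additive 5-taxon tree", {
  set.seed(15)
  gen <- ape::rtree(5)
  dm <- ape::cophenetic.phylo(gen)
  tr <- bionj_tree(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(gen), tr), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-6)
})

test_that("bionj_tree validates its input", {
  expect_error(bionj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                          c("a", "b")))),
               "at least 3")
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(bionj_tree(bad), "symmetric")
})

test_that("monophyly agrees with complete bipartition enumeration", {
  set.seed(23)
  for (rep in 1:50) {
    tr <- ape::unroot(ape::rtree(10))
    target <- sample(tr$tip.label, sample(2:5, 1))
    mine <- is_monophyletic(tr, target)
    idx <- sort(match(target, tr$tip.label))
    comp <- setdiff(seq_along(tr$tip.label), idx)
    oracle <- any(vapply(splits_oracle(tr), function(s) {
      identical(s, idx) || identical(s, comp)
    }, logical(1)))
    expect_identical(mine, oracle)
    # complement symmetry under the unrooted convention
    expect_identical(is_monophyletic(tr, setdiff(tr$tip.label, target)),
                     mine)
  }
})

test_that("single leaves are monophyletic; degenerate sets error", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(is_monophyletic(tr, "c"))
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_error(is_monophyletic(tr, character(0)), "empty")
  expect_error(is_monophyletic(tr, c("a", "b", "c", "d")), "proper subset")
  expect_error(is_monophyletic(tr, "zz"), "unknown")
})

test_that("newick round-trips preserve topology, labels and lengths", {
  f <- withr::local_tempfile(lines = "(a:1,b:1,c:1);")
  tr <- read_newick(f)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(sort(tr2$tip.label), c("a", "b", "c"))
  expect_equal(tr2$edge.length, tr$edge.length)
  set.seed(31)
  for (rep in 1:50) {
    g <- ape::rtree(sample(4:12, 1))
    p <- withr::local_tempfile(fileext = ".nwk")
    write_newick(g, p)
    back <- read_newick(p)
    expect_equal(phangorn::RF.dist(g, back), 0)
    expect_equal(sort(back$edge.length), sort(g$edge.length),
                 tolerance = 1e-6)
  }
  bad <- withr::local_tempfile(lines = "((a:1,b:1;")
  expect_error(read_newick(bad), "malformed|parenthe")
})

test_that("the planted cyanophage clade is recovered on synthetic families", {
  mono <- vapply(1:10, function(r) {
    fam <- simulate_family(small_config(n = 6L, seed = 4000L + r))
    out <- run_pipeline(fam$records, withr::local_tempdir(),
                        aligner = "none",
                        clade_sets = list(
                          cyanophage = grep("^cyanophage_",
                                            fam$records$id, value = TRUE)))
    out$monophyly$monophyletic[1]
  }, logical(1))
  expect_gte(sum(mono), 8L)
})
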