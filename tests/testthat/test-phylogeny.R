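# distance helpers for additive-tree checks
tree_path_dists <- function(tree) {
  ape::cophenetic.phylo(tree)
}

test_that("concatenation preserves widths and demands shared taxa", {
  b1 <- c(t1 = "ACGT", t2 = "ACGA", t3 = "ACGG")
  b2 <- c(t2 = "TTTTTT", t1 = "TTTTTA", t3 = "TTTTTC")
  cat2 <- concat_alignment(list(b1, b2))
  expect_equal(attr(cat2, "total_columns"), 10L)
  expect_equal(unname(cat2["t1"]), "ACGTTTTTTA")
  expect_error(concat_alignment(list(b1, c(t1 = "AA", t2 = "AA"))),
               "every taxon")
  expect_error(concat_alignment(list(c(t1 = "AC", t2 = "ACG", t3 = "AC"))),
               "unequal")
})

test_that("JC distances match the closed form on a constructed alignment", {
  # 100 columns, 10 differences between a and b -> p = 0.1
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  c_ <- paste0(strrep("A", 50), strrep("G", 20), strrep("A", 30))
  d <- build_distance_matrix(c(a = a, b = b, c = c_))
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  expect_equal(d["a", "b"], jc(0.1), tolerance = 1e-9)
  expect_equal(d["a", "c"], jc(0.2), tolerance = 1e-9)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
})

test_that("pairwise deletion is used and sparse overlap is an error", {
  a <- paste0(strrep("A", 100), strrep("-", 100))
  b <- paste0(strrep("A", 100), strrep("-", 100))
  c_ <- strrep("A", 200)
  expect_error(build_distance_matrix(c(a = a, b = b, c = c_),
                                     min_shared = 150),
               "fewer than 150")
  d <- build_distance_matrix(c(a = a, b = b, c = c_), min_shared = 50)
  expect_equal(d["a", "b"], 0)
})

test_that("NJ reconstructs additive distances exactly (4-6 taxa)", {
  set.seed(1201)
  for (ntaxa in 4:6) {
    tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 0.3))
    tr$tip.label <- paste0("t", seq_len(ntaxa))
    d <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(d)
    # topology identical (RF distance 0) and path lengths recovered
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)),
                 0, ignore_attr = TRUE)
    expect_equal(tree_path_dists(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("negative NJ branches are clamped without breaking paths much", {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 1.5,
                3, 3, 1.5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("rooting places the outgroup basally", {
  set.seed(1202)
  tr <- ape::rtree(5)
  tr$tip.label <- c("out", paste0("in", 1:4))
  d <- ape::cophenetic.phylo(tr)
  rooted <- neighbor_joining(d, outgroup = "out")
  expect_true(ape::is.rooted(rooted))
  expect_error(neighbor_joining(d, outgroup = "nope"), "outgroup")
})

test_that("JC simulation on a known tree is recovered by NJ", {
  set.seed(1203)
  tr <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.2))
  tr$tip.label <- paste0("t", 1:8)
  aln <- simulate_jc_alignment(tr, n_columns = 4000, seed = 1204)
  expect_equal(unique(nchar(aln)), 4000L)
  est <- neighbor_joining(build_distance_matrix(aln))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)),
               0, ignore_attr = TRUE)
})

test_that("bootstrap is seeded and supports the true clades strongly", {
  set.seed(1205)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.08, 0.25))
  tr$tip.label <- paste0("t", 1:6)
  aln <- simulate_jc_alignment(tr, n_columns = 3000, seed = 1206)
  b1 <- bootstrap_support(aln, n_reps = 30, seed = 7)
  b2 <- bootstrap_support(aln, n_reps = 30, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 80))
})

test_that("newick output round-trips through ape", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, c("x", "y", "z"))
})
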