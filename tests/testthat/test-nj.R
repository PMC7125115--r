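dmat <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

# additive matrix from a tree via its path lengths
tree_dists <- function(tree) {
  m <- cophenetic(tree)
  m[order(rownames(m)), order(colnames(m))]
}

test_that("two taxa split their distance evenly", {
  m <- dmat(0.4, c("A", "B"))
  tr <- neighbour_joining(m)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.2, 0.2))
  expect_identical(to_newick(tr), "(A:0.200000,B:0.200000);")
})

test_that("a 4-taxon additive matrix is recovered exactly", {
  # generating tree ((A:1,B:2):1,(C:3,D:4)); internal edge 1
  m <- dmat(c(3, 5, 6, 6, 7, 7), c("A", "B", "C", "D"))
  tr <- neighbour_joining(m)
  expect_equal(tree_dists(tr), m, tolerance = 1e-12)
  # AB|CD split present
  expect_true(check_monophyly(tr, c("A", "B")))
  expect_true(check_monophyly(tr, c("C", "D")))
})

test_that("NJ is consistent on random additive matrices and matches ape", {
  set.seed(50)
  for (k in 1:6) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(x) runif(x, 0.1, 1))
    m <- tree_dists(gen)
    tr <- neighbour_joining(m)
    expect_lt(max(abs(tree_dists(tr) - m)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    # independent implementation agrees on the topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(m), tr)), 0)
  }
})

test_that("label permutation yields an isomorphic tree", {
  set.seed(51)
  gen <- ape::rtree(6, br = function(x) runif(x, 0.1, 1))
  m <- tree_dists(gen)
  perm <- sample(nrow(m))
  tr1 <- neighbour_joining(m)
  tr2 <- neighbour_joining(m[perm, perm])
  expect_setequal(tr2$tip.label, tr1$tip.label)
  expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
  expect_equal(max(abs(tree_dists(tr1) - tree_dists(tr2))), 0, tolerance = 1e-12)
})

test_that("non-additive matrices (triangle violations) are still accepted", {
  # d(A,C) > d(A,B) + d(B,C): fine for gene-content distances
  m <- dmat(c(0.1, 0.9, 0.2, 0.95, 0.15, 0.9), c("A", "B", "C", "D"))
  tr <- neighbour_joining(m)
  expect_setequal(tr$tip.label, rownames(m))
  expect_true(all(tr$edge.length >= 0))
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(neighbour_joining(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
  m <- dmat(c(0.5, 0.5, 0.5), c("A", "B", "C"))
  m[1, 2] <- 0.4
  expect_error(neighbour_joining(m), "symmetric")
  # negative branch estimates are clamped to zero with a message:
  # three taxa with d(B,C) > d(A,B) + d(A,C) force a negative terminal edge
  mm <- dmat(c(1, 1, 3), c("A", "B", "C"))
  expect_message(tr <- neighbour_joining(mm), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting places the root on the longest path's centre", {
  tr2 <- neighbour_joining(dmat(0.4, c("A", "B")))
  r2 <- midpoint_root(tr2)
  expect_equal(sort(r2$edge.length), c(0.2, 0.2))

  # three leaves on a star: longest path A-C of length 4, midpoint 2 from each
  star <- from_newick("(A:1,B:0,C:3);")
  r <- midpoint_root(star)
  depths <- setNames(ape::node.depth.edgelength(r)[1:3], r$tip.label)
  expect_equal(unname(depths["A"]), 2)
  expect_equal(unname(depths["C"]), 2)
  # path lengths preserved
  expect_equal(cophenetic(r), cophenetic(star)[rownames(cophenetic(r)),
                                               colnames(cophenetic(r))])

  balanced <- from_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  rb <- midpoint_root(ape::unroot(balanced))
  db <- setNames(ape::node.depth.edgelength(rb)[1:4], rb$tip.label)
  expect_true(all(abs(db - 1.5) < 1e-12))

  zero <- from_newick("((A:0,B:0):0,C:0);")
  expect_warning(rz <- midpoint_root(zero), "zero")
  expect_true(ape::is.rooted(rz))
})

test_that("Newick writer uses fixed decimals and quotes awkward labels", {
  tr <- from_newick("((A:1,B:2):1,(C:3,D:4):1);")
  s <- to_newick(tr)
  expect_match(s, "A:1.000000", fixed = TRUE)
  expect_match(s, ";$")
  tr$tip.label[1] <- "odd:label 1"
  s2 <- to_newick(tr)
  expect_match(s2, "'odd:label 1'", fixed = TRUE)
  back <- from_newick(s2)
  expect_true("odd:label 1" %in% back$tip.label)
})

test_that("Newick round trip preserves topology and lengths at 6 decimals", {
  set.seed(52)
  tr <- ape::rtree(10, br = function(n) runif(n, 0.01, 2))
  back <- from_newick(to_newick(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  m1 <- tree_dists(tr)
  m2 <- tree_dists(back)
  expect_lt(max(abs(m1 - m2)), 2e-5)
})

test_that("unbalanced Newick input reports the offending position", {
  expect_error(from_newick("((A:1,B:2):1;"), "unclosed")
  expect_error(from_newick("(A:1,B:2)):1;"), "position 10")
})
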