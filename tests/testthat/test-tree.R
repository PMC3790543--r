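test_that("read_newick parses small trees and enforces the invariants", {
  tr <- read_newick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths, c(1, 1))

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr3), 3L)
  V <- phylo_vcv(tr3)
  expect_equal(V["A", "B"], 1)

  expect_error(read_newick("((A:1,B:1):1,C:2"), "character")
  expect_error(read_newick("((A:1,B:1)):1,C:2);"), "character|unmatched")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick("((A:1,B:-1):1,C:2);"), "non-negative")
})

test_that("phylo_vcv matches hand sums and the MRCA-walk oracle", {
  V <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(diag(V), c(A = 2, B = 2, C = 2))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["B", "C"], 0)

  Vstar <- phylo_vcv(read_newick("(A:1,B:1,C:1);"))
  expect_equal(Vstar, diag(3), ignore_attr = TRUE)

  set.seed(71)
  for (i in 1:20) {
    tr <- random_rtree(sample(5:50, 1))
    expect_equal(phylo_vcv(tr), oracle_vcv(tr), tolerance = 1e-12)
  }
})

test_that("phylo_vcv output is symmetric positive semidefinite", {
  set.seed(72)
  for (i in 1:10) {
    tr <- simulate_tree(sample(5:60, 1))
    V <- phylo_vcv(tr)
    expect_equal(V, t(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
    expect_true(all(V[upper.tri(V)] <= min(diag(V)) + 1e-12))
  }
})

test_that("lambda_transform scales off-diagonals only and composes", {
  V <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_identical(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  W <- lambda_transform(V, 0.5)
  expect_equal(W["A", "B"], 0.5)
  expect_equal(diag(W), diag(V))
  # composition: off-diagonals scaled by a * b
  expect_equal(lambda_transform(lambda_transform(V, 0.6), 0.5),
               lambda_transform(V, 0.3))
  # monotone in lambda off the diagonal
  expect_true(all(lambda_transform(V, 0.8)[upper.tri(V)] >=
                    lambda_transform(V, 0.3)[upper.tri(V)]))
  expect_error(lambda_transform(V, -0.1), "lambda")
  expect_error(lambda_transform(V, 1.1), "lambda")
})

test_that("pd_total sums the minimal root-inclusive spanning subtree", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(pd_total(tr, c("A", "B")), 3)
  expect_equal(pd_total(tr, "C"), 2)
  expect_equal(pd_total(tr), sum(tr$edge.length))
  expect_error(pd_total(tr, character(0)), "at least one")
  expect_error(pd_total(tr, c("A", "Z")), "Z")

  # monotone non-decreasing under subset inclusion
  set.seed(73)
  big <- simulate_tree(40, seed = 5)
  tips <- sample(big$tip.label)
  pds <- vapply(seq(2, 40, by = 4),
                function(k) pd_total(big, tips[seq_len(k)]), numeric(1))
  expect_true(all(diff(pds) >= -1e-12))
  expect_equal(pd_total(big, big$tip.label) / pd_total(big), 1)
})

test_that("polytomies are accepted by vcv/pd but must be resolved for D", {
  poly <- read_newick("((A:1,B:1,C:1):1,D:2);")
  expect_equal(phylo_vcv(poly)["A", "C"], 1)
  expect_equal(pd_total(poly, c("A", "D")), 4)
  x <- c(A = 1, B = 1, C = 0, D = 0)
  expect_error(sum_sister_differences(poly, x), "binary")
  expect_error(fit_D(poly, x, n_perm = 100), "binary")
  expect_s3_class(fit_D(poly, x, n_perm = 100, seed = 1, resolve = TRUE), "D_fit")
  bin <- resolve_polytomies(poly)
  expect_true(ape::is.binary(bin))
  expect_equal(sum(bin$edge.length), sum(poly$edge.length))
})

test_that("a non-ultrametric tree triggers the lambda interpretation warning", {
  tr <- read_newick("((A:1,B:3):1,C:2);")
  x <- c(A = 1, B = 2, C = 3, D = 4)
  expect_warning(fit_lambda(read_newick("((A:1,B:3):1,(C:2,D:5):1);"),
                            c(A = 1, B = 2.5, C = 0.3, D = 4)),
                 "ultrametric")
})
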