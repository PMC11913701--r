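test_that("distanceFromPIM is the p-distance transform", {
  v <- matrix(c(100, 77.1, 0,
                77.1, 100, 50,
                0, 50, 100), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  pim <- new("PercentIdentityMatrix", values = v)
  d <- distanceFromPIM(pim)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], 0.229)
  expect_equal(d["a", "c"], 1)
  dk <- distanceFromPIM(pim, correction = "kimura")
  expect_gt(dk["a", "b"], d["a", "b"])  # correction stretches distances
})

test_that("three-taxon neighbor joining solves the two-point equations", {
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  tr <- njTree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["a"]], (5 + 9 - 8) / 2)
  expect_equal(len[["b"]], (5 + 8 - 9) / 2)
  expect_equal(len[["c"]], (9 + 8 - 5) / 2)
})

test_that("NJ recovers topology and distances from additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (i in 1:25) {
    inst <- random_additive(sample(4:10, 1))
    tr <- njTree(inst$d)
    expect_equal(phangorn::RF.dist(tr, ape::unroot(inst$tree)), 0)
    got <- stats::cophenetic(tr)[rownames(inst$d), colnames(inst$d)]
    expect_lt(max(abs(got - inst$d)), 1e-9)
  }
})

test_that("NJ is label-permutation equivariant and validates input", {
  skip_if_not_installed("phangorn")
  set.seed(22)
  inst <- random_additive(6)
  perm <- sample(6)
  tr1 <- njTree(inst$d)
  tr2 <- njTree(inst$d[perm, perm])
  expect_equal(phangorn::RF.dist(tr1, tr2), 0)
  bad <- inst$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(njTree(bad), "symmetric")
  neg <- inst$d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(njTree(neg), "non-negative")
})

test_that("two-leaf trees midpoint-root at half the path", {
  tr <- njTree(matrix(c(0, 6, 6, 0), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  # force asymmetric branch lengths 2 and 4
  tr$edge.length <- c(2, 4)
  r <- midpointRoot(tr)
  expect_equal(unname(root_depths(r)), c(3, 3))
  expect_equal(sum(r$edge.length), 6)
})

test_that("midpoint rooting equalizes the two most distant leaves", {
  set.seed(23)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:15, 1), rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    r <- midpointRoot(tr)
    expect_true(ape::is.rooted(r))
    depths <- root_depths(r)
    D <- stats::cophenetic(tr)
    expect_equal(max(depths) * 2, max(D), tolerance = 1e-9)
    # the two deepest leaves realize the diameter, equidistant from root
    top2 <- sort(depths, decreasing = TRUE)[1:2]
    expect_equal(unname(top2[1]), unname(top2[2]), tolerance = 1e-9)
    expect_equal(sum(r$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("midpoint rooting agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(24)
  for (i in 1:10) {
    tr <- ape::rtree(8, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    mine <- midpointRoot(tr)
    ref <- phangorn::midpoint(tr)
    expect_equal(root_depths(mine)[tr$tip.label],
                 root_depths(ref)[tr$tip.label], tolerance = 1e-9)
  }
})

test_that("Newick output has the documented shape and quoting", {
  tr <- njTree(matrix(c(0, 6, 6, 0), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(toNewick(tr), "(A:3,B:3);")
  lab <- "jgi|ChlNC64A|41714"
  tr$tip.label[1] <- lab
  nwk <- toNewick(tr)
  expect_match(nwk, "'jgi|ChlNC64A|41714'", fixed = TRUE)
  back <- fromNewick(nwk)
  expect_setequal(back$tip.label, c(lab, "B"))
})

test_that("Newick round-trip preserves topology and branch lengths", {
  skip_if_not_installed("phangorn")
  set.seed(25)
  for (i in 1:10) {
    tr <- ape::rtree(20)
    back <- fromNewick(toNewick(tr, digits = 10))
    expect_equal(phangorn::RF.dist(tr, back), 0)
    D1 <- stats::cophenetic(tr)
    D2 <- stats::cophenetic(back)[rownames(D1), colnames(D1)]
    expect_lt(max(abs(D1 - D2)), 1e-6)
  }
})

test_that("toNewick output is readable by ape", {
  set.seed(26)
  tr <- ape::rtree(12)
  back <- ape::read.tree(text = toNewick(tr, digits = 10))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})

test_that("malformed Newick raises positional parse errors", {
  expect_error(fromNewick("((A:1,B:2);"), "position")
  expect_error(fromNewick("(A:1,,B:2);"), "dangling|empty")
  expect_error(fromNewick("(A:1,B:2)"), "expected ';'")
  expect_error(fromNewick("(A:1,B:2); junk"), "trailing")
  expect_error(fromNewick("(A:1,B:abc);"), "position")
})
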