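test_that("binary matrix scores allele presence with deterministic columns", {
  cells <- matrix(list(c(100L, 100L), c(100L, 120L), integer(0)), 3,
                  dimnames = list(c("A", "B", "C"), "M1"))
  tb <- genotype_table(cells)
  bm <- to_binary_matrix(tb)
  expect_equal(colnames(bm), c("M1:100", "M1:120"))
  expect_equal(bm["A", ], c(`M1:100` = 1L, `M1:120` = 0L))
  expect_equal(bm["B", ], c(`M1:100` = 1L, `M1:120` = 1L))
  expect_equal(unname(bm["C", ]), c(0L, 0L))  # missing -> all zero

  tri <- genotype_table(
    matrix(list(c(100L, 100L, 120L)), 1, dimnames = list("t", "M")),
    ploidy = 3L)
  expect_equal(unname(to_binary_matrix(tri)[1, ]), c(1L, 1L))
})

test_that("binary dissimilarities match their set definitions", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  expect_equal(as.matrix(binary_distance(m, "jaccard"))["a", "b"], 2 / 3)
  expect_equal(as.matrix(binary_distance(m, "dice"))["a", "b"], 0.5)
  expect_equal(as.matrix(binary_distance(m, "simple_matching"))["a", "b"],
               2 / 3)

  m2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  d <- as.matrix(binary_distance(m2, "jaccard"))
  expect_equal(d["a", "b"], 0)     # identical rows
  expect_equal(d["a", "c"], 1)     # disjoint rows

  # all-zero rows: 0 to each other, 1 to anything else
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  d3 <- as.matrix(binary_distance(m3, "jaccard"))
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 1)
  expect_error(binary_distance(m3[1, , drop = FALSE]), "at least 2")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)$tree
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces additive distances from random trees", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    dd <- stats::cophenetic(true)
    rec <- nj_tree(dd)$tree
    dr <- stats::cophenetic(rec)[rownames(dd), colnames(dd)]
    expect_lt(max(abs(dr - dd)), 1e-9)
  }
})

test_that("equidistant taxa give a star-like tree with equal terminal branches", {
  n <- 5
  d <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- nj_tree(d)$tree
  term <- tr$edge.length[tr$edge[, 2] <= n]
  expect_true(all(abs(term - term[1]) < 1e-12))
})

test_that("newick export carries branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- nj_tree(d)$newick
  expect_match(nwk, "^\\(")
  expect_match(nwk, "C:3")
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("negative NJ branches are clamped with total length preserved", {
  # deliberately non-additive distances that force a negative branch
  d <- matrix(c(0, 1, 10, 9,
                1, 0, 9, 10,
                10, 9, 0, 0.1,
                9, 10, 0.1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(as.dist(d))
  tr <- nj_tree(d)$tree
  if (any(raw$edge.length < 0)) {
    expect_true(all(tr$edge.length >= 0))
    expect_equal(sum(tr$edge.length), sum(raw$edge.length))
  } else {
    expect_equal(tr$edge.length, raw$edge.length)
  }
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(17)
  X <- matrix(rnorm(24), 12, 2)
  rownames(X) <- sprintf("s%02d", 1:12)
  p <- pcoa(dist(X), k = 2)
  expect_lt(max(abs(dist(p$points) - dist(X))), 1e-8)
  expect_equal(sort(p$eigenvalues, decreasing = TRUE), p$eigenvalues)

  # collinear points: first axis carries all positive inertia
  Y <- cbind(seq(0, 5, length.out = 6), 0)
  rownames(Y) <- letters[1:6]
  p1 <- pcoa(dist(Y), k = 1)
  pos <- p1$eigenvalues[p1$eigenvalues > 1e-9]
  expect_equal(p1$eigenvalues[1] / sum(pos), 1)

  # identical samples land on identical coordinates
  Z <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4), d = c(6, 0))
  pz <- pcoa(dist(Z), k = 2)
  expect_equal(pz$points["a", ], pz$points["b", ])
})

test_that("PCoA warns when fewer positive axes exist than requested", {
  Y <- cbind(seq_len(4), 0)
  rownames(Y) <- letters[1:4]
  expect_warning(pcoa(dist(Y), k = 3), "positive eigenvalue")
})

test_that("axis signs are canonical and relabeling permutes outputs consistently", {
  set.seed(23)
  X <- matrix(rnorm(20), 10, 2)
  rownames(X) <- sprintf("s%02d", 1:10)
  p1 <- pcoa(dist(X), k = 2)
  for (j in 1:2) {
    expect_gt(p1$points[which.max(abs(p1$points[, j])), j], 0)
  }
  perm <- sample(10)
  Xp <- X[perm, , drop = FALSE]
  p2 <- pcoa(dist(Xp), k = 2)
  expect_equal(abs(p2$points[rownames(X), ]), abs(p1$points),
               tolerance = 1e-9)

  dd <- as.matrix(dist(X))
  t1 <- nj_tree(dd)$tree
  t2 <- nj_tree(dd[perm, perm])$tree
  expect_equal(sort(stats::cophenetic(t2)[rownames(dd), rownames(dd)]),
               sort(stats::cophenetic(t1)[rownames(dd), rownames(dd)]))
})

test_that("tree cutting partitions the tips into k groups", {
  set.seed(3)
  X <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 8), 5))
  rownames(X) <- sprintf("s%02d", 1:10)
  tr <- nj_tree(dist(X))$tree
  g <- cut_tree_groups(tr, 2)
  expect_equal(length(unique(g)), 2L)
  expect_equal(unname(g[1:5] == g[1]), rep(TRUE, 5))
  expect_true(all(g[6:10] != g[1]))
})

test_that("distance matrices export as square TSV", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(binary_distance(m, "jaccard"), f)
  tab <- utils::read.delim(f)
  expect_equal(tab$sample, c("a", "b"))
  expect_equal(tab$b[1], 1)
})
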