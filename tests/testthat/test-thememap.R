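test_that("binary matrix is first-appearance ordered and idempotent", {
  assoc <- data.frame(gene_id = c("g1", "g2", "g1"),
                      theme_id = c("t1", "t2", "t1"),
                      stringsAsFactors = FALSE)
  m <- build_binary_matrix(assoc)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(rownames(m), c("g1", "g2"))
  expect_equal(unname(m), matrix(c(1L, 0L, 0L, 1L), 2))
  # duplicated pair changes nothing
  expect_equal(build_binary_matrix(assoc[c(1, 1, 2), ]), m[, , drop = FALSE])
})

test_that("profile distances are sqrt of disagreement counts", {
  m <- rbind(g1 = c(1L, 0L, 0L), g2 = c(0L, 1L, 0L), g3 = c(1L, 0L, 0L))
  colnames(m) <- c("t1", "t2", "t3")
  d <- euclidean_distances(m)
  expect_equal(d["g1", "g2"], sqrt(2))
  expect_equal(d["g1", "g3"], 0)
  expect_equal(euclidean_distances(rbind(a = c(1L, 1L),
                                         b = c(0L, 0L)))["a", "b"], sqrt(2))
  expect_error(euclidean_distances(m[1, , drop = FALSE]), "2 rows")
})

test_that("UPGMA reproduces hand-worked merges", {
  # three leaves: close pair first, then the singleton at the plain average
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dg3 <- upgma(d3)
  expect_equal(dg3$height, c(1, 4))
  expect_equal(dg3$labels[dg3$order], c("a", "b", "c"))
  # four leaves, uniform far distances: size-weighted average stays 8
  d4 <- matrix(8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0
  d4["a", "b"] <- d4["b", "a"] <- 2
  dg4 <- upgma(d4)
  expect_equal(dg4$height[1], 2)
  expect_equal(dg4$height[2], 8)  # d((ab), c) = (8+8)/2
  # all-equal distances: merge order fully set by the index tie-break
  de <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  dge <- upgma(de)
  expect_equal(dge$merge[1, ], c(-1L, -2L))
  expect_equal(dge$merge[2, ], c(-3L, 1L))  # cluster {1,2} joins leaf 3
})

test_that("UPGMA heights match a recompute-from-scratch oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- matrix(runif(n * 4), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("r", seq_len(n)), paste0("r", seq_len(n)))
    dg <- upgma(d)
    expect_true(upgma_matches_oracle(dg, oracle_upgma(d), tol = 1e-9))
    # heights never decrease (average linkage on a metric)
    expect_true(all(diff(dg$height) >= -1e-12))
    # cross-check heights against stats::hclust average linkage
    hc <- stats::hclust(as.dist(d), method = "average")
    expect_equal(sort(dg$height), sort(hc$height), tolerance = 1e-9)
  }
})

test_that("identical profiles sit adjacent in the leaf order", {
  m <- rbind(g1 = c(1L, 0L, 1L), g2 = c(0L, 1L, 1L), g3 = c(1L, 0L, 1L),
             g4 = c(0L, 0L, 1L))
  dg <- upgma(euclidean_distances(m))
  ord <- rownames(m)[dg$order]
  expect_equal(abs(which(ord == "g1") - which(ord == "g3")), 1L)
  expect_equal(dg$height[1], 0)
})

test_that("matrix export honours sort modes and round-trips", {
  m <- rbind(g2 = c(1L, 0L), g1 = c(0L, 1L))
  colnames(m) <- c("t1", "t2")
  dg <- upgma(euclidean_distances(m))
  f <- withr::local_tempfile(fileext = ".tsv")
  byname <- export_matrix(m, dg, sort = "name", path = f)
  expect_equal(rownames(byname), c("g1", "g2"))
  back <- read_binary_matrix(f)
  expect_equal(unname(back), unname(byname), ignore_attr = TRUE)
  bynone <- export_matrix(m, dg, sort = "none", path = f)
  expect_equal(rownames(bynone), c("g2", "g1"))
  bycl <- export_matrix(m, dg, sort = "cluster", path = f)
  expect_equal(rownames(bycl), rownames(m)[dg$order])
  # Newick export is a valid single-tree string over the leaves
  nwk <- dendrogram_newick(dg)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(m))
})

test_that("nonzero user matrix entries coerce to 1 and zero rows drop", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\tt1\tt2", "g1\t2\t0", "g2\t0\t0", "g3\t1\t1"))
  expect_warning(m <- suppressMessages(read_binary_matrix(f)), "coerced")
  expect_equal(rownames(m), c("g1", "g3"))
  expect_equal(attr(m, "dropped_rows"), "g2")
  expect_true(all(m %in% c(0L, 1L)))
})
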