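test_that("dominance split applies the threshold and exclusion rules", {
  X <- matrix(c(99, 1), 1, 2, dimnames = list("c1", c("A", "B")))
  sp <- split_dominant_secondary(X, 0.005)
  expect_setequal(sp$dominant, c("A", "B"))  # 1% > 0.5%

  X2 <- matrix(c(99.6, 0.4), 1, 2, dimnames = list("c1", c("A", "B")))
  sp2 <- split_dominant_secondary(X2, 0.005)
  expect_equal(sp2$secondary, "B")

  X3 <- matrix(c(80, 10, 10), 1, 3, dimnames = list("c1", c("A", "Copepoda", "B")))
  sp3 <- split_dominant_secondary(X3, 0.005, exclusion = "Copepoda")
  expect_true("Copepoda" %in% sp3$dominant)
  expect_false("Copepoda" %in% sp3$clustering)

  expect_error(split_dominant_secondary(matrix(0, 2, 2)), "zero")
})

test_that("Hellinger transform and distance follow the closed forms", {
  expect_equal(hellinger_transform(rbind(c(4, 0, 0)))[1, ], c(1, 0, 0))
  expect_equal(hellinger_transform(rbind(rep(1, 4)))[1, ], rep(0.5, 4))
  expect_equal(hellinger_transform(rbind(c(1, 3)))[1, ], c(0.5, sqrt(3) / 2))

  X <- rbind(c(0, 0), c(1, 1))
  Y <- hellinger_transform(X)
  expect_equal(Y[1, ], c(0, 0))
  expect_equal(attr(Y, "zero_rows"), 1L)

  Y2 <- hellinger_transform(rbind(c(1, 0), c(0, 1)))
  D <- hellinger_distance(Y2)
  expect_equal(D[1, 2], sqrt(2))
  expect_equal(diag(D), c(0, 0), ignore_attr = TRUE)

  # random matrices: unit rows, distances bounded by sqrt(2)
  set.seed(8)
  M <- matrix(rexp(60), 10, 6)
  YM <- hellinger_transform(M)
  expect_equal(unname(rowSums(YM^2)), rep(1, 10))
  expect_true(all(hellinger_distance(YM) <= sqrt(2) + 1e-12))

  # worked 4 x 3 distances vs the elementwise formula
  W <- matrix(c(1, 2, 3, 0, 1, 0, 4, 4, 4, 2, 0, 2), 4, 3, byrow = TRUE)
  YW <- hellinger_transform(W)
  DW <- hellinger_distance(YW)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(DW[i, j], sqrt(sum((YW[i, ] - YW[j, ])^2)))
  }
})

test_that("fanny memberships are valid, monotone in objective and scale-invariant", {
  D <- block_distance(c(5, 5))
  fm <- fanny_cluster(D, 2, seed = 1)
  expect_true(all(fm$U >= 0 & fm$U <= 1))
  expect_equal(unname(rowSums(fm$U)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(diff(fm$trace) <= 1e-12))
  # every cell prefers its own block
  expect_true(all(fm$U[cbind(1:10, rep(fm$labels[c(1, 6)], each = 5))] > 0.9))

  fm3 <- fanny_cluster(3 * D, 2, seed = 1)
  expect_equal(fm3$objective, 3 * fm$objective, tolerance = 1e-9)
  expect_equal(fm3$U, fm$U, tolerance = 1e-6)

  Dz <- matrix(0, 6, 6)
  expect_equal(fanny_cluster(Dz, 2, seed = 1)$objective, 0)
  expect_error(fanny_cluster(D, 10, seed = 1), "smaller")
})

test_that("the k = 1 relaxation of the objective is the mean pairwise dissimilarity", {
  set.seed(4)
  n <- 8
  D <- as.matrix(dist(matrix(rnorm(16), n, 2)))
  U <- matrix(1, n, 1)
  expect_equal(plankgrid:::fanny_objective(D, U, 1.2), sum(D) / (2 * n))
})

test_that("our fanny matches the reference implementation's solution quality", {
  skip_if_not_installed("cluster")
  set.seed(11)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2),
               matrix(rnorm(20, 8), 10, 2))
  D <- as.matrix(dist(pts))
  ours <- fanny_cluster(D, 3, seed = 2)
  ref <- cluster::fanny(as.dist(D), 3, memb.exp = 1.2, maxit = 1000)
  obj_ref <- plankgrid:::fanny_objective(D, ref$membership, 1.2)
  expect_lte(ours$objective, obj_ref + 1e-6)
  expect_equal(
    mclust::adjustedRandIndex(ours$labels, max.col(ref$membership)), 1)
})

test_that("row order only permutes memberships when cells are labelled", {
  D <- block_distance(c(4, 4), within = 0.3, between = 5)
  fm <- fanny_cluster(D, 2, seed = 9)
  perm <- c(3, 7, 1, 5, 2, 8, 6, 4)
  Dp <- D[perm, perm]
  fmp <- fanny_cluster(Dp, 2, seed = 9)
  expect_equal(fmp$U[rownames(D), ], fm$U, tolerance = 1e-9)
})

test_that("crisp maps break ties toward the lowest cluster", {
  U <- rbind(c(0.7, 0.3), c(0.5, 0.5))
  mm <- max_membership_map(U)
  expect_equal(unname(mm$label), c(1, 1))
  expect_equal(unname(mm$membership), c(0.7, 0.5))
  expect_equal(unname(max_membership_map(rbind(rep(0.2, 5)))$label), 1)
  expect_equal(unname(max_membership_map(rbind(rep(0.2, 5)))$membership), 0.2)
})

test_that("silhouette widths follow the hand formula", {
  D <- block_distance(c(2, 2), within = 0, between = 10)
  s <- silhouette_widths(D, c(1, 1, 2, 2))
  expect_equal(unname(s$widths), rep(1, 4))

  # singleton convention
  D2 <- block_distance(c(2, 1), within = 1, between = 5)
  s2 <- silhouette_widths(D2, c(1, 1, 2))
  expect_equal(unname(s2$widths[3]), 0)

  # 5-point worked example against a direct double loop
  set.seed(21)
  P <- matrix(runif(10), 5, 2)
  D5 <- as.matrix(dist(P))
  lab <- c(1, 1, 2, 2, 2)
  s5 <- silhouette_widths(D5, lab)
  for (i in 1:5) {
    own <- which(lab == lab[i] & seq_len(5) != i)
    a <- if (length(own)) mean(D5[i, own]) else 0
    b <- min(sapply(setdiff(unique(lab), lab[i]),
                    function(c2) mean(D5[i, lab == c2])))
    expect_equal(unname(s5$widths[i]), (b - a) / max(a, b))
  }
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(lab, dmatrix = D5)
  expect_equal(unname(s5$widths), unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("Mantel correlation equals Pearson on the lower triangles", {
  D <- block_distance(c(3, 3), within = 1, between = 3)
  expect_equal(mantel_correlation(D, c(1, 1, 1, 2, 2, 2)), 1)
  expect_error(mantel_correlation(matrix(2, 4, 4) - diag(2, 4), c(1, 1, 2, 2)),
               "variance")

  set.seed(13)
  D6 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  lab <- c(1, 2, 1, 2, 1, 2)
  M <- (outer(lab, lab, `!=`)) * 1
  oracle <- cor(D6[lower.tri(D6)], M[lower.tri(M)])
  expect_equal(mantel_correlation(D6, lab), oracle)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(as.dist(D6), as.dist(M), permutations = 0)
  expect_equal(mantel_correlation(D6, lab), unname(ref$statistic), tolerance = 1e-12)
})

test_that("KGS penalty is minimized where the tree supports the block count", {
  D <- block_distance(c(5, 5), within = 0.1, between = 10)
  pen <- kgs_penalty(D, 2:6)
  expect_equal(as.integer(names(pen)[which.min(pen)]), 2)

  # equidistant points carry no cluster structure: the penalty minimum sits
  # at the smallest candidate k (splitting buys nothing, k is pure cost)
  Dflat <- matrix(4, 6, 6) - diag(4, 6)
  penf <- kgs_penalty(Dflat, 2:4)
  expect_equal(as.integer(names(penf)[which.min(penf)]), 2)

  expect_equal(unname(kgs_penalty(D, 3)), 1 + 3)  # length-1 range maps to 1

  expect_warning(pz <- kgs_penalty(matrix(0, 5, 5), 2:3), "all-zero")
  expect_equal(unname(pz), c(2, 3))
})

test_that("k-selection tables are well-formed and duplication-invariant", {
  D <- block_distance(c(4, 4, 4), within = 0.5, between = 6)
  tab <- select_k_table(D, 2:5, seed = 3)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mean_silhouette >= -1 & tab$mean_silhouette <= 1))
  expect_true(all(tab$mantel_r >= -1 & tab$mantel_r <= 1))
  best <- tab$k[which.max(tab$mean_silhouette)]
  expect_equal(best, 3)

  # duplicating every cell leaves the silhouette argmax unchanged
  idx <- rep(seq_len(nrow(D)), each = 2)
  D2 <- D[idx, idx]
  rownames(D2) <- colnames(D2) <- sprintf("dup%02d", seq_along(idx))
  tab2 <- select_k_table(D2, 2:5, seed = 3)
  expect_equal(tab2$k[which.max(tab2$mean_silhouette)], best)

  expect_equal(nrow(select_k_table(D, 2, seed = 1)), 1)
})
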