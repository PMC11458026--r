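test_that("N/P ratio arithmetic and missingness rules", {
  expect_equal(np_ratio(1, 10, 5, 1), 16)  # Redfield reference point
  expect_true(is.na(np_ratio(1, 1, 1, 0)))
  expect_equal(np_ratio(0, 0, 0, 2), 0)
  expect_equal(np_ratio(c(1, 1), c(10, 1), c(5, 1), c(1, NA)),
               c(16, NA))
})

test_that("PCA matches an eigen-decomposition oracle with the sign rule", {
  set.seed(6)
  # two perfectly correlated variables: one dimension carries everything
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x)
  rownames(X) <- sprintf("c%02d", 1:20)
  pc <- drivers_pca(X, scale = TRUE)
  expect_equal(unname(pc$explained_var[1]), 1, tolerance = 1e-9)

  # 6 x 3 worked matrix: explained variances from a direct eigen solve
  W <- matrix(c(2, 1, 0, 4, 3, 1, 1, 0, 2, 5, 4, 2, 3, 3, 3, 0, 1, 1), 6, 3,
              byrow = TRUE, dimnames = list(sprintf("r%d", 1:6), c("u", "v", "w")))
  pc2 <- drivers_pca(W, center = TRUE, scale = FALSE)
  ev <- eigen(cov(W))$values
  expect_equal(unname(pc2$explained_var), ev / sum(ev), tolerance = 1e-9)
  # scores are centered and the sign convention is applied
  expect_lt(max(abs(colMeans(pc2$scores))), 1e-9)
  for (d in seq_len(ncol(pc2$loadings))) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, d])), d], 0)
  }
  expect_equal(sum(pc2$explained_var), 1, tolerance = 1e-9)

  # duplicated cell changes scores only, not loadings
  W2 <- rbind(W, r7 = W[1, ])
  pc3 <- drivers_pca(W2, center = TRUE, scale = FALSE)
  expect_equal(dim(pc3$loadings), dim(pc2$loadings))

  Xz <- cbind(a = rnorm(10), flatvar = rep(2, 10))
  expect_error(drivers_pca(Xz, scale = TRUE), "flatvar")
})

test_that("supplementary projection is the correlation with the scores", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("c%d", 1:20), c("a", "b", "d")))
  pc <- drivers_pca(X)
  co <- project_supplementary(pc, pc$scores[, "Dim.1"])
  expect_equal(unname(co["Dim.1"]), 1, tolerance = 1e-9)
  expect_lt(max(abs(co[-1])), 1e-9)

  v <- pc$scores[, "Dim.1"] + rnorm(20, 0, 0.5)
  co2 <- project_supplementary(pc, v)
  expect_equal(unname(co2), unname(cor(v, pc$scores)[1, ]))

  expect_error(project_supplementary(pc, rep(1, 20)), "zero variance")
})

test_that("the design export carries products, clusters and the cross-PCA check", {
  pipe <- cached_pipeline(1)
  des <- pipe$glmm_design
  expect_true(all(c("Dim.1abiotic", "Dim.2abiotic", "Dim.1biotic",
                    "Dim.1abiotic_x_Dim.1biotic", "Dim.2abiotic_x_Dim.1biotic",
                    "cluster") %in% names(des)))
  expect_equal(des$Dim.1abiotic_x_Dim.1biotic,
               des$Dim.1abiotic * des$Dim.1biotic, tolerance = 1e-12)
  expect_equal(des$Dim.2abiotic_x_Dim.1biotic,
               des$Dim.2abiotic * des$Dim.1biotic, tolerance = 1e-12)
  expect_true(all(colnames(pipe$cells$mean_raw) %in% names(des)))
  cr <- attr(des, "cross_pca_correlation")
  expect_equal(unname(cr["Dim.1abiotic", "Dim.1biotic"]),
               cor(des$Dim.1abiotic, des$Dim.1biotic), tolerance = 1e-12)
})

test_that("per-cluster means equal the group-by oracle", {
  pipe <- cached_pipeline(1)
  pcm <- per_cluster_means(pipe$cells, pipe$labels)
  lab <- as.integer(pipe$labels[pipe$cells$cells$cell_id])
  for (c0 in sort(unique(lab))) {
    expect_equal(unname(pcm[c0, ]),
                 unname(colMeans(pipe$cells$mean_raw[lab == c0, , drop = FALSE])))
  }
  # two cells (2, 4) in one cluster average to 3
  fake <- list(cells = data.frame(cell_id = c("a", "b")),
               mean_raw = matrix(c(2, 4), 2, 1, dimnames = list(c("a", "b"), "T")))
  expect_equal(unname(per_cluster_means(fake, c(a = 1, b = 1))[1, 1]), 3)
})

test_that("cell differences subtract elementwise on shared cells", {
  pipe <- cached_pipeline(1)
  ct <- pipe$cells
  cd0 <- cell_difference(ct, ct)
  expect_true(all(cd0$diff == 0))
  expect_true(all(cd0$total_diff == 0))

  ct2 <- ct
  ct2$mean_raw[, 1] <- ct2$mean_raw[, 1] + 1
  cd1 <- cell_difference(ct, ct2)
  expect_equal(unname(cd1$diff[, 1]), rep(1, nrow(cd1$diff)))
  expect_true(all(cd1$diff[, -1] == 0))

  set.seed(3)
  ct3 <- ct
  ct3$mean_raw <- ct$mean_raw + matrix(rnorm(length(ct$mean_raw)), nrow(ct$mean_raw))
  ct3$mean_raw[ct3$mean_raw < 0] <- 0
  cd2 <- cell_difference(ct, ct3)
  expect_equal(cd2$diff, ct3$mean_raw - ct$mean_raw, tolerance = 1e-12)

  ct4 <- ct
  ct4$cells$lon_min <- ct4$cells$lon_min + 0.1
  expect_error(cell_difference(ct, ct4), "different grids")
})

test_that("anomalies are deviations from the period mean", {
  a <- anomaly_series(2000:2004, rep(5, 5))
  expect_true(all(a$anomaly == 0))

  b <- anomaly_series(c(2008, 2022), c(1, 3))
  expect_equal(b$anomaly, c(-1, 1))
  expect_equal(b$standardized, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(10)
  v <- rnorm(25, 10, 2); v[c(4, 9)] <- NA
  s <- anomaly_series(1998:2022, v)
  ok <- !is.na(v)
  expect_equal(s$anomaly, v[ok] - mean(v[ok]))
  expect_equal(s$standardized, (v[ok] - mean(v[ok])) / sd(v[ok]))
  expect_equal(sum(s$anomaly), 0, tolerance = 1e-9)
  expect_error(anomaly_series(2000, 1), "at least 2")
})

test_that("restricted re-clustering is idempotent on the full extent and recovers two regions", {
  pipe <- cached_pipeline(1)
  sc <- scenario_default()
  cfg <- pipe$config
  cfg$cell_size_deg <- pipe$cell_size_deg
  full <- restrict_and_recluster(pipe$survey$datasets, sc$polygon, cfg)
  expect_equal(full$cells$mean_raw, pipe$cells$mean_raw)
  expect_equal(full$cells$mean_log, pipe$cells$mean_log)

  # western half holds regions 1 and 4: k = 2 should separate them
  west <- study_polygon(cbind(c(-5, -3.4, -3.4, -5), c(45, 45, 48, 48)))
  cfg2 <- cfg
  cfg2$k <- 2L
  res <- restrict_and_recluster(pipe$survey$datasets, west, cfg2)
  truth <- true_regions(res$cells$cells$lon_centroid,
                        res$cells$cells$lat_centroid, sc)
  keep <- truth %in% c(1, 4)
  ari <- mclust::adjustedRandIndex(res$labels[keep], truth[keep])
  expect_gte(ari, 0.9)

  far <- study_polygon(cbind(c(20, 21, 21, 20), c(10, 10, 11, 11)))
  expect_error(restrict_and_recluster(pipe$survey$datasets, far, cfg2))
})

test_that("environmental cell table separates the regional nutrient regimes", {
  pipe <- cached_pipeline(1)
  env <- pipe$env_cells
  expect_equal(env$nox, env$no3 + env$no2, tolerance = 1e-12)
  expect_equal(env$np_ratio, (env$no2 + env$no3 + env$nh4) / env$po4,
               tolerance = 1e-12)
  expect_true(!is.null(pipe$abiotic_pca))
  expect_true(all(is.finite(pipe$np_supplementary)))
  expect_true(sum(pipe$abiotic_pca$explained_var[1:2]) > 0.4)
})
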