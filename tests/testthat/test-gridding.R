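test_that("grid construction keeps exactly the polygon-intersecting cells", {
  poly <- unit_square()
  expect_equal(nrow(build_grid(poly, 0.5)$cells), 4)
  expect_equal(nrow(build_grid(poly, 2)$cells), 1)

  rect <- study_polygon(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  grid <- build_grid(rect, 0.83)
  # oracle: exhaustive intersection of the 3 x 2 candidate lattice
  expected <- 0
  for (cx in 0:2) for (cy in 0:1) {
    x0 <- cx * 0.83; y0 <- cy * 0.83
    if (min(x0 + 0.83, 2) - max(x0, 0) > 0 && min(y0 + 0.83, 1) - max(y0, 0) > 0) {
      expected <- expected + 1
    }
  }
  expect_equal(nrow(grid$cells), expected)

  far <- study_polygon(cbind(c(10, 11, 11, 10), c(10, 10, 11, 11)))
  expect_error(build_grid(far, 0.5, origin = c(0, 0)), NA)  # origin below bbox ok
  expect_error(build_grid(poly, 0.5, origin = c(0.2, 0)), "origin")
})

test_that("station assignment follows the half-open greater-side rule", {
  poly <- unit_square()
  grid <- build_grid(poly, 0.5)
  st <- data.frame(station_id = c("edge", "out", "in"),
                   lon = c(0.5, 1.4, 0.2), lat = c(0.25, 0.5, 0.8))
  d <- survey_dataset("x", st, abundance = matrix(1, 3, 1, dimnames = list(st$station_id, "T")))
  asg <- assign_stations(d, grid, poly)
  expect_equal(unname(asg["edge"]), "c02_01")  # boundary goes to greater side
  expect_false("out" %in% names(asg))          # outside polygon: dropped
  expect_equal(unname(asg["in"]), "c01_02")
})

test_that("assignment agrees with a point-in-rectangle oracle and ignores order", {
  poly <- unit_square()
  grid <- build_grid(poly, 0.25)
  set.seed(3)
  st <- data.frame(station_id = sprintf("s%03d", 1:100),
                   lon = runif(100), lat = runif(100))
  d <- survey_dataset("x", st,
                      abundance = matrix(1, 100, 1, dimnames = list(st$station_id, "T")))
  asg <- assign_stations(d, grid, poly)
  for (i in 1:100) {
    col <- min(floor(st$lon[i] / 0.25) + 1, 4)
    row <- min(floor(st$lat[i] / 0.25) + 1, 4)
    expect_identical(unname(asg[st$station_id[i]]), sprintf("c%02d_%02d", col, row))
  }
  perm <- sample(100)
  d2 <- survey_dataset("x", st[perm, ],
                       abundance = matrix(1, 100, 1,
                                          dimnames = list(st$station_id[perm], "T")))
  asg2 <- assign_stations(d2, grid, poly)
  expect_identical(asg2[names(asg)], asg)
})

test_that("bootstrap means honor exact cases and the analytic expectation", {
  expect_identical(bootstrap_cell_mean(7, B = 5, seed = 1, transform = "raw"), 7)
  expect_identical(bootstrap_cell_mean(0, B = 5, seed = 1, transform = "log1p"), 0)
  got <- bootstrap_cell_mean(c(0, 2), B = 10000, seed = 42, transform = "raw")
  expect_lt(abs(got - 1.0), 0.05)  # 3 SE of the B-averaged resample mean
  expect_identical(got, bootstrap_cell_mean(c(0, 2), B = 10000, seed = 42,
                                            transform = "raw"))
})

test_that("cell table excludes under-sampled cells and reports them", {
  poly <- unit_square()
  grid <- build_grid(poly, 0.5)
  st1 <- data.frame(station_id = c("a1", "a2"), lon = c(0.2, 0.7), lat = c(0.2, 0.2))
  st2 <- data.frame(station_id = "b1", lon = 0.2, lat = 0.2)
  d1 <- survey_dataset("meso", st1,
                       abundance = matrix(c(3, 5), 2, 1, dimnames = list(st1$station_id, "A")))
  d2 <- survey_dataset("eggs", st2,
                       abundance = matrix(2, 1, 1, dimnames = list(st2$station_id, "B")))
  ct <- build_cell_table(list(d1, d2), grid, poly, pipeline_config(seed = 1, bootstrap_B = 100))
  # only c01_01 holds stations from both datasets
  expect_equal(ct$cells$cell_id, "c01_01")
  expect_true("c02_01" %in% ct$excluded$cell_id)
  # single-station values pass through exactly
  expect_equal(unname(ct$mean_raw[1, c("A", "B")]), c(3, 2))
  expect_equal(unname(ct$total_raw[1]), 5)
})

test_that("cell means respect concavity and station-order invariance on the default scenario", {
  pipe <- cached_pipeline(1)
  ct <- pipe$cells
  # concavity: mean of log1p <= log1p of mean, up to the Monte-Carlo error of
  # the two independent bootstrap streams (3 SE each, exact for n = 1)
  poly <- scenario_default()$polygon
  for (dn in names(pipe$survey$datasets)) {
    d <- pipe$survey$datasets[[dn]]
    asg <- assign_stations(d, pipe$grid, poly)
    for (cid in ct$cells$cell_id) {
      vals <- d$abundance[names(asg)[asg == cid], , drop = FALSE]
      n <- nrow(vals)
      for (tx in colnames(vals)) {
        se <- if (n < 2) 0 else {
          (sd(log1p(vals[, tx])) +
             sd(vals[, tx]) / (1 + mean(vals[, tx]))) / sqrt(n * ct$B)
        }
        expect_lte(ct$mean_log[cid, tx],
                   log1p(ct$mean_raw[cid, tx]) + 3 * se + 1e-6)
      }
    }
  }
  expect_equal(unname(ct$total_raw), unname(rowSums(ct$mean_raw)), tolerance = 1e-9)

  # shuffling a dataset's stations leaves the table identical (seeded per cell/taxon)
  sim <- pipe$survey
  ds <- sim$datasets
  d <- ds$fish_larvae
  perm <- rev(seq_len(nrow(d$stations)))
  ds$fish_larvae <- survey_dataset(d$name, d$stations[perm, ],
                                   abundance = d$abundance[perm, , drop = FALSE],
                                   units = d$units)
  cfg <- pipe$config
  ct2 <- build_cell_table(ds, pipe$grid, scenario_default()$polygon, cfg)
  expect_equal(ct2$mean_raw, ct$mean_raw)
  expect_equal(ct2$mean_log, ct$mean_log)
})

test_that("doubling B moves cell means by about one Monte-Carlo standard error", {
  pipe <- cached_pipeline(1)
  sim <- pipe$survey
  poly <- scenario_default()$polygon
  d <- sim$datasets$mesozooplankton
  asg <- assign_stations(d, pipe$grid, poly)
  cells <- intersect(unique(asg), pipe$cells$cells$cell_id)
  z <- c()
  for (cid in cells) {
    vals <- d$abundance[names(asg)[asg == cid], "Acartia_clausi"]
    n <- length(vals); s <- sd(vals)
    if (n < 2 || s == 0) next
    m1 <- bootstrap_cell_mean(vals, B = 10000, seed = 77, transform = "raw")
    m2 <- bootstrap_cell_mean(vals, B = 20000, seed = 78, transform = "raw")
    z <- c(z, abs(m1 - m2) / (s / sqrt(n * 10000)))
  }
  expect_gt(length(z), 10)
  expect_lt(median(z), 3)
  expect_lt(quantile(z, 0.9), 4.5)
})
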