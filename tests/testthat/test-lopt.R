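test_that("block-averaged structured variance matches a brute-force lattice sum", {
  m <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  v <- 50; mm <- 10
  got <- block_mean_structured_variogram(m, v, m = mm)
  # oracle: explicit double loop over the same lattice
  u <- seq(0, v, length.out = mm)
  g <- as.matrix(expand.grid(u, u))
  acc <- 0; cnt <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (i != j) {
      h <- sqrt(sum((g[i, ] - g[j, ])^2))
      acc <- acc + gamma_struct(m, h); cnt <- cnt + 1
    }
  }
  expect_equal(got, acc / cnt, tolerance = 1e-12)
  # m = 40 refinement stays within the coarse lattice's discretization error
  expect_lt(abs(got - block_mean_structured_variogram(m, v, m = 40)) / got, 0.10)
})

test_that("block averaging has the right small- and large-cell limits", {
  m <- variogram_model("spherical", nugget = 0.5, psill = 2, range = 60)
  expect_lt(block_mean_structured_variogram(m, 60 / 1e6, 10), 1e-4 * m$psill)
  expect_equal(block_mean_structured_variogram(m, 10 * 60, 10), m$psill,
               tolerance = 0.02)
})

test_that("information curve honors its limits and monotonicity", {
  m <- variogram_model("spherical", nugget = 1, psill = 1, range = 60)
  cv <- information_curve(m, station_density = 0.002, v_grid = c(5, 200, 0.5))
  # n_bar clamped at 1 => PN = 0 => f = 0
  expect_true(all(cv$f[cv$n_bar == 1] == 0))
  expect_true(all(diff(cv$PN) >= -1e-12))
  expect_true(all(diff(cv$PS) <= 1e-12))
  expect_true(all(cv$PN >= 0 & cv$PN <= 1 & cv$PS >= 0 & cv$PS <= 1))
  expect_equal(cv$f, cv$PN * cv$PS)

  # pure nugget: PS == 1, f = PN, optimum at the largest candidate
  m0 <- variogram_model("spherical", nugget = 2, psill = 0, range = 60)
  cv0 <- information_curve(m0, 0.002, c(5, 200, 0.5))
  expect_true(all(cv0$PS == 1))
  expect_equal(lopt(cv0), 200)
})

test_that("the optimum matches a 50x finer brute-force search", {
  m <- variogram_model("spherical", nugget = 1, psill = 1, range = 60)
  density <- 0.002
  cv <- information_curve(m, density, v_grid = c(5, 200, 0.5))
  v_fine <- seq(5, 200, by = 0.01)
  f_fine <- vapply(v_fine, function(v) {
    n_bar <- max(1, density * v^2)
    (1 - 1 / n_bar) * (1 - block_mean_structured_variogram(m, v, 10) / m$psill)
  }, numeric(1))
  expect_lte(abs(lopt(cv) - v_fine[which.max(f_fine)]), 0.5)
})

test_that("consensus is the median optimum with per-taxon loss bookkeeping", {
  m <- variogram_model("spherical", nugget = 1, psill = 1, range = 60)
  cv <- information_curve(m, 0.002, c(5, 200, 0.5))
  single <- consensus_lopt(list(tax = cv))
  expect_equal(single$consensus, lopt(cv))
  expect_equal(single$max_relative_f_loss, 0)

  fake_curve <- function(l) {
    structure(data.frame(v = c(l - 1, l, l + 1), f = c(0.5, 0.6, 0.5)),
              class = c("information_curve", "data.frame"),
              Lopt = l, f_at_Lopt = 0.6)
  }
  cons <- consensus_lopt(list(a = fake_curve(80), b = fake_curve(92),
                              c = fake_curve(123)))
  expect_equal(cons$consensus, 92)

  # loss oracle: direct evaluation of each taxon's own curve at the consensus
  curves <- lapply(c(30, 60, 120), function(a) {
    information_curve(variogram_model("spherical", 0.3, 1, a), 0.002,
                      c(5, 200, 0.5))
  })
  names(curves) <- paste0("t", 1:3)
  cons2 <- consensus_lopt(curves)
  loss_oracle <- max(vapply(curves, function(cvx) {
    f_at <- approx(cvx$v, cvx$f, xout = cons2$consensus, rule = 2)$y
    max(0, (attr(cvx, "f_at_Lopt") - f_at) / attr(cvx, "f_at_Lopt"))
  }, numeric(1)))
  expect_equal(cons2$max_relative_f_loss, loss_oracle, tolerance = 1e-12)
})

test_that("a longer correlation range never shrinks the optimal cell size", {
  lopts <- vapply(c(30, 60, 120), function(a) {
    lopt(information_curve(variogram_model("spherical", 0.3, 1, a), 0.0013,
                           c(5, 200, 0.5)))
  }, numeric(1))
  expect_true(all(diff(lopts) >= 0))
})

test_that("empty-cell report counts unoccupied cells per dataset", {
  poly <- unit_square()
  grid <- build_grid(poly, 0.5)
  st <- data.frame(station_id = c("a", "b", "c"),
                   lon = c(0.1, 0.2, 0.15), lat = c(0.1, 0.2, 0.3))
  d <- survey_dataset("x", st, abundance = matrix(1, 3, 1, dimnames = list(st$station_id, "T")))
  rep1 <- empty_cell_report(grid, list(d), poly)
  expect_equal(rep1$empty_cells, 3)
  expect_equal(rep1$min_stations_occupied, 3)

  d0 <- survey_dataset("y", st[0, ],
                       abundance = matrix(numeric(0), 0, 1, dimnames = list(NULL, "T")))
  rep0 <- empty_cell_report(grid, list(d0), poly)
  expect_equal(rep0$empty_cells, 4)
  expect_true(is.na(rep0$min_stations_occupied))
})
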