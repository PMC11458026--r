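# Optimal grid cell size from the variogram: block-averaged structured
# variance, the information-content curve f(v) = PN(v) * PS(v), and the
# consensus (median) cell size across taxa.
#
# Rationale: averaging n stations inside a v x v cell removes nugget
# (uncorrelated) variance in proportion PN(v) = 1 - 1/n(v), but also averages
# away spatially structured variance; the fraction retained is
# PS(v) = 1 - gamma_bar_struct(v) / c1, with gamma_bar_struct the structured
# semivariance averaged over point pairs within the cell. The optimal cell
# side Lopt maximizes the product f(v) = PN(v) * PS(v): large enough to
# suppress nugget noise, small enough to keep the spatial signal.

#' Block-averaged structured semivariance over a square cell
#'
#' Average of `gamma_struct` over all distinct ordered pairs of an m x m
#' uniform lattice spanning a v x v cell (self-pairs excluded). This is the
#' classical within-block variance approximation used in change-of-support
#' calculations.
#'
#' @param model a [variogram_model()].
#' @param v cell side length in km (> 0).
#' @param m lattice side (>= 2; default 10).
#' @return semivariance (variance units).
#' @export
block_mean_structured_variogram <- function(model, v, m = 10L) {
  .check(v > 0, "v must be positive")
  .check(.is_count(m) && m >= 2, "m must be an integer >= 2")
  u <- seq(0, 1, length.out = m)
  g <- expand.grid(x = u, y = u)
  d <- as.numeric(stats::dist(g)) * v
  mean(gamma_struct(model, d))
}

#' Information-content curve over candidate cell sizes
#'
#' For each candidate side v: expected stations per cell
#' `n(v) = max(1, density * v^2)`; proportion of nugget variance removed
#' `PN(v) = 1 - 1/n(v)`; proportion of structured (sill) variance retained
#' `PS(v) = 1 - gamma_bar_struct(v)/c1` (identically 1 for a pure-nugget
#' model); information content `f(v) = PN(v) * PS(v)`. `Lopt` is the v
#' maximizing f, ties resolved to the smallest v.
#'
#' @param model a [variogram_model()].
#' @param station_density stations per square km (> 0).
#' @param v_grid `c(v_min, v_max, step)` in km.
#' @param m block-discretization lattice side (default 10).
#' @return object of class `information_curve`: data.frame with `v`, `n_bar`,
#'   `PN`, `PS`, `f`, plus attributes `Lopt` and `f_at_Lopt`.
#' @export
information_curve <- function(model, station_density, v_grid = c(5, 200, 0.5),
                              m = 10L) {
  .check(station_density > 0, "station density must be positive")
  .check(length(v_grid) == 3 && v_grid[1] < v_grid[2] && v_grid[3] > 0,
         "v_grid must be (v_min, v_max, step)")
  v <- seq(v_grid[1], v_grid[2], by = v_grid[3])
  n_bar <- pmax(1, station_density * v^2)
  PN <- 1 - 1 / n_bar
  if (model$psill <= 0) {
    PS <- rep(1, length(v))
  } else {
    # distances scale linearly with v: evaluate on a unit lattice once
    u <- seq(0, 1, length.out = m)
    d_unit <- as.numeric(stats::dist(expand.grid(x = u, y = u)))
    PS <- vapply(v, function(vi) {
      1 - mean(gamma_struct(model, d_unit * vi)) / model$psill
    }, numeric(1))
  }
  f <- PN * PS
  i <- which.max(f)  # first maximum = smallest v on ties
  out <- data.frame(v = v, n_bar = n_bar, PN = PN, PS = PS, f = f)
  structure(out, class = c("information_curve", "data.frame"),
            Lopt = v[i], f_at_Lopt = f[i], model = model,
            station_density = station_density)
}

#' @export
print.information_curve <- function(x, ...) {
  cat(sprintf(
    "information_curve: %d cell sizes in [%g, %g] km; Lopt = %g km (f = %.4f)\n",
    nrow(x), min(x$v), max(x$v), attr(x, "Lopt"), attr(x, "f_at_Lopt")
  ))
  invisible(x)
}

#' @export
plot.information_curve <- function(x, ...) {
  graphics::plot(x$v, x$f, type = "l", lwd = 2, xlab = "cell size v (km)",
                 ylab = "f(v) = PN * PS", ylim = c(0, 1), ...)
  graphics::lines(x$v, x$PN, lty = 2, col = "steelblue")
  graphics::lines(x$v, x$PS, lty = 3, col = "darkgreen")
  graphics::abline(v = attr(x, "Lopt"), col = "firebrick")
  graphics::legend("topright", c("f", "PN", "PS"), lty = 1:3,
                   col = c("black", "steelblue", "darkgreen"), bty = "n")
  invisible(x)
}

#' Optimal cell size of an information curve
#' @param curve an `information_curve`.
#' @return Lopt in km.
#' @export
lopt <- function(curve) attr(curve, "Lopt")

#' Consensus optimal cell size across taxa
#'
#' The consensus is the median of the taxon-specific optima (mean of the
#' middle two for even counts). The reported `max_relative_f_loss` is the
#' largest relative drop, over taxa, between a taxon's own maximal
#' information content and its information content at the consensus size
#' (linear interpolation on the taxon's curve), clamped at 0 from below.
#'
#' @param curves named list of [information_curve()] objects (one per taxon).
#' @return object of class `consensus_lopt`: list with `per_taxon_lopt`,
#'   `consensus` (km), `max_relative_f_loss`.
#' @export
consensus_lopt <- function(curves) {
  .check(length(curves) >= 1, "need at least one taxon curve")
  lopts <- vapply(curves, function(cv) attr(cv, "Lopt"), numeric(1))
  consensus <- stats::median(lopts)
  losses <- vapply(curves, function(cv) {
    f_own <- attr(cv, "f_at_Lopt")
    f_cons <- stats::approx(cv$v, cv$f, xout = consensus, rule = 2)$y
    if (f_own <= 0) 0 else max(0, (f_own - f_cons) / f_own)
  }, numeric(1))
  structure(
    list(per_taxon_lopt = lopts, consensus = consensus,
         max_relative_f_loss = max(losses)),
    class = "consensus_lopt"
  )
}

#' @export
print.consensus_lopt <- function(x, ...) {
  cat(sprintf(
    "consensus_lopt: %g km (%.2f deg) from %d taxa (range %g-%g km); max relative f loss %.3f\n",
    x$consensus, km_to_degrees(x$consensus), length(x$per_taxon_lopt),
    min(x$per_taxon_lopt), max(x$per_taxon_lopt), x$max_relative_f_loss
  ))
  invisible(x)
}

#' Empty and sparsely occupied cells per dataset
#'
#' For each dataset: how many polygon-intersecting cells hold zero stations,
#' and the minimum station count among occupied cells.
#'
#' @param grid a [build_grid()] result.
#' @param datasets list of `survey_dataset` objects.
#' @param polygon the study polygon used for station filtering.
#' @return data.frame with `dataset`, `n_cells`, `empty_cells`,
#'   `min_stations_occupied`.
#' @export
empty_cell_report <- function(grid, datasets, polygon) {
  rows <- lapply(datasets, function(d) {
    asg <- assign_stations(d, grid, polygon)
    counts <- table(factor(asg, levels = grid$cells$cell_id))
    data.frame(
      dataset = d$name,
      n_cells = nrow(grid$cells),
      empty_cells = sum(counts == 0),
      min_stations_occupied = if (any(counts > 0)) min(counts[counts > 0]) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
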