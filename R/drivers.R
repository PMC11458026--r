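# Environmental driver PCAs, the mixed-model design export, and the
# inter-annual comparison arithmetic (restricted re-clustering, per-cluster
# means, cell differences, anomaly series).

#' Dissolved nitrogen to phosphate ratio
#'
#' `(no2 + no3 + nh4) / po4`; missing (NA) when po4 <= 0 or any input is
#' missing. Values near the Redfield ratio 16:1 indicate balanced nutrient
#' supply.
#'
#' @param no2,no3,nh4,po4 concentrations in umol/L (vectorized).
#' @return numeric vector (dimensionless).
#' @export
np_ratio <- function(no2, no3, nh4, po4) {
  out <- (no2 + no3 + nh4) / po4
  out[!is.finite(out) | is.na(po4) | po4 <= 0] <- NA_real_
  out
}

#' Bootstrap environmental cell table
#'
#' Aggregates per-station environmental measurements onto the grid with the
#' same seeded bootstrap used for abundances (raw-scale means), then derives
#' `nox = no3 + no2` and the N/P ratio from the cell means.
#'
#' @param env data.frame from [read_environment_csv()] (or the synthetic
#'   generator).
#' @param grid a [build_grid()] result.
#' @param polygon the study polygon.
#' @param config a [pipeline_config()].
#' @return data.frame keyed by `cell_id` with the environmental cell means,
#'   `nox`, `np_ratio` and `n_stations`.
#' @export
build_env_cell_table <- function(env, grid, polygon, config = pipeline_config()) {
  vars <- c("temperature", "salinity", "depth", "no3", "no2", "nh4", "po4",
            "sioh4", "pom", "chla")
  .check(all(vars %in% names(env)), "environment table is missing variables")
  asg <- assign_stations(list(stations = env[, c("station_id", "lon", "lat")]),
                         grid, polygon)
  cells <- unique(asg)
  rows <- lapply(cells, function(cid) {
    sub <- env[match(sort(names(asg)[asg == cid]), env$station_id), , drop = FALSE]
    means <- vapply(vars, function(v) {
      bootstrap_cell_mean(sub[[v]], B = config$bootstrap_B,
                          seed = .cell_seed(config$seed, cid, v, "raw"),
                          transform = "raw")
    }, numeric(1))
    data.frame(cell_id = cid, t(means), n_stations = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id), , drop = FALSE]
  out$nox <- out$no3 + out$no2
  out$np_ratio <- np_ratio(out$no2, out$no3, out$nh4, out$po4)
  rownames(out) <- NULL
  out
}

#' Principal component analysis with a deterministic sign convention
#'
#' Eigen-decomposition of the covariance (or correlation, when `scale =
#' TRUE`) matrix of the column-prepared input, via [stats::prcomp()]. Rows
#' with missing values are dropped and reported in the `dropped` attribute.
#' Each dimension is oriented so its largest-|loading| variable has a
#' positive loading.
#'
#' @param X cells x variables numeric matrix (rownames = cell ids).
#' @param center,scale logical column preparation flags.
#' @return object of class `drivers_pca`: `loadings` (variables x dims),
#'   `scores` (cells x dims, `Dim.1`, `Dim.2`, ...), `explained_var`
#'   (fractions), `dropped` (cell ids with missing data).
#' @export
drivers_pca <- function(X, center = TRUE, scale = TRUE) {
  X <- as.matrix(X)
  complete <- stats::complete.cases(X)
  dropped <- rownames(X)[!complete]
  X <- X[complete, , drop = FALSE]
  .check(nrow(X) > 1, "need at least 2 complete cells for a PCA")
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("zero-variance column(s) with scale = TRUE: %s",
                   paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
    }
  }
  pc <- stats::prcomp(X, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(d) {
    j <- which.max(abs(pc$rotation[, d]))
    sign(pc$rotation[j, d])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  dims <- paste0("Dim.", seq_len(ncol(scores)))
  colnames(loadings) <- dims
  colnames(scores) <- dims
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(loadings = loadings, scores = scores,
         explained_var = stats::setNames(ev, dims),
         center = center, scale = scale, dropped = dropped),
    class = "drivers_pca"
  )
}

#' @export
print.drivers_pca <- function(x, ...) {
  cat(sprintf("drivers_pca: %d cells x %d variables\n", nrow(x$scores), nrow(x$loadings)))
  ev <- utils::head(x$explained_var, 4)
  cat("explained variance:",
      paste(sprintf("%s %.1f%%", names(ev), 100 * ev), collapse = ", "), "\n")
  invisible(x)
}

#' Project a supplementary variable onto PCA dimensions
#'
#' Coordinate on each dimension = Pearson correlation between the variable
#' and that dimension's scores (the standard supplementary-variable
#' construction on a correlation circle).
#'
#' @param pca a [drivers_pca()] result.
#' @param v numeric values aligned to the PCA's retained cells.
#' @return named numeric coordinates per dimension.
#' @export
project_supplementary <- function(pca, v) {
  .check(length(v) == nrow(pca$scores),
         "supplementary variable must align with the PCA's retained cells (%d)",
         nrow(pca$scores))
  ok <- is.finite(v)
  if (stats::sd(v[ok]) == 0) {
    stop("supplementary variable has zero variance", call. = FALSE)
  }
  vapply(colnames(pca$scores), function(d) {
    stats::cor(v[ok], pca$scores[ok, d])
  }, numeric(1))
}

#' Export the mixed-model design table
#'
#' One row per cell with the abiotic PCA dimensions 1-2, biotic dimension 1,
#' their interaction products, the cluster label, and every taxon's raw cell
#' mean, ready for external mixed-model fitting (e.g. glmmTMB with a random
#' cluster intercept). The correlations between the dimensions of the two
#' PCAs are reported in the `cross_pca_correlation` attribute.
#'
#' @param cells a [build_cell_table()] result.
#' @param abiotic_pca,biotic_pca [drivers_pca()] results (rownames = cell
#'   ids).
#' @param labels named integer cluster labels per cell.
#' @return data.frame design table.
#' @export
glmm_design_export <- function(cells, abiotic_pca, biotic_pca, labels) {
  ids <- Reduce(intersect, list(cells$cells$cell_id,
                                rownames(abiotic_pca$scores),
                                rownames(biotic_pca$scores),
                                names(labels)))
  if (!length(ids)) stop("no cells shared between cell table, PCAs and labels", call. = FALSE)
  d1a <- abiotic_pca$scores[ids, "Dim.1"]
  d2a <- abiotic_pca$scores[ids, "Dim.2"]
  d1b <- biotic_pca$scores[ids, "Dim.1"]
  df <- data.frame(
    cell_id = ids,
    Dim.1abiotic = d1a, Dim.2abiotic = d2a, Dim.1biotic = d1b,
    Dim.1abiotic_x_Dim.1biotic = d1a * d1b,
    Dim.2abiotic_x_Dim.1biotic = d2a * d1b,
    cluster = as.integer(labels[ids]),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(cells$mean_raw[ids, , drop = FALSE]))
  rownames(df) <- NULL
  cross <- stats::cor(cbind(Dim.1abiotic = d1a, Dim.2abiotic = d2a),
                      cbind(Dim.1biotic = d1b))
  structure(df, cross_pca_correlation = cross)
}

#' Re-grid and re-cluster within a restricted polygon
#'
#' Reruns station assignment, the bootstrap cell table, the dominance split
#' and FANNY inside a smaller polygon (the common extent of an inter-annual
#' comparison) at the configured k. Requires `config$cell_size_deg` (the
#' grid cell size is fixed once, from the full-extent analysis).
#'
#' @param datasets list of `survey_dataset` objects.
#' @param small_polygon the restricted [study_polygon()].
#' @param config a [pipeline_config()] with `cell_size_deg` set.
#' @return list with `grid`, `cells`, `membership` (a `fanny_membership`),
#'   `labels`, `split`.
#' @export
restrict_and_recluster <- function(datasets, small_polygon, config) {
  .check(!is.null(config$cell_size_deg),
         "config$cell_size_deg must be set (fixed from the full-extent analysis)")
  grid <- build_grid(small_polygon, config$cell_size_deg)
  cells <- build_cell_table(datasets, grid, small_polygon, config)
  split <- split_dominant_secondary(cells$mean_raw, config$dominance_threshold,
                                    config$clustering_exclusion_list)
  D <- hellinger_distance(hellinger_transform(cells$mean_log[, split$clustering, drop = FALSE]))
  fm <- fanny_cluster(D, config$k, r = config$r,
                      seed = derive_seed(config$seed, "fanny-restricted"))
  list(grid = grid, cells = cells, membership = fm, labels = fm$labels,
       split = split)
}

#' Per-cluster taxon means
#'
#' Arithmetic mean of the raw-scale cell means per cluster and taxon (the
#' non-transformed grid cell mean).
#'
#' @param cells a [build_cell_table()] result.
#' @param labels named integer cluster labels covering the cells.
#' @return clusters x taxa matrix (clusters without cells reported as NA
#'   rows).
#' @export
per_cluster_means <- function(cells, labels) {
  ids <- cells$cells$cell_id
  .check(all(ids %in% names(labels)), "labels must cover every cell")
  lab <- as.integer(labels[ids])
  k <- max(lab)
  out <- matrix(NA_real_, k, ncol(cells$mean_raw),
                dimnames = list(paste0("cluster", seq_len(k)),
                                colnames(cells$mean_raw)))
  for (c0 in seq_len(k)) {
    idx <- which(lab == c0)
    if (length(idx)) out[c0, ] <- colMeans(cells$mean_raw[idx, , drop = FALSE])
  }
  out
}

#' Per-cell differences between two years
#'
#' `difference = year_b - year_a` on cells present in both tables (taxa
#' harmonized upstream); cells present in only one year are reported
#' separately, and the per-cell total difference sums over taxa.
#'
#' @param year_a,year_b `cell_table` objects on the same grid.
#' @return list with `diff` (cells x taxa), `total_diff`, `only_a`,
#'   `only_b` (cell ids).
#' @export
cell_difference <- function(year_a, year_b) {
  ga <- year_a$cells; gb <- year_b$cells
  same_grid <- isTRUE(all.equal(
    ga[match(intersect(ga$cell_id, gb$cell_id), ga$cell_id),
       c("lon_min", "lat_min")],
    gb[match(intersect(ga$cell_id, gb$cell_id), gb$cell_id),
       c("lon_min", "lat_min")],
    check.attributes = FALSE
  ))
  if (!same_grid) stop("cell tables are on different grids", call. = FALSE)
  taxa <- intersect(colnames(year_a$mean_raw), colnames(year_b$mean_raw))
  .check(length(taxa) > 0, "no shared taxa between the two years")
  shared <- intersect(ga$cell_id, gb$cell_id)
  d <- year_b$mean_raw[shared, taxa, drop = FALSE] -
    year_a$mean_raw[shared, taxa, drop = FALSE]
  list(diff = d, total_diff = rowSums(d),
       only_a = setdiff(ga$cell_id, gb$cell_id),
       only_b = setdiff(gb$cell_id, ga$cell_id))
}

#' Anomaly series of a yearly variable
#'
#' Anomaly = value minus the mean over available years; the standardized
#' companion divides by the sample standard deviation (n - 1). Missing
#' years are omitted.
#'
#' @param year integer years.
#' @param value numeric values (NA allowed).
#' @return object of class `anomaly_series`: data.frame with `year`,
#'   `value`, `long_term_mean`, `anomaly`, `standardized`.
#' @export
anomaly_series <- function(year, value) {
  ok <- !is.na(value)
  .check(sum(ok) >= 2, "need at least 2 years with values")
  year <- year[ok]; value <- value[ok]
  m <- mean(value)
  s <- stats::sd(value)
  structure(
    data.frame(year = year, value = value, long_term_mean = m,
               anomaly = value - m,
               standardized = if (s > 0) (value - m) / s else 0),
    class = c("anomaly_series", "data.frame")
  )
}

#' @export
plot.anomaly_series <- function(x, ...) {
  graphics::barplot(x$standardized, names.arg = x$year,
                    ylab = "standardized anomaly", las = 2, ...)
  graphics::abline(h = 0)
  invisible(x)
}
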