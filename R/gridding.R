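# Analysis grid construction, station assignment and seeded bootstrap cell
# means on raw and log(x+1) abundances.

#' Build a square analysis grid over the study polygon
#'
#' Axis-aligned square cells in degrees, half-open `[x, x+s) x [y, y+s)`,
#' anchored at `origin` (default: lower-left corner of the polygon bounding
#' box). Only cells intersecting the polygon with positive area are kept.
#'
#' @param polygon a [study_polygon()].
#' @param cell_size cell side in degrees (> 0).
#' @param origin optional `(lon, lat)` of the grid's lower-left corner; must
#'   be at or below/left of the polygon bounding box.
#' @return object of class `grid_spec`: list with `origin`, `cell_size`,
#'   `n_cols`, `n_rows` and a `cells` data.frame (`cell_id`, `col`, `row`,
#'   `lon_min`, `lat_min`, `lon_centroid`, `lat_centroid`).
#' @export
build_grid <- function(polygon, cell_size, origin = NULL) {
  .check(cell_size > 0, "cell_size must be positive")
  bb <- polygon_bbox(polygon)
  if (is.null(origin)) origin <- c(bb[1], bb[3])
  .check(origin[1] <= bb[1] && origin[2] <= bb[3],
         "origin must be at or below/left of the polygon bounding box")
  n_cols <- max(1L, ceiling((bb[2] - origin[1]) / cell_size - 1e-9))
  n_rows <- max(1L, ceiling((bb[4] - origin[2]) / cell_size - 1e-9))
  cells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  cells$lon_min <- origin[1] + (cells$col - 1L) * cell_size
  cells$lat_min <- origin[2] + (cells$row - 1L) * cell_size
  keep <- vapply(seq_len(nrow(cells)), function(i) {
    polygon_rect_area(polygon,
                      cells$lon_min[i], cells$lon_min[i] + cell_size,
                      cells$lat_min[i], cells$lat_min[i] + cell_size) > 1e-12
  }, logical(1))
  cells <- cells[keep, , drop = FALSE]
  if (!nrow(cells)) stop("no grid cell intersects the polygon", call. = FALSE)
  cells$cell_id <- sprintf("c%02d_%02d", cells$col, cells$row)
  cells$lon_centroid <- cells$lon_min + cell_size / 2
  cells$lat_centroid <- cells$lat_min + cell_size / 2
  rownames(cells) <- NULL
  structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         n_cols = n_cols, n_rows = n_rows,
         cells = cells[, c("cell_id", "col", "row", "lon_min", "lat_min",
                           "lon_centroid", "lat_centroid")]),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %g deg cells, %d x %d lattice, %d kept cells\n",
              x$cell_size, x$n_cols, x$n_rows, nrow(x$cells)))
  invisible(x)
}

#' Assign stations of a dataset to grid cells
#'
#' Stations outside the polygon (boundary inclusive) are dropped; the rest
#' map to the unique half-open cell containing them, so a station on a
#' shared interior edge belongs to the cell on the greater side. Stations
#' sitting exactly on the grid's outer maximum edge are folded into the last
#' cell.
#'
#' @param dataset a `survey_dataset`.
#' @param grid a [build_grid()] result.
#' @param polygon the study polygon.
#' @return named character vector mapping station id to cell id (dropped
#'   stations absent).
#' @export
assign_stations <- function(dataset, grid, polygon) {
  st <- dataset$stations
  inside <- point_in_polygon(st$lon, st$lat, polygon)
  st <- st[inside, , drop = FALSE]
  if (!nrow(st)) return(stats::setNames(character(0), character(0)))
  s <- grid$cell_size
  col <- floor((st$lon - grid$origin[1]) / s) + 1L
  row <- floor((st$lat - grid$origin[2]) / s) + 1L
  col <- pmin(col, grid$n_cols)  # fold outer max edge into the last cell
  row <- pmin(row, grid$n_rows)
  ids <- sprintf("c%02d_%02d", col, row)
  known <- ids %in% grid$cells$cell_id
  stats::setNames(ids[known], st$station_id[known])
}

#' Seeded bootstrap mean of a cell's station values
#'
#' Applies the transform elementwise (`log1p` uses the natural logarithm),
#' then averages `B` bootstrap replicates of the resample mean (resample
#' size n, with replacement). Deterministic given the seed.
#'
#' @param values station values in the cell (length >= 1).
#' @param B bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param transform `"raw"` or `"log1p"`.
#' @return the bootstrap mean (a single number).
#' @export
bootstrap_cell_mean <- function(values, B = 10000L, seed = 1L,
                                transform = c("raw", "log1p")) {
  transform <- match.arg(transform)
  n <- length(values)
  if (n == 0L) stop("empty cell: no values to aggregate", call. = FALSE)
  .check(.is_count(B), "B must be a positive integer")
  x <- if (transform == "log1p") log1p(values) else values
  if (n == 1L || stats::var(x) == 0) return(mean(x))  # resampling is a no-op
  with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    mean(colMeans(matrix(x[idx], nrow = n, ncol = B)))
  })
}

# seed for the (cell, taxon, transform) bootstrap stream: order-independent
# and reproducible under station reordering.
.cell_seed <- function(seed, cell_id, taxon, transform) {
  derive_seed(seed, cell_id, taxon, transform)
}

#' Bootstrap cell table over all datasets
#'
#' Assigns each dataset's stations to grid cells, drops cells failing any
#' dataset's `min_stations_per_cell`, and computes per-cell per-taxon
#' bootstrap means of raw and log(x+1) abundances, plus the per-cell total
#' raw abundance (sum over taxa of the raw means). Bootstrap streams are
#' keyed by (seed, cell, taxon, transform) so results do not depend on
#' station or cell order.
#'
#' @param datasets list of `survey_dataset` objects (taxon sets must be
#'   disjoint across datasets).
#' @param grid a [build_grid()] result.
#' @param polygon the study polygon.
#' @param config a [pipeline_config()] (uses `seed`, `bootstrap_B`).
#' @return object of class `cell_table`: list with `cells` (info
#'   data.frame), matrices `mean_raw`, `mean_log` (cells x taxa),
#'   `n_stations` (cells x datasets data.frame), `total_raw`, `excluded`
#'   (report of dropped cells), `B`, `seed`.
#' @export
build_cell_table <- function(datasets, grid, polygon, config = pipeline_config()) {
  taxa_by_ds <- lapply(datasets, function(d) colnames(d$abundance))
  all_taxa <- unlist(taxa_by_ds, use.names = FALSE)
  .check(!anyDuplicated(all_taxa),
         "taxon names must be disjoint across datasets")
  ids <- grid$cells$cell_id
  asg <- lapply(datasets, assign_stations, grid = grid, polygon = polygon)
  counts <- vapply(asg, function(a) {
    as.integer(table(factor(a, levels = ids)))
  }, integer(length(ids)))
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(ids, vapply(datasets, `[[`, character(1), "name")))
  mins <- vapply(datasets, function(d) {
    d$min_stations_per_cell %||% config$min_stations_per_cell
  }, integer(1))
  ok <- rowSums(sweep(counts, 2, mins, `>=`)) == length(datasets)
  excluded <- data.frame(cell_id = ids[!ok],
                         counts[!ok, , drop = FALSE], row.names = NULL)
  if (!any(ok)) stop("no grid cell satisfies the station minima", call. = FALSE)
  keep <- ids[ok]

  mean_raw <- matrix(NA_real_, length(keep), length(all_taxa),
                     dimnames = list(keep, all_taxa))
  mean_log <- mean_raw
  for (di in seq_along(datasets)) {
    d <- datasets[[di]]
    a <- asg[[di]]
    for (cid in keep) {
      sids <- sort(names(a)[a == cid])  # canonical order: station order never matters
      vals <- d$abundance[sids, , drop = FALSE]
      for (tx in colnames(vals)) {
        mean_raw[cid, tx] <- bootstrap_cell_mean(
          vals[, tx], B = config$bootstrap_B,
          seed = .cell_seed(config$seed, cid, tx, "raw"), transform = "raw")
        mean_log[cid, tx] <- bootstrap_cell_mean(
          vals[, tx], B = config$bootstrap_B,
          seed = .cell_seed(config$seed, cid, tx, "log1p"), transform = "log1p")
      }
    }
  }
  structure(
    list(cells = grid$cells[ok, , drop = FALSE],
         mean_raw = mean_raw, mean_log = mean_log,
         n_stations = as.data.frame(counts[ok, , drop = FALSE]),
         total_raw = rowSums(mean_raw),
         excluded = excluded, B = config$bootstrap_B, seed = config$seed),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells x %d taxa (B = %d, seed = %d); %d cell(s) excluded\n",
              nrow(x$mean_raw), ncol(x$mean_raw), x$B, x$seed, nrow(x$excluded)))
  invisible(x)
}

#' Write a cell table as CSV
#' @param cells a `cell_table`.
#' @param path output CSV path.
#' @export
write_cell_table_csv <- function(cells, path) {
  df <- cbind(
    cells$cells[, c("cell_id", "lon_centroid", "lat_centroid")],
    stats::setNames(cells$n_stations,
                    paste0("n_stations.", names(cells$n_stations))),
    stats::setNames(as.data.frame(cells$mean_raw),
                    paste0("mean_raw.", colnames(cells$mean_raw))),
    stats::setNames(as.data.frame(cells$mean_log),
                    paste0("mean_log.", colnames(cells$mean_log))),
    total_raw = cells$total_raw
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
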