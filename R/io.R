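# Readers/writers for the artifact formats and the pipeline configuration.

#' Read a long-format survey CSV into a survey dataset
#'
#' Expects columns `station_id`, `lon`, `lat`, `taxon`, `abundance` (extra
#' columns such as `dataset` or `date` are carried along when present). One
#' row per station x taxon; a taxon absent at a station is an observed zero,
#' not missing data.
#'
#' @param path CSV file path.
#' @param dataset_name label for the dataset (e.g. `"mesozooplankton"`).
#' @param units abundance units label, default `"ind.m-3"`.
#' @param min_stations_per_cell minimum stations required in a grid cell for
#'   this dataset (default 1).
#' @return an object of class `survey_dataset`: station table plus a dense
#'   stations x taxa abundance matrix.
#' @export
read_survey_csv <- function(path, dataset_name, units = "ind.m-3",
                            min_stations_per_cell = 1L) {
  .check(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("station_id", "lon", "lat", "taxon", "abundance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("survey CSV %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$abundance) | df$abundance < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite abundance at row %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  survey_dataset(
    name = dataset_name,
    stations = unique(df[, c("station_id", "lon", "lat")]),
    long = df[, c("station_id", "taxon", "abundance")],
    units = units,
    min_stations_per_cell = min_stations_per_cell,
    date = if ("date" %in% names(df)) df$date[!duplicated(df$station_id)] else NULL
  )
}

#' Construct a survey dataset
#'
#' @param name dataset label.
#' @param stations data.frame with `station_id`, `lon`, `lat` (one row per
#'   station).
#' @param long optional long table (`station_id`, `taxon`, `abundance`) used
#'   to fill the abundance matrix; alternatively pass `abundance` directly.
#' @param abundance optional stations x taxa matrix (rownames = station ids).
#' @param units abundance units label.
#' @param min_stations_per_cell minimum stations per grid cell.
#' @param date optional per-station dates.
#' @return object of class `survey_dataset`.
#' @export
survey_dataset <- function(name, stations, long = NULL, abundance = NULL,
                           units = "ind.m-3", min_stations_per_cell = 1L,
                           date = NULL) {
  stations$station_id <- as.character(stations$station_id)
  .check(!anyDuplicated(stations$station_id),
         "station ids must be unique within dataset '%s'", name)
  .check(all(is.finite(stations$lon)) && all(is.finite(stations$lat)),
         "station coordinates must be finite")
  .check(all(stations$lon >= -180 & stations$lon <= 180), "longitude outside [-180, 180]")
  .check(all(stations$lat >= -90 & stations$lat <= 90), "latitude outside [-90, 90]")
  if (is.null(abundance)) {
    .check(!is.null(long), "either `long` or `abundance` must be given")
    taxa <- sort(unique(as.character(long$taxon)))
    abundance <- matrix(0, nrow(stations), length(taxa),
                        dimnames = list(stations$station_id, taxa))
    ri <- match(as.character(long$station_id), stations$station_id)
    ci <- match(as.character(long$taxon), taxa)
    .check(!anyNA(ri), "long table references unknown station ids")
    abundance[cbind(ri, ci)] <- long$abundance
  } else {
    abundance <- as.matrix(abundance)
    if (is.null(rownames(abundance))) rownames(abundance) <- stations$station_id
    .check(identical(rownames(abundance) %||% character(0),
                     as.character(stations$station_id)),
           "abundance matrix rows must match station ids")
  }
  .check(all(abundance >= 0), "abundances must be non-negative")
  structure(
    list(name = name, stations = stations, abundance = abundance,
         units = units,
         min_stations_per_cell = as.integer(min_stations_per_cell),
         date = date),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset '%s': %d stations, %d taxa (%s)\n",
              x$name, nrow(x$stations), ncol(x$abundance), x$units))
  invisible(x)
}

#' Write a survey dataset to a long-format CSV
#'
#' Inverse of [read_survey_csv()]; zero abundances are written too so the
#' round trip is field-for-field.
#'
#' @param dataset a `survey_dataset`.
#' @param path output CSV path.
#' @export
write_survey_csv <- function(dataset, path) {
  st <- dataset$stations
  taxa <- colnames(dataset$abundance)
  df <- data.frame(
    dataset = dataset$name,
    station_id = rep(st$station_id, each = length(taxa)),
    lon = rep(st$lon, each = length(taxa)),
    lat = rep(st$lat, each = length(taxa)),
    taxon = rep(taxa, times = nrow(st)),
    abundance = as.vector(t(dataset$abundance)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-station environment CSV
#'
#' Required columns: `station_id`, `lon`, `lat`, `temperature`, `salinity`,
#' `depth`, `no3`, `no2`, `nh4`, `po4`, `sioh4`, `pom`, `chla`.
#'
#' @param path CSV path.
#' @return data.frame with the columns above.
#' @export
read_environment_csv <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("station_id", "lon", "lat", "temperature", "salinity", "depth",
                "no3", "no2", "nh4", "po4", "sioh4", "pom", "chla")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("environment CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$station_id <- as.character(df$station_id)
  df
}

#' Read a study polygon from WKT or GeoJSON
#'
#' Accepts a file holding either a WKT `POLYGON (...)` (single outer ring) or
#' GeoJSON containing exactly one Polygon geometry (bare geometry, Feature,
#' or a FeatureCollection with a single polygon feature). Multi-polygons,
#' inner rings and open or self-intersecting rings are rejected.
#'
#' @param path file path.
#' @return a [study_polygon()].
#' @export
read_polygon <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt_trim <- trimws(txt)
  if (startsWith(txt_trim, "{")) {
    return(.polygon_from_geojson(txt_trim))
  }
  .polygon_from_wkt(txt_trim)
}

.polygon_from_wkt <- function(txt) {
  up <- toupper(txt)
  if (grepl("MULTIPOLYGON", up)) {
    stop("expected a single polygon, got MULTIPOLYGON", call. = FALSE)
  }
  .check(grepl("^POLYGON\\s*\\(", up), "not a WKT POLYGON: %s", substr(txt, 1, 30))
  inner <- sub("^POLYGON\\s*\\(\\s*", "", txt, ignore.case = TRUE)
  inner <- sub("\\)\\s*$", "", inner)
  rings <- strsplit(inner, "\\)\\s*,\\s*\\(")[[1]]
  if (length(rings) > 1L) {
    stop("polygons with interior rings are not supported", call. = FALSE)
  }
  ring_txt <- gsub("[()]", "", rings[1])
  pairs <- strsplit(trimws(strsplit(ring_txt, ",")[[1]]), "\\s+")
  coords <- t(vapply(pairs, function(p) as.numeric(p[1:2]), numeric(2)))
  .check(all(is.finite(coords)), "could not parse WKT coordinates")
  if (!all(coords[1, ] == coords[nrow(coords), ])) {
    stop("WKT polygon ring is not closed", call. = FALSE)
  }
  study_polygon(coords)
}

.polygon_from_geojson <- function(txt) {
  g <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  geom <- switch(
    g$type %||% "",
    "Polygon" = g,
    "Feature" = g$geometry,
    "FeatureCollection" = {
      feats <- g$features
      n <- if (is.data.frame(feats)) nrow(feats) else length(feats)
      if (n != 1L) stop("GeoJSON must contain exactly one polygon feature", call. = FALSE)
      if (is.data.frame(feats)) {
        list(type = feats$geometry$type[1],
             coordinates = feats$geometry$coordinates[[1]])
      } else {
        feats[[1]]$geometry
      }
    },
    stop("unsupported GeoJSON type", call. = FALSE)
  )
  if (!identical(geom$type, "Polygon")) {
    stop(sprintf("expected a single Polygon geometry, got %s", geom$type), call. = FALSE)
  }
  coords <- geom$coordinates
  if (is.list(coords)) {
    if (length(coords) > 1L) stop("polygons with interior rings are not supported", call. = FALSE)
    ring <- coords[[1]]
  } else if (length(dim(coords)) == 3L) {
    if (dim(coords)[1] > 1L) stop("polygons with interior rings are not supported", call. = FALSE)
    ring <- coords[1, , ]
  } else {
    ring <- coords
  }
  ring <- matrix(as.numeric(ring), ncol = 2)
  if (!all(ring[1, ] == ring[nrow(ring), ])) {
    stop("GeoJSON polygon ring is not closed", call. = FALSE)
  }
  study_polygon(ring)
}

#' Write a study polygon as GeoJSON
#' @param poly a `study_polygon`.
#' @param path output path.
#' @export
write_polygon_geojson <- function(poly, path) {
  obj <- list(
    type = "Polygon",
    coordinates = list(lapply(seq_len(nrow(poly$ring)),
                              function(i) as.numeric(poly$ring[i, ])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Every tunable of the analysis as a named value with its standard default:
#' bootstrap iterations `bootstrap_B` (10000), fuzzy membership exponent `r`
#' (1.2), dominance threshold (0.5% relative abundance), indicator-value
#' cutoff (0.25), significance level `alpha` (0.05, Benjamini-Hochberg
#' adjusted), permutation count `n_perm` (999), the clustering exclusion list
#' (broad aggregate groups Copepoda, Calanoida, Crustacea nauplius), the
#' variogram family and trend order, and the cell-size search window in km.
#'
#' @param seed integer master seed consumed by every randomized stage.
#' @param bootstrap_B bootstrap iterations per cell mean.
#' @param r fuzzy membership exponent (> 1).
#' @param k number of clusters for the final run.
#' @param k_range integer candidates examined by the k-selection diagnostics.
#' @param dominance_threshold relative-abundance fraction separating dominant
#'   from secondary taxa.
#' @param indval_threshold minimum indicator value.
#' @param alpha adjusted p-value cutoff.
#' @param n_perm label permutations for IndVal significance.
#' @param clustering_exclusion_list taxa excluded from clustering (kept for
#'   IndVal).
#' @param variogram_family `"spherical"` or `"exponential"`.
#' @param trend_order polynomial trend removed before variography: 0, 1, 2 or
#'   `"auto"` (AIC choice).
#' @param lopt_search `c(v_min, v_max, step)` cell-size candidates in km.
#' @param block_m lattice side for block-averaging the variogram (default 10).
#' @param min_stations_per_cell default per-dataset minimum stations per cell.
#' @param cell_size_deg optional fixed cell size in degrees; when `NULL` the
#'   consensus optimal size is used.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed = 1L,
                            bootstrap_B = 10000L,
                            r = 1.2,
                            k = 5L,
                            k_range = 2:8,
                            dominance_threshold = 0.005,
                            indval_threshold = 0.25,
                            alpha = 0.05,
                            n_perm = 999L,
                            clustering_exclusion_list = c("Copepoda", "Calanoida", "Crustacea_nauplius"),
                            variogram_family = c("spherical", "exponential"),
                            trend_order = "auto",
                            lopt_search = c(5, 200, 0.5),
                            block_m = 10L,
                            min_stations_per_cell = 1L,
                            cell_size_deg = NULL) {
  variogram_family <- match.arg(variogram_family)
  .check(.is_count(bootstrap_B), "bootstrap_B must be a positive integer")
  .check(r > 1, "membership exponent r must exceed 1")
  .check(dominance_threshold > 0 && dominance_threshold < 1,
         "dominance_threshold must be in (0, 1)")
  .check(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  .check(.is_count(n_perm), "n_perm must be a positive integer")
  .check(length(lopt_search) == 3 && lopt_search[1] < lopt_search[2] && lopt_search[3] > 0,
         "lopt_search must be (v_min, v_max, step) with v_min < v_max, step > 0")
  .check(.is_count(block_m) && block_m >= 2, "block_m must be an integer >= 2")
  .check(identical(trend_order, "auto") || trend_order %in% 0:2,
         "trend_order must be 0, 1, 2 or 'auto'")
  structure(
    list(seed = as.integer(seed), bootstrap_B = as.integer(bootstrap_B), r = r,
         k = as.integer(k), k_range = as.integer(k_range),
         dominance_threshold = dominance_threshold,
         indval_threshold = indval_threshold, alpha = alpha,
         n_perm = as.integer(n_perm),
         clustering_exclusion_list = clustering_exclusion_list,
         variogram_family = variogram_family, trend_order = trend_order,
         lopt_search = lopt_search, block_m = as.integer(block_m),
         min_stations_per_cell = as.integer(min_stations_per_cell),
         cell_size_deg = cell_size_deg),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  cat(sprintf("  seed %d, bootstrap_B %d, r %.2f, k %d (range %s)\n",
              x$seed, x$bootstrap_B, x$r, x$k,
              paste(range(x$k_range), collapse = "-")))
  cat(sprintf("  dominance %.3f, indval > %.2f, alpha %.2f (BH), n_perm %d\n",
              x$dominance_threshold, x$indval_threshold, x$alpha, x$n_perm))
  cat(sprintf("  variogram %s, trend %s, cell-size search [%g, %g] km step %g\n",
              x$variogram_family, as.character(x$trend_order),
              x$lopt_search[1], x$lopt_search[2], x$lopt_search[3]))
  invisible(x)
}

#' Write grid cells, station counts and cluster labels as GeoJSON
#'
#' One polygon feature per kept grid cell with properties `cell_id`,
#' per-dataset station counts, `cluster` and `max_membership`.
#'
#' @param grid a [build_grid()] result.
#' @param cells a [build_cell_table()] result (or `NULL` for geometry only).
#' @param labels optional named cluster labels (names = cell ids), e.g. from
#'   [max_membership_map()].
#' @param path output path.
#' @param max_membership optional named numeric of per-cell maxima.
#' @export
write_grid_geojson <- function(grid, cells = NULL, labels = NULL, path,
                               max_membership = NULL) {
  ids <- grid$cells$cell_id
  if (!is.null(labels)) {
    unknown <- setdiff(names(labels), ids)
    if (length(unknown)) {
      stop(sprintf("labels refer to unknown cell(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  use <- if (is.null(cells)) ids else cells$cells$cell_id
  feats <- lapply(use, function(id) {
    i <- match(id, ids)
    x0 <- grid$cells$lon_min[i]; y0 <- grid$cells$lat_min[i]
    s <- grid$cell_size
    ring <- list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s), c(x0, y0))
    props <- list(cell_id = id)
    if (!is.null(cells)) {
      ns <- cells$n_stations[match(id, cells$cells$cell_id), , drop = TRUE]
      for (d in names(ns)) props[[paste0("n_stations.", d)]] <- as.integer(ns[[d]])
    }
    props$cluster <- if (!is.null(labels) && id %in% names(labels)) {
      as.integer(labels[[id]])
    } else {
      NA
    }
    props$max_membership <- if (!is.null(max_membership) && id %in% names(max_membership)) {
      as.numeric(max_membership[[id]])
    } else {
      NA
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read back a grid GeoJSON written by [write_grid_geojson()]
#'
#' @param path GeoJSON path.
#' @return data.frame of feature properties (`cell_id`, `cluster`,
#'   `max_membership`, station-count columns) with the cell corner
#'   coordinates.
#' @export
read_grid_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check(identical(g$type, "FeatureCollection"), "not a FeatureCollection")
  if (!length(g$features)) {
    return(data.frame(cell_id = character(0), cluster = integer(0)))
  }
  rows <- lapply(g$features, function(f) {
    p <- f$properties
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(v) as.numeric(v[[1]]), numeric(1))
    ys <- vapply(ring, function(v) as.numeric(v[[2]]), numeric(1))
    out <- c(list(cell_id = p$cell_id,
                  lon_min = min(xs), lat_min = min(ys),
                  cluster = if (is.null(p$cluster)) NA_integer_ else as.integer(p$cluster),
                  max_membership = if (is.null(p$max_membership)) NA_real_ else as.numeric(p$max_membership)),
             p[grepl("^n_stations\\.", names(p))])
    out
  })
  nm <- names(rows[[1]])
  df <- as.data.frame(lapply(nm, function(k) unlist(lapply(rows, `[[`, k))),
                      stringsAsFactors = FALSE)
  names(df) <- nm
  df
}
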