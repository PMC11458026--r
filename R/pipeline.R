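# End-to-end pipeline on a synthetic scenario or on read-in surveys:
# variography -> optimal cell size -> grid -> bootstrap cell table ->
# dominance split -> Hellinger FANNY -> indicator analysis -> driver PCAs ->
# mixed-model design export.

# station-level dominance filter used before a grid exists: a taxon's share
# of the summed per-dataset mean station abundances (mean, not sum, so the
# denser survey does not dominate by station count alone)
.station_dominance <- function(datasets, threshold) {
  means <- unlist(unname(lapply(datasets, function(d) colMeans(d$abundance))))
  rel <- means / sum(means)
  names(rel)[rel > threshold]
}

#' Run the full assemblage pipeline
#'
#' Simulates (or takes) the surveys, fits per-taxon variograms on detrended
#' log(x+1) station abundances, derives taxon-specific and consensus optimal
#' grid cell sizes, builds the analysis grid and bootstrap cell table,
#' splits dominant/secondary taxa, clusters Hellinger-transformed log-scale
#' cell means with FANNY, computes the k-selection diagnostics and the
#' indicator table, and assembles the driver PCAs and mixed-model design.
#'
#' @param scenario a `synthetic_scenario`; used when `datasets` is NULL.
#' @param config a [pipeline_config()].
#' @param datasets optional named list of `survey_dataset` objects (skips
#'   simulation).
#' @param environment optional per-station environment data.frame.
#' @param polygon optional study polygon (defaults to the scenario's).
#' @param k_selection compute the k-selection diagnostics table (default
#'   TRUE).
#' @return object of class `plankgrid_pipeline`: list with `survey`,
#'   `variograms`, `curves`, `consensus`, `cell_size_deg`, `grid`, `cells`,
#'   `split`, `distance`, `k_table`, `membership`, `labels`, `indicators`,
#'   `abiotic_pca`, `biotic_pca`, `np_supplementary`, `glmm_design`,
#'   `empty_cells`, `config`.
#' @export
run_pipeline <- function(scenario = scenario_default(),
                         config = pipeline_config(),
                         datasets = NULL, environment = NULL, polygon = NULL,
                         k_selection = TRUE) {
  survey <- NULL
  if (is.null(datasets)) {
    survey <- simulate_survey(scenario, seed = config$seed)
    datasets <- survey$datasets
    environment <- survey$environment
    polygon <- scenario$polygon
  }
  .check(!is.null(polygon), "a study polygon is required")
  bb <- polygon_bbox(polygon)
  ref <- c(mean(bb[1:2]), mean(bb[3:4]))
  area_km2 <- polygon_area(polygon) *
    .KM_PER_DEG_LON * cos(ref[2] * pi / 180) * .KM_PER_DEG_LAT

  # --- variography on dominant taxa, taxon-specific optimal cell sizes ----
  vg_taxa <- .station_dominance(datasets, config$dominance_threshold)
  variograms <- list()
  curves <- list()
  for (d in datasets) {
    inside <- point_in_polygon(d$stations$lon, d$stations$lat, polygon)
    km <- project_km(d$stations$lon[inside], d$stations$lat[inside], ref)
    density <- sum(inside) / area_km2
    for (tx in intersect(colnames(d$abundance), vg_taxa)) {
      z <- log1p(d$abundance[inside, tx])
      dt <- if (identical(config$trend_order, "auto")) {
        detrend_auto(km, z)
      } else {
        detrend(km, z, config$trend_order)
      }
      emp <- empirical_variogram(km, dt$residuals, trend_order = dt$order)
      vm <- tryCatch(fit_variogram(emp, config$variogram_family),
                     error = function(e) NULL)
      if (is.null(vm) || vm$psill <= 1e-8) next  # pure nugget: no spatial optimum
      variograms[[tx]] <- vm
      curves[[tx]] <- information_curve(vm, density, config$lopt_search,
                                        m = config$block_m)
    }
  }
  .check(length(curves) > 0, "no taxon yielded a usable variogram")
  consensus <- consensus_lopt(curves)
  cell_size_deg <- config$cell_size_deg %||% km_to_degrees(consensus$consensus)

  # --- grid, bootstrap cell table ----------------------------------------
  grid <- build_grid(polygon, cell_size_deg)
  empty_cells <- empty_cell_report(grid, datasets, polygon)
  cells <- build_cell_table(datasets, grid, polygon, config)

  # --- assemblages --------------------------------------------------------
  split <- split_dominant_secondary(cells$mean_raw, config$dominance_threshold,
                                    config$clustering_exclusion_list)
  .check(length(split$clustering) >= 2, "fewer than 2 taxa in the clustering set")
  Y <- hellinger_transform(cells$mean_log[, split$clustering, drop = FALSE])
  D <- hellinger_distance(Y)
  k_table <- if (k_selection) {
    select_k_table(D, config$k_range, r = config$r,
                   seed = derive_seed(config$seed, "k-selection"))
  } else {
    NULL
  }
  fm <- fanny_cluster(D, config$k, r = config$r,
                      seed = derive_seed(config$seed, "fanny"))

  # --- indicators (all taxa: dominant, secondary and excluded aggregates) -
  ind <- indicator_table(cells$mean_raw, fm$labels,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "indval"),
                         iv_threshold = config$indval_threshold,
                         alpha = config$alpha)

  # --- drivers ------------------------------------------------------------
  abiotic_pca <- NULL; biotic_pca <- NULL; np_sup <- NULL; design <- NULL
  env_cells <- NULL
  if (!is.null(environment)) {
    env_cells <- build_env_cell_table(environment, grid, polygon, config)
    abio_vars <- c("temperature", "salinity", "depth", "nox", "nh4", "po4",
                   "sioh4", "pom", "chla")
    Xa <- log1p(as.matrix(env_cells[, abio_vars]))
    rownames(Xa) <- env_cells$cell_id
    abiotic_pca <- drivers_pca(Xa, center = TRUE, scale = TRUE)
    np <- stats::setNames(env_cells$np_ratio, env_cells$cell_id)
    np_sup <- tryCatch(
      project_supplementary(abiotic_pca, np[rownames(abiotic_pca$scores)]),
      error = function(e) NULL
    )
    Xb <- hellinger_transform(cells$mean_raw[, split$clustering, drop = FALSE])
    biotic_pca <- drivers_pca(Xb, center = TRUE, scale = FALSE)
    design <- tryCatch(
      glmm_design_export(cells, abiotic_pca, biotic_pca, fm$labels),
      error = function(e) NULL
    )
  }

  structure(
    list(survey = survey, variograms = variograms, curves = curves,
         consensus = consensus, cell_size_deg = cell_size_deg, grid = grid,
         cells = cells, split = split, distance = D, k_table = k_table,
         membership = fm, labels = fm$labels, indicators = ind,
         env_cells = env_cells, abiotic_pca = abiotic_pca,
         biotic_pca = biotic_pca, np_supplementary = np_sup,
         glmm_design = design, empty_cells = empty_cells, config = config),
    class = "plankgrid_pipeline"
  )
}

#' @export
print.plankgrid_pipeline <- function(x, ...) {
  cat("plankgrid pipeline run\n")
  print(x$consensus)
  print(x$grid)
  print(x$cells)
  cat(sprintf("clustering set: %d taxa (dominant %d, secondary %d, excluded %d)\n",
              length(x$split$clustering), length(x$split$dominant),
              length(x$split$secondary),
              length(setdiff(x$split$dominant, x$split$clustering))))
  print(x$membership)
  cat(sprintf("indicator taxa: %d\n", sum(x$indicators$is_indicator)))
  invisible(x)
}

#' Write the pipeline's primary outputs
#'
#' Cell table, membership matrix, crisp labels, k-selection table, indicator
#' table, information curves, consensus summary, PCA loadings/scores and the
#' mixed-model design as CSV, plus the labelled grid as GeoJSON. Two runs
#' with equal config and inputs produce byte-identical files.
#'
#' @param pipe a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_pipeline_outputs <- function(pipe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  write_cell_table_csv(pipe$cells, file.path(dir, "cell_table.csv"))
  paths <- c(paths, file.path(dir, "cell_table.csv"))
  w(data.frame(cell_id = rownames(pipe$membership$U), pipe$membership$U,
               check.names = FALSE), "memberships.csv")
  w(data.frame(cell_id = names(pipe$labels), cluster = as.integer(pipe$labels),
               max_membership = as.numeric(pipe$membership$max_membership)),
    "labels.csv")
  if (!is.null(pipe$k_table)) w(as.data.frame(pipe$k_table), "k_selection.csv")
  w(as.data.frame(pipe$indicators), "indicators.csv")
  w(data.frame(taxon = names(pipe$consensus$per_taxon_lopt),
               lopt_km = as.numeric(pipe$consensus$per_taxon_lopt)),
    "taxon_lopt.csv")
  curves <- do.call(rbind, lapply(names(pipe$curves), function(tx) {
    cbind(taxon = tx, as.data.frame(pipe$curves[[tx]]))
  }))
  w(curves, "information_curves.csv")
  if (!is.null(pipe$abiotic_pca)) {
    w(data.frame(variable = rownames(pipe$abiotic_pca$loadings),
                 pipe$abiotic_pca$loadings, check.names = FALSE),
      "abiotic_pca_loadings.csv")
    w(data.frame(cell_id = rownames(pipe$abiotic_pca$scores),
                 pipe$abiotic_pca$scores, check.names = FALSE),
      "abiotic_pca_scores.csv")
  }
  if (!is.null(pipe$glmm_design)) w(pipe$glmm_design, "glmm_design.csv")
  gj <- file.path(dir, "grid.geojson")
  write_grid_geojson(pipe$grid, pipe$cells, pipe$labels, gj,
                     max_membership = pipe$membership$max_membership)
  paths <- c(paths, gj)
  js <- file.path(dir, "consensus.json")
  jsonlite::write_json(
    list(consensus_lopt_km = pipe$consensus$consensus,
         cell_size_deg = pipe$cell_size_deg,
         max_relative_f_loss = pipe$consensus$max_relative_f_loss,
         n_cells = nrow(pipe$cells$mean_raw),
         k = pipe$config$k, seed = pipe$config$seed),
    js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, js)
  invisible(paths)
}
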