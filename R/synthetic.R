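# Synthetic winter plankton surveys with known spatial structure.
#
# Ground truth for every pipeline stage: K contiguous assemblage regions
# (Voronoi cells of seeded points), log-normal taxon abundances with a
# spatially autocorrelated Gaussian field and nugget noise, planted
# indicator taxa that are hard zeros outside their region, aggregate taxa
# (sums of members, mirroring broad groups like Copepoda), and environmental
# covariates tied to the regions.

#' Simulate a Gaussian random field at point locations
#'
#' Draws from a zero-mean Gaussian process whose covariance is derived from
#' a variogram model: `C(h) = c1 - gamma_struct(h)` off the diagonal and
#' `c0 + c1` on the diagonal (nugget = spatially uncorrelated component).
#' Cholesky factorization with escalating diagonal jitter on numerical
#' failure.
#'
#' @param points data.frame/matrix with planar km columns x, y (n <= 2000).
#' @param model a [variogram_model()].
#' @param seed integer seed; the draw is deterministic given it.
#' @return numeric vector of field values, one per point.
#' @export
simulate_grf <- function(points, model, seed = 1L) {
  points <- as.data.frame(points)
  n <- nrow(points)
  .check(n >= 1 && n <= 2000, "simulate_grf supports 1..2000 points (got %d)", n)
  sill <- model$nugget + model$psill
  if (sill == 0) return(numeric(n))
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  C <- model$psill - matrix(gamma_struct(model, D), n, n)
  diag(C) <- sill
  L <- NULL
  for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(chol(C + diag(jit * sill, n)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) {
    stop("covariance matrix is numerically non-positive-definite even after jitter",
         call. = FALSE)
  }
  with_seed(seed, as.numeric(t(L) %*% stats::rnorm(n)))
}

#' Reference synthetic scenario
#'
#' Five contiguous assemblage regions (Voronoi cells of fixed seed points in
#' a 4 x 3 degree shelf-sea polygon), 20 taxa (17 base + 3 aggregate groups
#' Copepoda, Calanoida, Crustacea nauplius), five planted indicator taxa
#' (one per region, hard zero elsewhere), a rank-abundance ladder spanning
#' four orders of magnitude so several taxa fall below the 0.5% dominance
#' threshold, a shared spherical variogram (nugget 0.3, partial sill 1.0,
#' range 60 km) on the log scale, and three surveys of differing coverage:
#' mesozooplankton (140 stations, scattered), fish larvae (130, scattered)
#' and fish eggs (860, dense parallel transects, CUFES-like).
#'
#' @param seed scenario seed (default 20080127).
#' @return object of class `synthetic_scenario`.
#' @export
scenario_default <- function(seed = 20080127L) {
  poly <- study_polygon(cbind(c(-5, -1, -1, -5), c(45, 45, 48, 48)))
  region_seeds <- cbind(
    lon = c(-4.3, -1.9, -3.0, -4.4, -1.8),
    lat = c(45.6, 45.7, 46.5, 47.5, 47.4)
  )
  base <- data.frame(
    name = c("Acartia_clausi", "Temora_longicornis", "Calanus_helgolandicus",
             "Pseudocalanus_elongatus", "Oithona_similis", "Euterpina_acutifrons",
             "Appendicularia", "Chaetognatha", "Evadne_nordmanni", "Podon_spp",
             "Echinodermata_larvae", "Cirripedia_nauplii",
             "Clupea_harengus_larvae", "Sprattus_sprattus_larvae",
             "Merlangius_merlangus_larvae",
             "Sardina_pilchardus_eggs", "Engraulis_encrasicolus_eggs"),
    dataset = c(rep("mesozooplankton", 12), rep("fish_larvae", 3), rep("fish_eggs", 2)),
    mu0 = c(7.6, 7.0, 6.3, 5.9, 6.6, 4.8, 5.2, 4.2, NA, 3.6, 0.2, -1.7,
            NA, 3.0, NA, NA, NA),
    pref_region = c(1, 2, 3, 4, 5, 1, 2, 3, NA, 5, 2, 3, NA, 4, NA, NA, NA),
    indicator_region = c(NA, NA, NA, NA, NA, NA, NA, NA, 4, NA, NA, NA,
                         1, NA, 5, 2, 3),
    mu_indicator = c(NA, NA, NA, NA, NA, NA, NA, NA, 7.8, NA, NA, NA,
                     7.6, NA, 7.4, 8.0, 7.8),
    sigma = 1,
    p0 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.1, 0.3, 0.3, 0, 0.2, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  K <- nrow(region_seeds)
  pref_boost <- 1.5
  mu <- matrix(-Inf, nrow(base), K, dimnames = list(base$name, NULL))
  for (i in seq_len(nrow(base))) {
    if (is.na(base$indicator_region[i])) {
      mu[i, ] <- base$mu0[i]
      mu[i, base$pref_region[i]] <- base$mu0[i] + pref_boost
    } else {
      mu[i, base$indicator_region[i]] <- base$mu_indicator[i]
    }
  }
  aggregates <- list(
    Copepoda = c("Acartia_clausi", "Temora_longicornis", "Calanus_helgolandicus",
                 "Pseudocalanus_elongatus", "Oithona_similis", "Euterpina_acutifrons"),
    Calanoida = c("Acartia_clausi", "Temora_longicornis", "Calanus_helgolandicus",
                  "Pseudocalanus_elongatus"),
    Crustacea_nauplius = "Cirripedia_nauplii"
  )
  datasets <- list(
    list(name = "mesozooplankton", n_stations = 140L, layout = "scatter"),
    list(name = "fish_larvae", n_stations = 130L, layout = "scatter"),
    list(name = "fish_eggs", n_stations = 860L, layout = "transect")
  )
  # per-region environmental means (units: degC, psu, m, umol/L, mg/L, ug/L)
  env_means <- rbind(
    temperature = c(12.6, 12.2, 11.6, 10.6, 10.9),
    salinity    = c(35.2, 34.6, 35.0, 34.2, 33.8),
    depth       = c(110, 45, 80, 130, 55),
    no3         = c(2.5, 6.0, 4.0, 8.0, 7.0),
    no2         = c(0.15, 0.40, 0.25, 0.45, 0.35),
    nh4         = c(0.30, 0.90, 0.55, 0.70, 1.10),
    po4         = c(0.25, 0.55, 0.40, 0.60, 0.50),
    sioh4       = c(1.5, 5.0, 3.0, 6.5, 5.5),
    pom         = c(0.6, 1.6, 1.0, 1.2, 2.0),
    chla        = c(0.5, 2.4, 1.2, 0.9, 2.8)
  )
  env_field_coef <- c(temperature = 0.5, salinity = 0.25, depth = 12,
                      no3 = 1.2, no2 = 0.08, nh4 = 0.2, po4 = 0.08,
                      sioh4 = 1.0, pom = 0.25, chla = 0.5)
  env_noise_sd <- c(temperature = 0.25, salinity = 0.12, depth = 6,
                    no3 = 0.6, no2 = 0.04, nh4 = 0.1, po4 = 0.04,
                    sioh4 = 0.5, pom = 0.12, chla = 0.25)
  structure(
    list(polygon = poly, K = K, region_seeds = region_seeds,
         taxa = base, mu = mu, aggregates = aggregates, datasets = datasets,
         variogram = variogram_model("spherical", nugget = 0.3, psill = 1.0,
                                     range = 60),
         env_means = env_means, env_field_coef = env_field_coef,
         env_noise_sd = env_noise_sd, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: %d regions, %d base + %d aggregate taxa, %d planted indicators\n",
    x$K, nrow(x$taxa), length(x$aggregates), sum(!is.na(x$taxa$indicator_region))
  ))
  for (d in x$datasets) {
    cat(sprintf("  dataset %-16s %4d stations (%s)\n", d$name, d$n_stations, d$layout))
  }
  invisible(x)
}

#' True assemblage region of point locations
#'
#' Nearest region seed in projected km (Voronoi partition of the polygon).
#'
#' @param lon,lat coordinates.
#' @param scenario a `synthetic_scenario`.
#' @return integer region labels in 1..K.
#' @export
true_regions <- function(lon, lat, scenario) {
  bb <- polygon_bbox(scenario$polygon)
  ref <- c(mean(bb[1:2]), mean(bb[3:4]))
  p <- project_km(lon, lat, ref)
  s <- project_km(scenario$region_seeds[, 1], scenario$region_seeds[, 2], ref)
  d2 <- outer(p$x, s$x, `-`)^2 + outer(p$y, s$y, `-`)^2
  max.col(-d2, ties.method = "first")
}

# exactly n points inside the polygon; scatter = uniform, transect = dense
# jittered parallel north-south tracks (CUFES-like underway sampling)
.place_stations <- function(polygon, n, layout, seed) {
  bb <- polygon_bbox(polygon)
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    if (layout == "transect") {
      n_tracks <- max(10L, ceiling(sqrt(n) / 1.5))
      track_lon <- seq(bb[1] + 0.05, bb[2] - 0.05, length.out = n_tracks)
    }
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 50L)
      if (layout == "scatter") {
        cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
      } else {
        cand <- cbind(sample(track_lon, m, replace = TRUE) + stats::rnorm(m, 0, 0.015),
                      stats::runif(m, bb[3], bb[4]))
      }
      keep <- point_in_polygon(cand[, 1], cand[, 2], polygon)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts[seq_len(n), , drop = FALSE]
  })
}

#' Simulate the surveys of a scenario
#'
#' Station abundance of base taxon t at station s is
#' `Bernoulli(1 - p0_t) * exp(mu_{t, region(s)} + sigma_t * Z_t(s))` with
#' `Z_t` the taxon's Gaussian random field under the scenario variogram;
#' planted indicators have `mu = -Inf` (hard zero) outside their region;
#' aggregate taxa are sums of their members. Environmental covariates are
#' region-linked means plus a shared random field plus independent noise,
#' sampled at the mesozooplankton stations. Everything is a pure function of
#' (scenario, seed).
#'
#' @param scenario a [scenario_default()]-style scenario.
#' @param seed optional override of `scenario$seed`.
#' @return object of class `synthetic_survey`: list with `datasets` (named
#'   list of `survey_dataset`), `environment` (data.frame), `truth` (region
#'   labels per station, region seeds, planted indicators, true variogram,
#'   environment coefficients), and the `scenario`.
#' @export
simulate_survey <- function(scenario, seed = NULL) {
  seed <- as.integer(seed %||% scenario$seed)
  bb <- polygon_bbox(scenario$polygon)
  ref <- c(mean(bb[1:2]), mean(bb[3:4]))
  base <- scenario$taxa
  out_ds <- list()
  truth_regions <- list()
  for (d in scenario$datasets) {
    pts <- .place_stations(scenario$polygon, d$n_stations, d$layout,
                           derive_seed(seed, "stations", d$name))
    region <- true_regions(pts[, 1], pts[, 2], scenario)
    km <- project_km(pts[, 1], pts[, 2], ref)
    tx <- base[base$dataset == d$name, , drop = FALSE]
    abund <- matrix(0, nrow(pts), nrow(tx),
                    dimnames = list(NULL, tx$name))
    for (i in seq_len(nrow(tx))) {
      nm <- tx$name[i]
      z <- simulate_grf(km, scenario$variogram,
                        seed = derive_seed(seed, "field", nm))
      mu_s <- scenario$mu[nm, region]
      a <- exp(mu_s + tx$sigma[i] * z)
      if (tx$p0[i] > 0) {
        pres <- with_seed(derive_seed(seed, "zero", nm),
                          stats::rbinom(nrow(pts), 1, 1 - tx$p0[i]))
        a <- a * pres
      }
      abund[, i] <- a
    }
    # aggregate groups are sums of member taxa of the same dataset
    for (ag in names(scenario$aggregates)) {
      members <- intersect(scenario$aggregates[[ag]], colnames(abund))
      if (length(members) == length(scenario$aggregates[[ag]])) {
        abund <- cbind(abund, rowSums(abund[, members, drop = FALSE]))
        colnames(abund)[ncol(abund)] <- ag
      }
    }
    ids <- sprintf("%s_%03d", abbreviate(d$name, 4), seq_len(nrow(pts)))
    stations <- data.frame(station_id = ids, lon = pts[, 1], lat = pts[, 2],
                           stringsAsFactors = FALSE)
    out_ds[[d$name]] <- survey_dataset(
      name = d$name, stations = stations, abundance = abund,
      units = if (d$name == "fish_eggs") "eggs.m-3" else "ind.m-3"
    )
    truth_regions[[d$name]] <- stats::setNames(region, ids)
  }

  env_st <- out_ds[[1]]$stations
  env_region <- truth_regions[[1]]
  km <- project_km(env_st$lon, env_st$lat, ref)
  W <- simulate_grf(km, scenario$variogram, seed = derive_seed(seed, "env_field"))
  env <- data.frame(station_id = env_st$station_id,
                    lon = env_st$lon, lat = env_st$lat)
  for (v in rownames(scenario$env_means)) {
    eps <- with_seed(derive_seed(seed, "env_noise", v),
                     stats::rnorm(nrow(env_st), 0, scenario$env_noise_sd[[v]]))
    env[[v]] <- pmax(0.01, scenario$env_means[v, env_region] +
                       scenario$env_field_coef[[v]] * W + eps)
  }

  planted <- base$name[!is.na(base$indicator_region)]
  structure(
    list(datasets = out_ds, environment = env,
         truth = list(regions = truth_regions, region_seeds = scenario$region_seeds,
                      planted_indicators = stats::setNames(
                        base$indicator_region[!is.na(base$indicator_region)], planted),
                      variogram = scenario$variogram,
                      env_means = scenario$env_means,
                      env_field_coef = scenario$env_field_coef),
         scenario = scenario, seed = seed),
    class = "synthetic_survey"
  )
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("synthetic_survey (seed %d):\n", x$seed))
  for (d in x$datasets) print(d)
  invisible(x)
}
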