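# Shared fixtures. Heavy objects (full pipeline runs) are cached per seed so
# several test files can reuse one computation.

.pg_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(seed, ...) {
  key <- sprintf("pipe_%d", seed)
  if (is.null(.pg_cache[[key]])) {
    .pg_cache[[key]] <- run_pipeline(scenario_default(),
                                     pipeline_config(seed = seed),
                                     k_selection = TRUE)
  }
  .pg_cache[[key]]
}

cached_survey <- function(seed) {
  key <- sprintf("survey_%d", seed)
  if (is.null(.pg_cache[[key]])) {
    .pg_cache[[key]] <- simulate_survey(scenario_default(), seed = seed)
  }
  .pg_cache[[key]]
}

unit_square <- function() study_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

# block-structured distance matrix: `sizes` cells per block, small within-
# block and large between-block distances
block_distance <- function(sizes, within = 0.1, between = 10) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(between, n, n)
  for (b in seq_along(sizes)) D[lab == b, lab == b] <- within
  diag(D) <- 0
  rownames(D) <- colnames(D) <- sprintf("cell%02d", seq_len(n))
  D
}

# tiny one-region noiseless scenario for exact-value checks
tiny_scenario <- function(mu = 2, sigma = 0, p0 = 0, n = 15L) {
  sc <- scenario_default()
  sc$region_seeds <- sc$region_seeds[1, , drop = FALSE]
  sc$K <- 1L
  sc$taxa <- data.frame(
    name = "Taxon_A", dataset = "mesozooplankton", mu0 = mu,
    pref_region = 1, indicator_region = NA, mu_indicator = NA,
    sigma = sigma, p0 = p0, stringsAsFactors = FALSE
  )
  sc$mu <- matrix(mu, 1, 1, dimnames = list("Taxon_A", NULL))
  sc$aggregates <- list()
  sc$datasets <- list(list(name = "mesozooplankton", n_stations = n,
                           layout = "scatter"))
  sc
}

# station-majority region per kept cell (composition-based ground truth)
cell_majority_regions <- function(pipe, scenario = scenario_default()) {
  ids <- pipe$cells$cells$cell_id
  votes <- matrix(0, length(ids), scenario$K, dimnames = list(ids, NULL))
  for (dn in names(pipe$survey$datasets)) {
    d <- pipe$survey$datasets[[dn]]
    asg <- assign_stations(d, pipe$grid, scenario$polygon)
    reg <- pipe$survey$truth$regions[[dn]][names(asg)]
    for (i in seq_along(asg)) {
      if (asg[i] %in% ids) votes[asg[i], reg[i]] <- votes[asg[i], reg[i]] + 1
    }
  }
  list(label = max.col(votes, ties.method = "first"),
       purity = votes[cbind(seq_len(nrow(votes)), max.col(votes))] / rowSums(votes))
}

planted_names <- c("Evadne_nordmanni", "Clupea_harengus_larvae",
                   "Merlangius_merlangus_larvae", "Sardina_pilchardus_eggs",
                   "Engraulis_encrasicolus_eggs")
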