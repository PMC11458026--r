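# plankgrid

Defining winter zooplankton and ichthyoplankton assemblages from
heterogeneous point surveys.

Shelf-sea plankton is sampled by gears with very different footprints: a few
dozen net hauls for mesozooplankton and fish larvae, hundreds of underway
pump samples for fish eggs. Comparing such surveys, and clustering them into
assemblages, first requires projecting everything onto a common spatial
grid whose cell size is neither so small that cells hold one noisy sample
nor so large that real spatial structure is averaged away. `plankgrid`
implements that whole chain for R users working on spatial community
ecology:

1. **Optimal grid cell size.** Per taxon, a semivariogram
   `γ(h) = c0 + γ_struct(h)` (nugget `c0`, partial sill `c1`, range `a`) is
   fitted to detrended log(x+1) station abundances by Cressie-weighted least
   squares. Averaging the `n(v)` stations inside a `v × v` cell removes
   nugget variance in proportion `PN(v) = 1 − 1/n(v)` while retaining the
   fraction `PS(v) = 1 − γ̄_struct(v)/c1` of the spatially structured
   variance (`γ̄_struct` is the block-averaged variogram). The information
   content `f(v) = PN(v)·PS(v)` has an interior maximum `Lopt`; the
   consensus cell size is the median of the taxon-specific optima.
2. **Bootstrap gridding.** Station abundances are aggregated to per-cell
   means of raw and log(x+1) data with a seeded bootstrap (B = 10000),
   reducing the bias of unequal station counts per cell.
3. **Fuzzy assemblages.** Cells are clustered on the Hellinger-transformed
   log-scale means (Hellinger distance, bounded by √2) with fuzzy c-means in
   dissimilarity form (the FANNY objective, membership exponent r = 1.2).
   Silhouette widths, Mantel correlation and the Kelly–Gardner–Sutcliffe
   penalty inform the number of clusters k; k itself stays a configured
   judgment call. Maximum-membership maps show assemblage coherence.
4. **Indicator taxa.** Dufrêne–Legendre IndVal on raw-scale cell means:
   specificity `A` × fidelity `B`, permutation p-values,
   Benjamini–Hochberg correction; indicators need IV > 0.25 and adjusted
   p < 0.05. Taxa excluded from clustering (broad aggregates such as
   Copepoda) stay in the indicator analysis.
5. **Drivers and comparisons.** PCAs of log-transformed, centered and scaled
   abiotic cell means (with the N/P ratio projected as a supplementary
   variable) and of Hellinger-transformed community means; a ready-to-fit
   mixed-model design table; polygon-restricted re-clustering, per-cluster
   means, per-cell between-year differences and anomaly series for
   inter-annual comparison.

Because raw survey data of this kind are rarely deposited, the package ships
a first-class synthetic survey generator (`scenario_default()`,
`simulate_survey()`): K = 5 contiguous assemblage regions, 20 taxa with a
rank-abundance ladder spanning four orders of magnitude, five planted
indicator taxa, spatially autocorrelated log-normal abundances under a known
spherical variogram, three surveys of realistic size (140 + 130 scattered
stations, 860 transect stations) and region-linked environmental fields —
so every stage of the pipeline can be tested against ground truth.

## Worked example

```r
library(plankgrid)
pipe <- run_pipeline(scenario_default(), pipeline_config(seed = 1))
print(pipe)
#> plankgrid pipeline run
#> consensus_lopt: 43 km (0.39 deg) from 15 taxa (range 28.5-54 km); max relative f loss 0.094
#> grid_spec: 0.39 deg cells, 11 x 8 lattice, 88 kept cells
#> cell_table: 60 cells x 20 taxa (B = 10000, seed = 1); 28 cell(s) excluded
#> clustering set: 13 taxa (dominant 15, secondary 5, excluded 2)
#> fanny_membership: 60 cells, k = 5, r = 1.20; objective 3.6995 (converged in 12 sweeps)
#> cluster sizes (crisp): 10 11 11 12 16
#> indicator taxa: 15
```

The taxon-specific optimal cell sizes range from 28.5 to 54 km; their median
(43 km ≈ 0.39°) defines the analysis grid, at a worst-case loss of 9.4% of
any taxon's own maximal information content. Of the 88 polygon-intersecting
cells, 60 satisfy every survey's minimum-station rule. The k-selection
diagnostics recover the five planted regions:

```r
print(pipe$k_table)
#>  k mean_silhouette mantel_r kgs_penalty
#>  2          0.2847   0.4537       6.360
#>  3          0.4331   0.6419       6.106
#>  4          0.5491   0.7554       6.489
#>  5          0.7024   0.9281       6.697
#>  6          0.6414   0.8905       7.576
#>  7          0.6341   0.8757       8.095
#>  8          0.6397   0.8715       9.000
```

Mean silhouette and Mantel correlation both peak at k = 5. The indicator
table ranks the five planted indicator taxa first, each with full fidelity
in its own assemblage and adjusted p ≈ 0.002:

```r
head(pipe$indicators[order(-pipe$indicators$IV), ], 5)
#>                        taxon best_cluster     A B    IV   p_adj
#>             Evadne_nordmanni            3 1.000 1 1.000 0.00182
#>  Merlangius_merlangus_larvae            2 1.000 1 1.000 0.00182
#>       Clupea_harengus_larvae            1 0.993 1 0.993 0.00182
#>      Sardina_pilchardus_eggs            4 0.986 1 0.986 0.00182
#>  Engraulis_encrasicolus_eggs            5 0.901 1 0.901 0.00182
```

`write_pipeline_outputs(pipe, "out/")` writes the cell table, memberships,
labels, diagnostics, indicator table, PCA results, mixed-model design and a
labelled GeoJSON grid; runs with equal configuration are byte-identical.

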