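# islandflora

Quantitative analysis of long-term change in archipelago floras from
presence/absence occurrence records spanning two census periods.

Island floras recorded over decades to centuries — typically compiled from
floristic literature into species × island × period occurrence tables — let
ecologists ask whether island assemblages behave as equilibrium systems
(composition turns over, richness and structure stay put) or respond
directionally to human pressure (native losses, alien invasion, changes
concentrated on small islands). `islandflora` implements the standard
quantitative toolkit for that question, for anyone working with two-period
archipelago incidence data:

* **ISAR** — the Arrhenius island species–area relationship `S = c·A^z`,
  fitted by nonlinear least squares in untransformed space
  (`fit_power_sar()`, `fit_all_groups()`), per species group (native/alien,
  annual herbaceous / perennial herbaceous / woody) and period;
* **SDR simplex** — pairwise beta diversity partitioned into Similarity
  `S = S_ij/S_t`, richness Difference `D = |S_i−S_j|/S_t` and Replacement
  `R = 2·min(S_i−S_ij, S_j−S_ij)/S_t` with `S + D + R = 1`
  (`sdr_pair()`, `sdr_simplex()`, `sdr_cross_temporal()`,
  `plot_sdr_simplex()`);
* **nestedness** — NODF (strict decreasing-fill rule) with a
  cell-probabilistic CE null model,
  `Z = (Nr − mean Ns)/sd(Ns)` and relative nestedness
  `RN = (Nr − mean Ns)/mean Ns` (`nodf()`, `ce_null()`,
  `nestedness_test()`);
* **change statistics** — period Jaccard similarity and percent change,
  G-tests of composition (`G = 2·Σ O·ln(O/E)`), inter-period OLS of
  per-island richness against the intercept-0/slope-1 no-change null, and
  per-island relative change versus area (`compare_periods()`, `g_test()`,
  `interperiod_regression()`, `relative_change_by_area()`);
* **synthetic archipelagos** — a generator with controllable SAR
  parameters, nestedness strength and occurrence-level turnover
  (`generate_archipelago()`), used to validate every estimator against
  known truth;
* **pipeline** — `run_all()` drives the whole analysis from one YAML
  config, writing plain tab-delimited tables and an auditable run summary.

## Worked example

```r
library(islandflora)

arch <- generate_archipelago(archipelago_config(seed = 1))

# native first-period species-area relationship
m1n <- build_incidence(arch$occurrences, arch$islands, "1830-1950",
                       arch$traits, origin = "native")
fit_power_sar(arch$islands$area_km2, richness_by_island(m1n)$richness)
#> Arrhenius SAR fit (n = 16): S = 260.5 * A^0.2881
#>   F(1, 14) = 8280.8, p = 8.18e-21, achieved tol = 2.59e-09

# whole-flora matrix: nestedness against 100 CE nulls
m1 <- build_incidence(arch$occurrences, arch$islands, "1830-1950")
nestedness_test(m1, n_null = 100, seed = 1)
#> NODF = 65.879 (rows 65.880, cols 59.767)
#> CE null (n = 100): mean 35.985, Z = 51.493, RN = 0.831, p = 0.009901

# archipelago-level change between the periods
compare_periods(arch$occurrences, periods = c("1830-1950", "1951-2015"))
#> total: 1406 -> 1351 species (-3.9%), 1327 shared, Jaccard 0.93, +24 / -79
```

The SAR fit recovers the generator's truth (`c = 252.2, z = 0.296`) from a
binomially noisy 16-island realization; the NODF value of 65.9 sits far
above the CE null mean of 36.0 (Z ≈ 51), i.e. small-island floras are
strongly nested subsets of large-island floras; and the period comparison
shows a modest net richness decline with high compositional stability at
the archipelago level.

Real data enter through three delimited files — occurrences
(`species,island,period`), islands (`island,area_km2`), traits
(`species,origin,functional_type`) — via `read_occurrences()`,
`read_islands()`, `read_traits()`, or through a `run_all()` config.

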