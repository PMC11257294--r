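# occbias

Quantify sampling biases in biodiversity occurrence records, stratified by
data source: **academic** records (collections, monitoring programs,
literature) versus **citizen science** records (participatory platforms,
unstandardized observation). Aggregated occurrence datasets such as GBIF
downloads mix both, and the two strata carry very different taxonomic,
spatial, temporal and environmental biases. `occbias` implements a full
assessment pipeline for Darwin-Core-style occurrence tables, plus a seeded
synthetic occurrence generator with *known* biases so that every statistic
can be validated by parameter recovery.

## What it computes

**Ingestion and stratification** — `read_occurrences()` reads flat
Darwin Core tables; `classify_source()` assigns each record to
academic / citizen science / excluded from its `basisOfRecord` (specimens,
material samples and literature are inherently academic; machine
observations classify by publisher; human observations by a curated
dataset-category table; fossil/living specimens and unknown provenance are
excluded); `merge_datasets()` folds in platform dumps not yet federated.

**Two-tier cleaning** — `clean_general()` (validity, study-area,
missing-order and duplicate filters; coordinate-less records kept) and
`clean_spatial()` (coordinates required; uncertainty > 10 km removed, with
missing uncertainty scored as 111,320/10^d m from the d printed decimal
places; records within 1 km of country capitals/centroids or 100 m of
biodiversity institutions removed). Every removal is attributed to exactly
one filter in a reconciling `cleaning_report`.

**Taxonomic bias** — per-order observation/species shares
(`order_composition()`), cross-platform Spearman correlations of per-order
counts (`platform_order_correlation()`), the user-by-order preference
matrix (`user_order_matrix()`), contributor segmentation by a Tukey
upper-fence outlier rule (`segment_users()`), Shannon diversity per order
(`shannon_per_order()`), and the **proportionality index**
(`proportionality_index()`): per decade, the r² of the OLS regression of
per-species record counts on per-species occupied 0.25° grid cells — 1
means species are sampled proportionately to their ranges.

**Spatial bias** — 0.25° grid densities (`grid_counts()`), the
**nearest-neighbour index** (`nn_index()`): mean observed NN distance over
the mean NN distance of an equal-size uniform sample in the study area,
summarized over 99 null iterations with a 5th–95th percentile band (< 1 ⇒
clustered); and a Bayesian Poisson **distance-decay model**
(`fit_distance_decay()`): `count_j ~ Poisson(q·exp(−Σ_f w_f d_fj))` with
distances to roads, cities and protected areas, exponential priors on the
per-km decay weights `w_f`, sampled with JAGS.

**Temporal bias** — daily count series with the January-1st
missing-date artifact masked (`daily_counts()`), classical additive weekly
decomposition (`decompose_weekly()`), and per-holiday effects
(`holiday_effects()`) against a Spain/Portugal national calendar with
computus-anchored movable feasts (`gregorian_easter()`); holidays falling
on weekends are excluded to avoid confounding with the weekend effect.

**Environmental bias** — correlation PCA of 15 bioclim variables on a
10,000-point background sample (`build_env_space()`), occurrence
projection (`extract_env()`, `project_env()`), and per-decade coverage and
consecutive-period Jaccard overlap of occupied environmental bins
(`period_env_coverage()`).

**Synthetic data** — `synthetic_scenario()` / `simulate_landscape()` /
`simulate_users()` / `simulate_occurrences()` generate
Darwin-Core-like tables with controllable order preferences (Dirichlet),
heavy-tailed user activity (lognormal), mixed uniform/Thomas/accessibility
spatial processes, weekday/holiday/seasonal temporal structure and smooth
environmental gradients — fully determined by one seed.

**Pipeline** — `run_pipeline()` orchestrates the stages from a declarative
config, writing per-stage CSV/JSON outputs and a manifest with content
hashes; synthetic runs are hash-identical across reruns.

## Worked example

```r
library(occbias)

sc   <- synthetic_scenario(seed = 7,
                           study_area = c(xmin = 0, xmax = 5,
                                          ymin = 40, ymax = 44),
                           n_users = 60, n_orders = 6,
                           species_per_order = 8, activity_meanlog = 2.5)
land <- simulate_landscape(sc)
occ  <- simulate_occurrences(sc, land, simulate_users(sc))

tab <- dataset_category_table(c(synthetic_platform = "citizen_science"))
occ <- classify_source(occ, tab)
gaz <- gazetteer_set(land$study_area)
gen <- clean_general(occ, gaz)
spa <- clean_spatial(gen$records, gaz)
spa$report
#> Cleaning report (spatial tier): 1491 -> 1361 records
#>   coords_missing         removed 0
#>   uncertainty            removed 130
#>   capitals               removed 0
#>   centroids              removed 0
#>   institutions           removed 0

proportionality_index(spa$records, land$grid, periods = NULL)
#>   period     value n_species
#> 1 pooled 0.8532071        48

nn_index(spa$records, land$study_area, seed = 3)
#>   period     index     lower     upper n_points n_iter
#> 1 pooled 0.8378563 0.8217888 0.8595596     1361     99
```

The 130 removed records carry a coordinate uncertainty above 10 km (the
generator plants them deliberately). A proportionality index of 0.85 says
record counts track range sizes fairly closely under the default
preference-driven sampling; an NN index of 0.84 with a null band below 1
says the simulated records are mildly but detectably more clustered than
uniform sampling of the same study area.

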