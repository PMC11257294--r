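---
title: "Methods: occurrence-record bias assessment in occbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence-record bias assessment in occbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the design choices where
the design was genuinely open, and the numerical conventions used
throughout `occbias`. It is the package's account of *why* each statistic
is computed the way it is; the README shows *how* to run them.

## Source stratification

Occurrence aggregators mix records of very different provenance. The
package stratifies on the Darwin Core `basisOfRecord` first and dataset
metadata second:

* preserved specimens, material samples and literature records are
  inherently academic — their provenance is physical or published
  evidence;
* machine observations are classified by publisher, because the same
  basis covers standardized monitoring instruments and participatory
  sound-recording platforms;
* human observations carry no intrinsic signal, so they follow a curated
  dataset-to-category table;
* fossil and living specimens and unknown provenance are excluded: they
  do not reflect wild contemporary biodiversity sampling.

Basis-level rules take precedence when the two sources of evidence
conflict (a preserved specimen published inside a citizen-science
dataset); conflicts are counted in an audit attribute rather than silently
resolved. The default policy for a dataset absent from the curated table
is an *error*: a silent fallback would hide classification drift as new
datasets enter an aggregate. Both fallback categories are available for
exploratory use.

## Two-tier cleaning

Non-spatial analyses can use records without coordinates; spatial
analyses cannot. Cleaning therefore runs in two tiers. The general tier
removes degenerate coordinates (the 0,0 point; latitude equal to
longitude — both classic transposition/entry artifacts), points outside
the study-area polygons, records without a taxonomic order, and
duplicates. The spatial tier additionally requires coordinates, bounds the
coordinate uncertainty at 10 km, and excises the classic
geo-referencing-default neighbourhoods: 1 km around country capitals and
country centroids, 100 m around biodiversity institutions.

Design choices worth recording:

* **Duplicate definition.** "Duplicate" is read conservatively as an
  identical (species, event date, latitude, longitude, dataset, user)
  tuple; the column set is configurable. Aggregator-level duplicate flags
  are not assumed to exist.
* **Implied precision.** A record with no reported uncertainty is treated
  as precise to $111{,}320/10^d$ m, where $d$ is the *smaller* of the two
  coordinates' printed decimal-place counts — one degree of longitude at
  the equator divided by the printed resolution, an upper bound at
  mid-latitudes and the conservative choice of $d$. When coordinates
  arrive as binary floats rather than text, the shortest round-tripping
  decimal representation stands in for the printed form, and the
  substitution is logged.
* **Distances.** All proximity rules use great-circle (haversine)
  distance on the mean-radius sphere (6371.0088 km). Mixing degree-based
  and meter-based buffers is a known source of irreproducibility in
  cleaning pipelines, so meters are standardized here.
* **Attribution.** Filters are pure predicates; the retained set is
  invariant to filter order. Only the *attribution* of a removal is
  order-dependent, and the documented first-match order (validity →
  study area → order → duplicate; coordinates → uncertainty → capitals →
  centroids → institutions) makes report counts reconcile exactly:
  input = output + Σ removed.
* **Gazetteers are inputs.** Capitals, centroids and institutions are
  user-supplied coordinate tables, not bundled lists — versioned,
  auditable, and replaceable per study region.

## Taxonomic bias

Composition tables give per-order percentages of observations and of
unique species (species-rank names after whitespace/case normalization;
no synonym resolution — a deliberate non-goal). Orders below 0.5% of
observations are flagged for display filtering but never dropped from
tables.

Cross-platform consistency uses Spearman correlations of log-transformed
per-order counts. Zeros are handled as $\log(x+1)$; rank correlations are
invariant to the offset, and Pearson users are warned about it. Platforms
with fewer than three distinct orders yield no coefficient.

**Contributor segmentation.** "Most active users" is operationalized as
the Tukey upper fence: per-user counts above $Q_3 + 1.5\,\mathrm{IQR}$
(quartiles type 7, R's default). The fence multiplier is configurable;
the sporadic threshold (≤ 10 observations) matches the user-matrix
inclusion rule (> 10). With fewer than four users the quartiles are not
meaningful and the leading set is empty by definition.

**Proportionality index.** For each 10-year period between 1982 and 2022
(`[1982,1992) … [2012,2022]`, the last bin closed so the final year is
kept), each species' range is the count of occupied 0.25° cells computed
*within that period*, its effort the record count, and the index is the
r² of the OLS regression (with intercept — "linear regression" is read
unqualified) of effort on range. The index is invariant to species
relabeling and to uniform scaling of counts. Periods with fewer than
three species return NA. Whether an "all years" figure should be a pooled
regression or an average of decadal values is ambiguous in general use;
the package computes the pooled regression and returns it alongside the
per-period series so both are available.

**Shannon diversity** uses the natural log (the ecological convention);
the base is configurable.

## Spatial bias

**Nearest-neighbour index.** The observed mean nearest-neighbour
great-circle distance is divided by the same quantity for an equal-size
uniform random sample of the study area. The ratio is computed per null
iteration (99 by default) and summarized by its mean and 5th/95th
percentiles, which is what a plotted null band represents; a pooled-null
variant would narrow the band artificially. Null points are drawn by
rejection sampling uniform in (lon, lat) — a planar approximation whose
bias is negligible over a regional extent and identical for observed and
null samples, cancelling in the ratio. Distances are in km; the ratio is
unit-invariant. Periods with fewer than 100 points are skipped rather
than reported noisily. Nearest neighbours are found exactly via unit-
vector dot products (chord and great-circle nearest neighbours coincide),
blockwise so memory stays bounded.

**Distance-decay model.** Per-cell counts follow
$y_j \sim \mathrm{Poisson}(q\,e^{-\sum_f w_f d_{fj}})$ with $d_{fj}$ the
km distance from the cell centroid (centroids, not edges, matching the
0.25° analysis resolution) to the nearest road, city or protected area;
$q$ is the expected count at distance zero and each $w_f \ge 0$ a per-km
decay rate. Priors are weakly informative: $w_f \sim \mathrm{Exp}(1)$,
$q \sim \Gamma(1, 0.01)$. The posterior is sampled with JAGS (2 chains ×
2,000 draws after 1,000 warm-up, per-chain seeds derived from one seed),
checked with the Gelman–Rubin diagnostic (flagged above 1.1), and a
constrained MAP fit (L-BFGS-B on $(\log q, w)$) initializes the chains
and serves as the fallback estimator where sampling is unnecessary or
unavailable. The likelihood is evaluated in log space so that extreme
decay proposals underflow gracefully instead of derailing the optimizer.

Line and polygon-boundary distances use a local equirectangular
approximation with segment densification (~1% accuracy at regional
extents, cross-checked in the tests against a dense point-sampling
oracle); point-feature distances are exact haversine. The polyline is
interpreted as drawn in coordinate space, the natural reading for map
features.

## Temporal bias

Daily record counts are tabulated over 2012–2022 by default, with
explicit zeros. January 1st is masked entirely (not merely dropped as a
holiday): aggregators commonly default missing dates to Jan 1, so its
counts measure metadata loss, not recording behaviour. The synthetic
generator emits genuinely absent dates instead of Jan-1 defaults
precisely so this masking rule can be tested by injection.

The decomposition is classical additive: a centered, missing-aware 7-day
moving-average trend (undefined on the first/last three days and wherever
fewer than 4 of the 7 window days are unmasked); a weekly component equal
to the mean detrended value per ISO weekday (Monday = 1), recentred to
sum to zero; and a residual making the identity
count = trend + weekly + residual exact on every date where all terms are
defined. An additive (not multiplicative) model is appropriate because
the weekly band is read as counts to add or subtract from the trend.
STL-style loess decomposition would be a reasonable alternative; the
classical form was chosen because its weekly component has a closed form
that parameter-recovery tests can target exactly.

Holiday effects are the mean residual over each holiday's dates, using
only years where the holiday falls on a weekday — a holiday on a weekend
is indistinguishable from the weekend effect itself. A dummy-regression
estimate would be the natural alternative; residual means were chosen for
transparency and because the decomposition already absorbs trend and
weekly structure. The calendar holds the twelve fixed Spain/Portugal
national holidays plus Good Friday (Easter − 2) and Corpus Christi
(Easter + 60), with Easter from the anonymous Gregorian computus
(Meeus/Jones/Butcher, validated 1900–2100 against an independent
algorithm in the tests). Regional and substituted holidays are ignored.

## Environmental bias

The environmental space is a PCA of 15 bioclimatic variables (Bio1–Bio7,
Bio10–Bio17) on a 10,000-cell background sample drawn uniformly without
replacement from valid raster cells — equivalent, on an aligned grid, to
sampling random geographic points and extracting, but exactly seedable.
Bio8, Bio9, Bio18 and Bio19 are rejected at validation: their
quarter-based definitions produce spatial discontinuities that distort
ordinations. Variables are z-scored on the background (correlation PCA —
bioclim units are incommensurable, and unscaled PCA would let
precipitation variance dominate). Loadings are sign-fixed (largest
absolute loading positive) so scores are reproducible across BLAS
implementations.

Because "coverage of environmental space" is a visual notion, the package
makes it measurable: the background PC1×PC2 scores are binned on a 50×50
grid over the background extent, and a period's coverage is the fraction
of background-occupied bins its occurrences also occupy; stability across
periods is the Jaccard overlap of consecutive periods' occupied-bin sets.
Occurrence scores outside the background extent are clipped to edge bins
and counted. Records before 1982 (or undated) are excluded — the
climate layers describe a modern normal.

Rasters are an in-package aligned grid-stack container with a plain-text
CSV serialization (`write_env_stack()`/`read_env_stack()`), keeping the
whole pipeline text-only and self-contained.

## The synthetic generator

The generator is first-class, tested code, and the package's measurement
standard: every estimator is validated by recovering a knob it planted.
One master seed expands into independent substreams (landscape, users,
events), so components can be regenerated independently and the full
occurrence table is bit-reproducible.

What it emulates — and the defaults, chosen once as a plausible regional
participatory platform:

* **Taxonomy.** 20 insect orders (real order names, so order-keyed
  statistics read naturally) × 25 species, geometric within-order
  abundances (decay 0.3), contiguous per-species ranges grown on the
  0.25° grid (mean ~30 cells).
* **Users.** 857 users; lognormal activity (meanlog 1.5, sdlog 1.5 — a
  heavy tail in which a few leading contributors dominate);
  Dirichlet(0.3) order preferences, concentrating most users on few
  orders.
* **Space.** A mixture of uniform (0.2), Thomas-cluster (0.5; 30 parents,
  10 km Gaussian scatter) and accessibility-thinned (0.3) location
  processes; accessibility weight $e^{-\sum_f w_f d_f}$ with decay
  0.05/km for roads and cities, 0.02/km for protected areas.
* **Time.** 2012–2022; log-linear trend (log-ratio 0.5 over the span),
  weekday multipliers depressed at weekends, 0.5 holiday suppression, an
  annual sinusoid (amplitude 0.5) peaking in early summer. Event dates
  are drawn from the normalized daily intensity — distributionally
  identical to thinning a uniform proposal, and cheaper.
* **Environment.** Smooth layers: low-order polynomial surfaces plus
  neighbour-smoothed Gaussian noise, z-scaled.
* **Imperfection.** 2% of records undated (truly absent, never Jan-1
  defaulted); 30% without reported uncertainty; uncertainties sampled
  from 10 m to 25 km so the cleaning tier has work to do.

Two special sampling modes bypass user preferences to make the
proportionality index testable in isolation: record intensity exactly
proportional to range size, and intensity independent of range.

What it does **not** emulate: real Iberian geography or CHELSA values,
taxonomic misidentification, positional error beyond the uncertainty
field, observer-level spatial home ranges, or platform growth dynamics.
Passing recovery tests therefore demonstrates estimator correctness under
known generative structure, not robustness to every artifact of real
aggregator data.

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale configurations chosen to give
each statistic comfortable power: ~25,000 records / 100 species for
proportionality recovery; 500 points × 99 null iterations × 200
replicates for nearest-neighbour calibration; 400 cells for
distance-decay recovery; ~120,000 events for weekly/holiday recovery.
Tolerances follow the estimators' noise floors: entropy and OLS oracles
agree to 1e−12/1e−10; the weekly zero-sum constraint to 1e−9; decay
weights to ±30% (Poisson noise at 400 cells); the NN null band is
expected to cover the null value in at least 85% of runs (a 90% nominal
band minus Monte-Carlo slack).

Other conventions: grid membership is half-open, so boundary points
belong to the upper cell deterministically; quantiles are R type 7
throughout; duplicate coordinates are allowed in NN computations (zero
distances are legitimate); empty feature layers contribute nothing to
accessibility weights; all dates are ISO-8601 and weekdays ISO (Mon = 1).

## Known limitations

* Reported uncertainty and printed precision are treated as exchangeable
  evidence of positional quality; no error propagation beyond the
  threshold rule.
* The NN null is uniform in (lon, lat), not equal-area; over extents
  much taller than Iberia's the approximation would need replacing.
* The distance-decay model assumes independent Poisson cells; spatial
  autocorrelation beyond the distance terms inflates posterior
  confidence.
* Coverage/Jaccard statistics depend on the bin count (default G = 50);
  comparisons are meaningful at fixed G.
* No attempt is made to separate insect activity from observer activity
  in the temporal decomposition; both are confounded in daily counts.
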