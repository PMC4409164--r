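---
title: "Linking estuarine meiofaunal communities to their environmental drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking estuarine meiofaunal communities to their environmental drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estuaryr)
```

## The problem

Estuarine benthic sediments host diverse communities of microbial
eukaryotes — above all the meiofauna, animals in the 45–500 µm size
fraction dominated by nematodes. Along an estuary, salinity, tidal energy
and sediment texture change together, and metabarcoding surveys (OTU tables
from 18S amplicon sequencing) let us ask which of these gradients actually
structures the community. `estuaryr` implements that analysis chain as
composable, tested pieces:

1. a 1-D sectional-averaged tidal model that turns channel geometry and
   tidal boundary forcing into per-station hydrodynamic statistics;
2. granulometry and salinity-range feature models that complete a
   14-variable environmental driver matrix;
3. community statistics on presence/absence OTU data (Sørensen
   dissimilarity, group-average clustering with SIMPROF, NMDS, richness
   tables, two-sample tests);
4. driver inference: BIOENV subset search, Mantel tests, CCA with
   collinearity filtering and stepwise AIC, and PLS regression with VIP
   scores;
5. a synthetic two-estuary generator with known ground truth, so the whole
   chain can be validated end to end without any field data.

## The tidal model

The solver integrates the sectional-averaged shallow-water equations

$$B\,\partial_t\eta + \partial_x(AU) = 0,\qquad
  \partial_t U + U\,\partial_x U =
  -g\,\partial_x\eta - \frac{C_D\,U\lvert U\rvert}{h+\eta},$$

with $\eta$ the free-surface elevation, $U$ the depth-averaged velocity,
$B$, $A$, $h$ the local width, cross-sectional area and mean depth, and
$C_D$ a quadratic bottom-friction coefficient. The discretisation is a
staggered grid (elevation at cell centres, velocity at faces),
first-order upwind advection and a semi-implicit friction term — the
simplest scheme that is stable under quadratic friction at estuarine
scales. The seaward boundary is forced by a sum of tidal constituents
(defaults M2, S2, N2, K1 — the dominant semidiurnals plus a diurnal, all
overridable); the landward boundary is a closed weir. Because the
continuity update telescopes exactly, the volume budget closes to
round-off, and the test suite verifies the frictionless linear limit
against the analytic co-oscillation profile
$a\cos k(L-x)/\cos kL$.

Parameter defaults are standard coastal values: $C_D = 2.5\times10^{-3}$,
$\rho = 1025$ kg m⁻³, $g = 9.81$ m s⁻². A run consists of a 2-day
cosine-ramped spin-up (excluded from output) followed by a 14.77-day
analysis window — one spring–neap cycle. Elevation amplitudes for
validation are extracted by harmonic regression at the forcing frequency,
which suppresses the undamped seiche transients that a frictionless run
retains. Total depth is clamped at 0.1 m by default when the upper estuary
nearly dries; a flag turns this into an error instead. "Mean velocity" and
the shear-stress statistics are computed on magnitudes, which the output
records (`velocity_stat = "abs"`).

```{r hydro}
geom <- channel_geometry(seq(250, 40e3 - 250, by = 500),
                         width = rep(400, 80), depth = rep(8, 80))
ser <- solve_tides(geom, tidal_constituents(1.5),
                   hydro_params(dt = 20, ramp_days = 1, run_days = 2,
                                output_every = 30))
station_statistics(ser, c(5e3, 20e3, 35e3))
```

## Environmental features

Granulometry works on cumulative grain-size curves. Percentile diameters
(D50, D10) interpolate linearly in $\log_2$ grain size — the
sedimentological phi scale — and the six size-class percentages use
Wentworth-style bounds at 4, 63, 250, 500 and 2000 µm (the 63–250 µm
"fine sand" class absorbs very fine sand so that six classes partition the
mass). Mechanically sieved and laser-diffraction curves are treated
identically, which assumes constant particle density.

Salinity range — the difference between mean high-tide and mean low-tide
salinity, the distance-decayed stressor of classical estuarine diversity
models — is rarely measured at the sampled stations. Two linear inference
models are provided: against mean salinity, and against distance from the
tidal head; coefficients can also be supplied directly when an externally
established equation is preferred. Linearity is the minimal assumption
compatible with "a fitted relationship"; predictions are clipped at 0 ppt
with a warning.

`assemble_env_matrix()` joins hydrodynamics, granulometry and salinity
range into the canonical 14-driver matrix (order fixed by
`env_driver_names()`), with optional macrofauna richness/abundance/biomass
columns. Stations lacking macrofauna are flagged, not dropped, so the same
object supports both a full-station core analysis and a reduced
macrofauna-inclusive view.

## Community statistics

Counts are converted to per-sample read percentages before any
abundance-based summary, because sequencing depth varies by an order of
magnitude between samples. Multivariate analyses use presence/absence
restricted to eleven metazoan target phyla (`metazoan_phyla()`), Sørensen
dissimilarity $d = 1 - 2a/(2a+b+c)$, group-average (UPGMA) clustering and
NMDS. A pair of empty samples has an undefined Sørensen coefficient; it is
defined as $d = 0$ with a warning so that degenerate stations do not crash
a pipeline.

SIMPROF follows the similarity-profile algorithm: at each dendrogram node,
the ordered between-sample similarity profile is compared with its mean
over independent within-OTU permutations; the statistic is
$\pi = \sum_i \lvert \mathrm{obs}_i - \mathrm{mean}_i \rvert$ and the
p-value is $(b+1)/(m+1)$ over further permutations, which can never reach
zero. Recursion stops at non-significant nodes; nodes with fewer than
three samples are not testable and form groups directly. Defaults are 1000
profile permutations, 999 test permutations and $\alpha = 0.05$, recorded
in the result object since the choice is conventional. The suite verifies
the nominal type-I error on i.i.d.-column nulls and the recovery of
disjoint community blocks.

NMDS minimises Kruskal stress-1 in the global non-metric model; the
package manages restarts (one metric start from principal coordinates,
the rest random) and returns the best, centred solution. Stress printed by
`nmds()` is on the 0–1 scale.

## Driver inference

**BIOENV** exhaustively enumerates variable subsets (up to a configurable
size; a guard refuses more than $2^{20}$ subsets unless forced), computes
Euclidean distances on the standardised subset and ranks subsets by the
Spearman correlation between those distances and the biotic
dissimilarities. Because Spearman is rank-based, the search scores squared
distances, which is a monotone shortcut. Station-level analyses pool the
replicate cores (an OTU is present at a station if present in any core),
since environmental variables exist only at station resolution;
sample-level analysis remains available by passing the sample-level
matrix.

**Mantel tests** use the same rank correlation with a
simultaneous row/column permutation null.

**CCA** chi-square-standardises the community matrix (total inertia =
Pearson chi-square / grand total — asserted against `chisq.test` and
`vegan::cca` in the tests), regresses it on row-weight-standardised
predictors and eigen-decomposes the fitted matrix. Predictors with
pairwise $\lvert r\rvert > 0.7$ are removed first by `filter_collinear()`
(the member of the worst pair with the higher mean absolute correlation
goes first; named variables can be protected). Model selection is
forward–backward stepwise on a deviance-style AIC,
$n\log(\text{residual inertia}/n) + 2k$. Per-variable significance uses
Freedman–Lane permutation of reduced-model residuals; with row weights
this is approximate, which is documented in preference to inventing an
exact scheme the literature does not supply.

**PLS-VIP** fits a univariate-response PLS by NIPALS-style deflation on
standardised data (both $X$ and $y$ are standardised), two components by
default. VIP scores satisfy $\sum_j \mathrm{VIP}_j^2 = p$ exactly;
predictors with VIP > 1 on the first latent variable are flagged
pertinent, and VIP over all components is reported alongside. The
association sign is the sign of the first-component coefficient. The
per-predictor $R^2$ values carry permutation p-values (response permuted),
mirroring how driver-importance tables annotate significance.

```{r drivers}
d <- generate_dataset(estuary_scenario(seed = 1, n_stations = 12,
                                       taxon_pool = c(Nematoda = 80,
                                                      Mollusca = 30)))
P <- to_presence(d$otu)
Pst <- pool_presence_by_station(
  P, d$otu$samples$station[match(rownames(P), d$otu$samples$sample)])
D <- sorensen_dissimilarity(Pst)
bioenv(D, env_values(d$env), max_subset_size = 3)$table[1:3, ]
```

## The synthetic generator

`estuary_scenario()` encodes the study design the package is built
around: two estuaries sampled at 20 and 15 stations with 3 replicate
cores each, per-sample read totals between 1044 and 30786, salinity
ranges bounded by 14.16 and 18.97 ppt respectively, spring tidal ranges
up to 6.56 and 8.64 m, and peak velocities up to 2.07 and 1.70 m s⁻¹ —
the magnitudes a UK east/west-coast estuary pair exhibits. Per-station
richness is not pinned to published values (none exist at that
resolution); magnitudes are calibrated only to these ranges.

The environmental gradient gives every variable a smooth along-channel
shape — logistic seaward-increasing mean salinity, a mid-estuary
salinity-range peak (a scaled beta-shaped curve, chosen because observed
ranges peak mid-ecocline and no published curve form is available),
seaward-growing tidal range and velocity, and a grain-size field coarse at
the mouth and head and fine near the turbidity maximum — plus independent
multiplicative station noise. The granulometry block is derived from
per-station log-normal cumulative curves through the same
`granulometry_summary()` used on real data, so D50, D10 and the fractions
are internally consistent (and, as in real estuaries, strongly
correlated).

Communities are generated at the phylum level: each phylum is assigned one
environmental driver and an effect on the logit-occupancy scale, so OTU
$j$ of phylum $g$ is present in sample $i$ with
$\mathrm{logit}\,p_{ij} = \beta_{0j} + \beta_j z_{g(i)} + \varepsilon_{ir}$,
where $z$ is the standardised driver value at the station and
$\varepsilon$ a Normal per-replicate offset (default SD 0.5: replicates
resemble each other without being identical). Phylum-level rather than
per-OTU assignment mirrors how per-phylum richness responds to drivers in
the field. OTU identifiers are estuary-specific. Read counts are
multinomial over present OTUs with log-normal relative abundances. All
randomness flows from one integer seed through per-stage derived seeds, so
every dataset is exactly reproducible.

What the generator does *not* emulate: sequence-level artefacts (chimeras,
denoising errors), phylogenetic structure among OTUs, shared taxa between
estuaries, abundance-driven detection, and tide-driven salt transport.
Passing tests therefore demonstrate that the statistics recover planted
structure of the assumed logistic form — not that field data meet those
assumptions.

## Numerical choices and degenerate inputs

* Permutation p-values are always $(b+1)/(m+1)$; the smallest attainable
  value is $1/(m+1)$.
* UPGMA ties break deterministically by label order; equal-distance inputs
  give a deterministic topology.
* Percentile interpolation returns exact bin edges when the cumulative
  curve hits the requested percent exactly; requests outside the observed
  span raise an error rather than extrapolate.
* Zero-variance predictors, all-zero samples, station key mismatches and
  rank-deficient CCA designs all fail with the offending names in the
  message.
* The CFL bound is checked before a tidal run and reported with the
  limiting time step.

## Problem sizes

The test suite and the acceptance script are sized for a single CPU: the
SIMPROF type-I simulation uses 500 null datasets of 10 samples × 30 OTUs
with 100 profile and 199 test permutations; driver-recovery simulations
use 50 seeds of 20-station, 200-OTU communities; the tidal-model checks
use 100–200-node channels at 20 s time steps over 2–4 days plus one
15-day spring–neap reduction. The end-to-end acceptance run uses the full
20+15-station design with 200/199 SIMPROF and 499 test permutations —
p-value floors of 1/200 and 1/500, far below the 0.05 working level. The
in-package defaults (1000/999) remain the convention for real analyses.

## Known limitations

* The 1-D model has no salt-transport module, so salinity range is always
  an inferred (regression) quantity, as in the motivating field design.
* The CCA per-variable permutation test is approximate under row
  weighting.
* BIOENV confidence is not quantified (no permutation envelope on ρ);
  the search reports the observed ranking only.
* With strongly collinear drivers — which the realistic generator
  reproduces deliberately — no subset search can isolate a unique driver;
  interpretation must lean on the collinearity filter and on the VIP
  table, exactly as with field data.
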