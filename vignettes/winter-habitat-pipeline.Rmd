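---
title: "From Argos fixes to accessibility-weighted winter habitat maps"
author: "iceSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Argos fixes to accessibility-weighted winter habitat maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Juvenile and sub-adult male Antarctic fur seals remain in maritime
Antarctica through the winter, foraging at and beyond the advancing sea-ice
edge. Satellite tags yield irregular, noisy position fixes; the question is
where suitable habitat lies, which environmental fields drive its use, and
how much of the apparently unsuitable area is simply *inaccessible* because
it sits deep inside the pack ice or too far from where the animals can
swim. `iceSDM` implements the complete chain from raw Argos tables to
accessibility-weighted monthly suitability maps, together with a synthetic
study system in which the true preference is known, so that the chain can
be validated by recovery rather than by inspection.

This vignette is the package's methods record: the models, their
assumptions, the tunable parameters, and the design decisions taken where
the problem statement left the choice open.

# Track cleaning and regularization

**Near-duplicates.** A fix is dropped iff it occurs 2 minutes or less
after the most recently *kept* fix of the same individual (sequential
scan, not all-pairs). The scan is idempotent and always returns a
subsequence of the input.

**Speed–distance–angle filter.** Class-Z (invalid) fixes are removed
first. A fix is then removed when a retained consecutive pair implies a
great-circle speed above `vmax` (default 3 m s⁻¹), or when it is the apex
of a spike: inner angle below 15° with both adjacent legs above 2.5 km, or
below 25° with both legs above 5 km. The inner angle is computed by the
planar law of cosines on great-circle side lengths; removal iterates to
convergence so the retained track satisfies all rules simultaneously.
When a speed violation is found, the fix involved in most violating pairs
is removed (an outlying fix violates on both sides); ties prefer the later
fix. All geodesy is haversine on a 6371-km sphere.

**Gap splitting.** Gaps strictly greater than 7 days split a track into
segments treated independently everywhere downstream ("in excess of" is
strict: a 7-day gap does not split). Duplicate removal is applied before
class-Z removal; the order is recorded here because the filter
specification does not fix it.

**State-space regularization.** Each segment is smoothed with a
discrete-time correlated random walk on a local equirectangular projection
(km). Per dimension the state is position and velocity; over an interval
of $f$ six-hour units
$$x' = x + f\,v, \qquad v' = \gamma^{f} v + \eta,\quad
  \operatorname{Var}(\eta) = \sigma^2 f,$$
with observations $z = x + \varepsilon$, $\varepsilon \sim
N(0, \tau^2_{\mathrm{class}})$ and $\tau$ fixed per Argos class from the
noise specification (`argosNoiseSpec()`; default SD ladder
0.25/0.5/1.5/4/6/10 km for classes 3/2/1/0/A/B — a configuration choice,
not a measured fact). $\gamma \in [0,1]$ and $\sigma$ are estimated by
maximum likelihood (Kalman filter over the union of observation and
lattice times; Nelder–Mead with up to three re-initialisations), and
positions on the exact 6-h lattice are extracted from an RTS smoother with
per-position uncertainty. Non-converged segments are flagged and excluded
with a warning. The smoother is fitted per segment, matching the
independent treatment of split tracks. On simulated tracks the smoothed
RMSE beats the raw observations in essentially every replicate
(`ssmBenefitExperiment()`).

**Haul-outs and trips.** Visual haul-out identification is replaced by a
reproducible rule: maximal runs of positions within `radiusKm` (default
5 km) of the coast lasting at least `minHours` (default 6 h), honouring a
dry-sensor flag when present. Because positions live on a 0.1° grid,
"distance to the coast" is measured to the land-cell boundary
(centre distance minus half the cell diagonal). Trips are the ocean
spans between consecutive haul-outs; a trip is a round trip iff both ends
share a haul-out identity.

# Pseudo-absences

Availability is represented by null tracks: a first-order vector
autoregression on the state $(s_t, \sin\theta_t, \cos\theta_t)$ — step
length and turning angle on the 6-h lattice — is fitted to each segment by
least squares, shrunk if needed so the spectral radius is below one.
Simulations fix the template's first at-sea location and timestamps, clamp
negative step lengths to zero, and keep every position at sea by rejection
sampling (100 draws, then a doubled innovation SD for 100 more; a
persistently blocked simulation is abandoned with a warning and redrawn).
Under an all-sea mask the pooled simulated step lengths are
distributionally indistinguishable from the template's (KS test in the
suite).

Presences and pseudo-absences are gridded at 0.1° per individual and UTC
day (half-open cell convention, one record per individual–day–cell–label).
A pseudo-absence is contradictory — and removed — when any presence of
*any* individual occupies its Moore neighbourhood (the 3 × 3 block
including the cell itself) within ±2 days; "adjacent" is not defined in
the source description, and the inclusive Moore reading is the
conservative one. Finally a 1:1 response is drawn: within each
(individual, day) stratum exactly `min(presences, absences)` absences are
sampled without replacement; strata left short keep what remains (the
shortfall is logged) rather than borrowing across strata.

# Environmental covariates

The covariate stack mirrors the standard 13-layer winter set: bathymetry
(GEBCO sign convention, negative at sea) and its slope; daily ice
fraction, ice thickness, distance to the ice edge, SST and its gradient,
salinity and its gradient, sea-surface height, eddy kinetic energy,
chlorophyll-a and mixed-layer depth. Derived layers:

* **Slope / gradients** — Horn's eight-neighbour stencil with
  latitude-corrected cell dimensions, replicated edges, missing neighbours
  replaced by the centre value; output in degrees.
* **EKE** — $0.5\,(U^2+V^2)$; EKE and chlorophyll are log(x+1)-transformed
  once at stack-assembly time and the transform is recorded in the object
  so it cannot be applied twice. Natural logarithm.
* **EDGE** — for each open-water cell, the shortest path (km) to the
  nearest cell with ice fraction above 0.15, where paths traverse sea
  cells only (8-connected, great-circle edge lengths, land blocks
  propagation; multi-source Dijkstra in compiled code, checked exactly
  against an igraph oracle). Ice-interior cells get 0; enclosed basins
  unreachable from any ice get `Inf`; with no ice anywhere the layer is
  undefined and a note is emitted.
* **Regridding** — bilinear, exact on affine fields, identity on matching
  grids, missing values propagate.

Records are matched to covariates by the mean over cells whose centres lie
within 15 great-circle km of the record's cell centre (ties at exactly
15 km included), from the record's UTC date; averaging skips missing
cells, so sparse chlorophyll coverage yields occasional missing values
that are *retained* and routed through the trees rather than imputed.

Collinearity is screened on the matched table with Spearman correlations
(average ranks, pairwise-complete); pairs at $|\rho| \ge 0.7$ are resolved
greedily, keeping the covariate earlier in the canonical layer order, until
no pair exceeds the threshold. Constant covariates have undefined
correlations and are reported, never dropped automatically. In the
synthetic world, ice thickness is generated as a monotone function of ice
fraction plus small noise precisely so this screen has something real to
discard.

# The boosted-tree habitat model

The Bernoulli boosted regression tree is implemented from scratch
(compiled core). With response $y \in \{0,1\}$ and logit-scale score
$F(x)$ initialised at the training prevalence, each iteration fits a
regression tree with at most `treeComplexity` splits (best-first growth)
to the gradient $y - p$ on a random `bagFraction` subsample, sets each
leaf to the Newton step $\sum (y-p) / \sum p(1-p)$, shrinks it by
`learningRate` and adds it to the ensemble. Split search is exact
(sort-and-scan least squares); missing covariate values are excluded from
the gain computation and routed to the majority child, at training and at
prediction. Boosting is deterministic given the seed; with the bag
fraction at 1 predictions are invariant to row order.

**Tuning.** The published candidate sets are the default grid: trees
50–10,000 in 50-tree increments, tree complexity 1/3/5, learning rate
0.005/0.001/0.05/0.01, bag fraction 0.5/0.6/0.7 (36 combinations). Model
selection uses leave-one-individual-out cross-validation — all data of the
held-out seal, its presences *and* its simulations' pseudo-absences, are
excluded from training — evaluating the staged ensemble every 50 trees
(identical to refitting per tree count for stagewise boosting). The
selected combination must exceed 1000 trees and maximises the mean
cross-validated AUC; the selection criterion is stated in the source as
*minimising* AUC, which contradicts AUC's direction as a performance
measure and is treated as a slip. Ties prefer larger learning rates, then
smaller tree complexities, then fewer trees. Cross-validated deviance
explained is pooled over folds against fold-specific intercept-only
models (the alternative — averaging per-fold ratios — was not taken;
pooling weights folds by their size).

**Interrogation.** Relative influence is the per-covariate sum of split
gain, normalised to 100%; a uniform-integer control covariate on [1, 100]
is appended before fitting, and any covariate whose influence falls at or
below the control is flagged uninformative. Partial dependence fixes one
covariate at each grid value, averages the ensemble on the logit scale
over the training rows and back-transforms; it is checked against direct
brute-force averaging.

**Uncertainty.** The model is refitted 50 times (20 in the desk-scale
experiment) on resamples of size ⌊N/2⌋ drawn with replacement — without
class stratification, matching the plain "half the data" prescription;
single-class resamples are redrawn and counted. Daily maps report the
per-cell median and the 95% confidence-interval range
($q_{0.975}-q_{0.025}$) of the bootstrap predictions; monthly summaries
average over exactly the days available in the month. At prediction the
random control is fixed at its training mean (50.5), keeping maps
deterministic given the fits.

# Accessibility

Habitat suitability says nothing about whether a cell can be reached. A
second model regresses a binary cell response — 1 if any observed *or*
simulated location fell in the open-water cell during the study, 0
otherwise — on distance beyond the ice edge, under a monotone
non-increasing constraint: logistic regression on an I-spline basis
(cumulative B-splines, degree 3, interior knots at distance quantiles)
whose coefficients are constrained non-negative and enter with a negative
sign, so every fitted curve is non-increasing by construction. A small
ridge penalty is chosen once on the full table by 2-fold cross-validated
deviance over a fixed grid {0, 10⁻⁴, 10⁻², 1}; the 50 bootstrap members
(half the data, with replacement) share it. With the penalty off, the
curve tracks pool-adjacent-violators isotonic regression on binned
empirical proportions.

The distance covariate of the pooled cell table is the cell's ice-edge
distance averaged over the study days (the response is pooled over the
period, so a single distance per cell is required); at *weighting* time
the curve is evaluated on each day's EDGE layer. Weighting multiplies the
median suitability by the access probability — "weighted by" is read as a
product of probabilities — and cells above 15% ice concentration are set
to zero outright; their distance is never evaluated. Land stays missing.

# Trip analytics

Departure and arrival histograms count trips per local solar hour
(UTC + longitude/15). Daylength uses the sunrise equation with declination
$\delta = -23.44°\cos(2\pi(d+10)/365)$, clamped to 0/24 h in polar night
and day, and agrees with a higher-accuracy ephemeris formula to within
0.2 h away from the polar transitions. The daylength–trip-duration
correlation (Pearson) pairs each trip with the daylength at its midpoint
date and mean at-sea latitude; pairing at the departure date was the
alternative and the midpoint was chosen as the trip's representative
exposure. Dive records aggregate to per-seal-day maxima, then monthly
mean ± SD across seal-days. Transect demography reports per-haul-out
totals, the pooled total and per-class percentage composition as
mean ± SD across censuses. The published tagging summary ships as a
plain-text table (`taggingTable()`); its trip column pools to 243 trips,
its longest track is 197 days, and 14 of the 15 tags survive the ~48-h
retention rule.

# The synthetic study system

`generateEnvStack()` builds a 60 × 60-cell (0.1°), 120-day world by
default: a southern coastal land band and a haul-out island; bathymetry
deepening away from land and saturating offshore; Gaussian random fields
(separable kernel smoothing, correlation length 6 cells) evolving as
daily AR(1) processes (coefficient 0.85, patch half-life ≈ 4 days);
SST with a south–north gradient, seasonal cooling and mesoscale patches;
an ice field whose 15% contour advances equatorward through the winter;
and ice thickness tied monotonically to ice fraction. About 0.6% of sea
chlorophyll values are blanked to emulate sparse ocean-colour coverage.

`truthModel()` defines suitability as a logistic in standardised SST
(−2.0), chlorophyll (+1.5) and bathymetry (+1.0) — cold, productive,
shallow. Movement is a 6-h correlated random walk biased by the
preference strength β: candidate steps are scored
$\exp(\beta\,s)$; high suitability slows the seal and loosens heading
persistence (area-restricted search, slowdown $e^{-0.4\beta s}$); 30% of
candidates are long omnidirectional "scout" steps exempt from the
slowdown; and occasional multi-day transit relocations head toward the
best of twelve 120-km bearings (softmax in β). At β = 0 every one of
these devices reduces to an unbiased correlated random walk. Haul-out
schedules depart in the evening and arrive in the morning (local solar
time), with trip durations lengthening log-linearly through the winter so
that late-winter excursions last weeks — which both matches the tagged
animals' behaviour and is what makes basin-scale habitat recovery
possible at all: early versions of the movement model produced
island-bound seals whose usage contained almost no habitat signal, an
availability artifact rather than a preference. Movement parameters
(step mean 12 km/6 h, gamma-distributed with shape 2; turning SD 40°)
are in the range reported for transiting fur seals. Haul-out positions
are retained in the habitat model's presence data: the brief synthetic
haul-outs are genuine coastal use, and the trip analytics — not the
habitat model — are where shore periods are segmented out.

Observations are the linearly interpolated true positions at
exponential-gap fix times (mean 2 h, with 6% of gaps under 2 minutes to
exercise the duplicate filter), plus isotropic class noise; classes are
drawn from a fixed frequency table including 5% class Z.

What the generator does *not* emulate: ocean physics (fields are
statistical, not dynamical), tidal or diel haul-out structure beyond the
evening/morning schedule, tag failure and duty cycling, and model biases
of assimilative ocean products. Passing the recovery experiment therefore
demonstrates that the pipeline's statistics are correct and that its
design can recover a known preference under realistic noise — not that
any particular field product is adequate for real seals.

# The recovery experiment

`recoveryExperiment()` runs the full pipeline on the default world with
8 individuals, 10 pseudo-tracks per segment and 20 bootstrap fits, and
measures: leave-one-seal-out cross-validated AUC (expected > 0.8);
whether each of the three generating covariates out-ranks the random
control in relative influence; the Spearman correlation between predicted
and true suitability on sea cells never visited by a presence (expected
≥ 0.7, evaluated on 8 dates spread over the season); monotonicity of
every bootstrap accessibility curve on a dense grid; and that weighted
suitability is exactly zero wherever ice fraction exceeds 15%. Across
development seeds the experiment gives AUC ≈ 0.82–0.90 and held-out
ρ ≈ 0.71–0.83. The tuning grid used here is a reduced subset (tree
complexity {3, 5} × learning rate {0.05, 0.01} × bag 0.5, up to 1500
trees) — the full published grid is the package default and the reduction
is an argument of the experiment, chosen to keep the experiment a
few-minute computation; with strong signal the selected configurations
plateau well before 1500 trees.

# Numerical choices and degenerate inputs

* Strict inequalities follow the stated wording: "2 min or less" drops at
  exactly 120 s; "in excess of 7 days" keeps a 7-day gap; the ice edge is
  "> 15%".
* Cell assignment is half-open with a 10⁻⁹-cell tolerance so boundary
  points land deterministically in the upper cell.
* The Kalman filter adds 10⁻⁸ positional process noise for conditioning;
  measurement SDs are floored at 1 m so a "noiseless" class remains
  well-posed.
* Degenerate VAR segments (constant velocity) fall back to the mean-state
  model with near-zero innovations; heading persistence is reported as 1
  for a straight line and negative for reversing zig-zags.
* Tree leaves cap the Newton step at |20| on the logit scale; empty-gain
  leaves predict 0.
* Single-class responses, all-missing rasters, degenerate one-cell grids,
  and accessibility tables with one class are rejected with errors, as are
  truth models referencing covariates absent from the world.

# Known limitations

* The CRW smoother is a discrete-time surrogate for continuous-time
  state-space formulations; its uncertainty is Gaussian and per-axis.
* Pseudo-track VAR innovations are Gaussian, so extreme step-length tails
  are under-represented relative to heavy-tailed movement kernels.
* The accessibility response pools the whole study period; a per-day
  response table is not implemented (the curve *is* evaluated daily when
  weighting).
* The demographic GLMM of dive depth is out of scope; only the monthly
  aggregates that would feed it are computed.
* Problem sizes in the shipped experiments (60 × 60 cells, 120 days,
  8 seals, 10 simulations, 20 bootstrap fits) are the package's validation
  conditions; scaling all of them up is a matter of configuration, not
  code.
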