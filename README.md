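# iceSDM

Winter habitat modelling of ice-associated marine predators from Argos
satellite telemetry.

`iceSDM` is an end-to-end, fully tested R implementation of a
presence/pseudo-absence species-distribution workflow for animals tracked
by satellite in the seasonal sea-ice zone — the setting is juvenile and
sub-adult male Antarctic fur seals overwintering around the western
Antarctic Peninsula, tagged at a moulting haul-out and tracked for 26–197
days through the austral winter. The package takes noisy, irregular Argos
fixes and daily gridded ocean fields, and produces accessibility-weighted
monthly habitat-suitability maps with bootstrap uncertainty.

Every modelling stage is implemented in the package rather than delegated:

1. **Track cleaning** — near-duplicate removal (fixes ≤ 2 min after the
   last kept fix), a speed–distance–angle filter (class-Z removal, speeds
   > 3 m s⁻¹, spikes sharper than 15°/25° with legs > 2.5/5 km), and
   splitting at data gaps in excess of 7 days.
2. **Regularization** — a correlated-random-walk state-space model
   (Kalman filter + RTS smoother, maximum likelihood for the velocity
   persistence γ and process noise σ) estimating positions every 6 h with
   Argos-class-specific measurement error.
3. **Pseudo-absences** — for each track segment, 50 (configurable)
   null tracks from a first-order vector autoregression fitted to the
   segment's step lengths and turning characteristics, constrained to the
   sea and sharing the template's start and timestamps; daily 0.1°
   gridding; removal of pseudo-absences Moore-adjacent to any presence
   within ±2 days; 1:1 stratified sampling per individual and day.
4. **Covariates** — seabed slope (Horn's method), SST/salinity gradients,
   eddy kinetic energy `EKE = 0.5 (U² + V²)`, shortest sea-path distance
   to the 15% sea-ice contour (multi-source Dijkstra; land blocks paths),
   bilinear regridding, 15-km-radius covariate matching, and a Spearman
   collinearity screen at |ρ| ≥ 0.7.
5. **Habitat model** — Bernoulli boosted regression trees written from
   scratch (stagewise gradient boosting with depth-limited least-squares
   trees, bagging and shrinkage; compiled core), tuned by
   leave-one-individual-out block cross-validation with the published
   candidate grid, a random-number importance control, relative influence
   and partial dependence, and a 50× half-data bootstrap giving per-cell
   median and 95%-CI-range daily maps with monthly averages.
6. **Accessibility** — a monotone non-increasing binomial model of cell
   access probability against distance beyond the ice edge (logistic
   regression on an I-spline basis with sign-constrained coefficients,
   bootstrapped), with cells above 15% ice concentration forced
   inaccessible, multiplied into the habitat maps.
7. **Trip analytics** — haul-out detection, trip segmentation,
   departure/arrival timing histograms (local solar hour), daylength via
   the sunrise equation and its correlation with trip duration, daily
   maximum dive-depth aggregation, and haul-out demography summaries.

Because the original tracking data are not redistributed, the package
ships a first-class synthetic-data module (`generateEnvStack`,
`truthModel`, `generateTracks`, `generateTransectCounts`) that simulates
the whole study system — seasonal ice advance, correlated ocean fields, a
coastal haul-out island, and seals whose movement prefers a known logistic
suitability — so the full pipeline is testable end to end and its ability
to recover a known truth is measured, not assumed.

## Worked example

```r
library(iceSDM)

cfg   <- syntheticWorldConfig(seed = 7)          # 60 x 60 cells, 120 days
world <- deriveCovariates(generateEnvStack(cfg)) # adds SLP, EKE, EDGE, ...
truth <- truthModel(world)                       # prefers cold, green, shallow
gen   <- generateTracks(world, truth, n = 3, seed = 11)

regs <- preprocessTracks(gen$obs)                # clean + 6-h smoothing
sims <- list()
for (k in seq_along(regs)) {
  reg <- regs[[k]]
  mm  <- fitMovementModel(reg)
  k0  <- which(atSea(world, reg$lon, reg$lat))[1]
  sims <- c(sims, simulatePseudoTracks(mm, reg[k0:nrow(reg), ], n = 10,
                                       stack = world, seed = 5 + k))
}
g   <- filterContradictions(gridLocations(do.call(rbind, regs), sims, world))
bal <- sampleBalanced(g, seed = 2)
covs <- c("BAT","SST","SAL","SIC","SIT","SSH","CHL","MLD","EKE")
tab <- addRandomControl(matchCovariates(bal, world, covariates = covs),
                        seed = 3)
scr <- collinearityScreen(tab, covs)
fit <- fitBRT(tab, c(scr$kept, "RAND"), nTrees = 500, treeComplexity = 3,
              learningRate = 0.05, bagFraction = 0.5, seed = 1)
sort(relativeInfluence(fit), decreasing = TRUE)
```

Output from this exact script:

```
2304 Argos fixes from 3 seals
3 regularized segments; 764 6-h positions
30 pseudo-tracks simulated
559 presences / 557 pseudo-absences after 1:1 sampling
screened out: SIT (rho = 1.00 with SIC)
 BAT  SIC  SSH  CHL  SST  EKE  MLD RAND
33.1 15.5 10.7 10.5 10.4  8.4  7.2  4.2
```

Sea-ice thickness is discarded by the collinearity screen (it is generated
as a monotone function of ice fraction), and the relative influences —
which sum to 100% — place the covariates the simulated seals actually
prefer (bathymetry, chlorophyll, temperature) above the random-number
control at 4.2%. With the full eight-individual design
(`recoveryExperiment()`), the leave-one-seal-out cross-validated AUC is
≈ 0.84 and predicted suitability rank-correlates with the generating truth
at ρ ≈ 0.74 on cells no seal ever visited.

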