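# End-to-end orchestration: raw Argos fixes -> cleaned, regularized tracks
# -> pseudo-absences -> matched covariates -> tuned BRT -> bootstrap maps ->
# accessibility weighting; plus the self-contained simulation experiments
# used to validate the pipeline against a known truth.

#' Clean and regularize raw Argos tracks
#'
#' Per individual: near-duplicate removal, the speed-distance-angle filter,
#' splitting at data gaps over 7 days, and CRW state-space regularization
#' of each segment to the 6-h lattice. Segments too short to smooth are
#' dropped with a message.
#'
#' @param obs Raw fixes (`id`, `time`, `lon`, `lat`, `lc`).
#' @param noise [argosNoiseSpec()] used for the measurement model.
#' @param vmax,maxGapDays,stepHours Filter and lattice parameters.
#' @param minFixes Minimum fixes per segment to attempt smoothing.
#' @return List of regularized segments (data.frames from [fitCRWSSM()]).
#' @export
preprocessTracks <- function(obs, noise = argosNoiseSpec(), vmax = 3,
                             maxGapDays = 7, stepHours = 6, minFixes = 8) {
  clean <- sdaFilter(removeNearDuplicates(obs), vmax = vmax)
  segs <- splitOnGaps(clean, maxGapDays = maxGapDays)
  out <- list()
  for (seg in segs) {
    if (nrow(seg) < max(4, minFixes) ||
        diff(range(as.numeric(seg$time))) < 2 * stepHours * 3600) {
      message("segment ", seg$segment[1], " too short to regularize; dropped")
      next
    }
    reg <- tryCatch(fitCRWSSM(seg, stepHours = stepHours, noise = noise),
                    warning = function(w) {
                      suppressWarnings(fitCRWSSM(seg, stepHours = stepHours,
                                                 noise = noise))
                    })
    if (!is.null(reg)) out[[length(out) + 1L]] <- reg
  }
  out
}

#' Full pipeline recovery experiment on synthetic data
#'
#' Simulates a world with a known habitat preference (logistic in three
#' covariates), runs the complete pipeline -- preprocessing, VAR(1)
#' pseudo-tracks, daily 0.1-degree gridding with the 2-day adjacency
#' filter, 1:1 stratified sampling, 15-km covariate matching, collinearity
#' screen, random-number control, leave-one-individual-out tuned BRT,
#' half-data bootstrap maps, and monotone accessibility weighting -- and
#' measures how well the truth is recovered.
#'
#' @param seed Integer seed driving every random stream.
#' @param config World configuration (default: 60 x 60 cells, 120 days).
#' @param nIndividuals Number of simulated seals.
#' @param nSim Pseudo-tracks per segment.
#' @param nBoot Bootstrap fits for maps and accessibility.
#' @param prefStrength Movement preference strength of the truth model.
#' @param covariates Covariates offered to the model (before screening).
#' @param tuneGrid Hyperparameter grid for [tuneBRT()].
#' @param nPredDates Number of evenly spread prediction dates (default 8).
#' @return List with `cvAUC`, `devianceExplained`, `influence`,
#'   `truthCovariates`, `influenceAboveRandom`, `spearmanHeldOut`,
#'   `accessMonotone`, `weightedZeroIce`, `screen`, `tune`, `maps`,
#'   `weighted`, `stack`, `nRecords`.
#' @export
recoveryExperiment <- function(seed = 1L,
                               config = syntheticWorldConfig(seed = seed),
                               nIndividuals = 8, nSim = 10, nBoot = 20,
                               prefStrength = 10,
                               covariates = c("BAT", "SST", "SAL", "SIC",
                                              "SIT", "SSH", "CHL", "MLD",
                                              "EKE"),
                               tuneGrid = brtGrid(
                                 treeComplexity = c(3, 5),
                                 learningRate = c(0.05, 0.01),
                                 bagFraction = 0.5,
                                 maxTrees = 1500, treeStep = 50),
                               nPredDates = 8) {
  stack <- deriveCovariates(generateEnvStack(config))
  truth <- truthModel(stack, prefStrength = prefStrength)
  gen <- generateTracks(stack, truth, n = nIndividuals, seed = seed + 1L)

  regs <- preprocessTracks(gen$obs)
  if (!length(regs)) stop("no usable segments after preprocessing")

  # haul-out positions are retained as genuine use; trip trimming is left
  # to the foraging-trip analytics (detectHaulouts / segmentTrips)
  atSeaRegs <- regs[vapply(regs, nrow, integer(1)) >= 12]
  if (!length(atSeaRegs)) stop("no usable segments")

  sims <- list()
  for (k in seq_along(atSeaRegs)) {
    reg <- atSeaRegs[[k]]
    mm <- fitMovementModel(reg)
    # simulations must start at sea; trim leading coastal positions
    k0 <- which(atSea(stack, reg$lon, reg$lat))[1]
    if (is.na(k0) || nrow(reg) - k0 < 12) next
    tmpl <- reg[k0:nrow(reg), , drop = FALSE]
    sims <- c(sims, simulatePseudoTracks(mm, tmpl, n = nSim, stack = stack,
                                         seed = seed + 100L + k))
  }
  realDf <- do.call(rbind, atSeaRegs)
  gridded <- gridLocations(realDf, sims, stack)
  filt <- filterContradictions(gridded, windowDays = 2)
  bal <- sampleBalanced(filt, seed = seed + 2L)
  matched <- matchCovariates(bal, stack, covariates = covariates,
                             radiusKm = 15)
  screen <- collinearityScreen(matched, covariates)
  matched <- addRandomControl(matched, seed = seed + 3L)
  modelCovs <- c(screen$kept, "RAND")

  tune <- tuneBRT(matched, modelCovs, foldColumn = "id", grid = tuneGrid,
                  seed = seed + 4L)
  ri <- relativeInfluence(tune$fit)
  truthCovs <- intersect(names(truth$coef), modelCovs)
  infAbove <- ri[truthCovs] > ri["RAND"]

  boots <- bootstrapEnsemble(matched, modelCovs, config = tune$config,
                             n = nBoot, seed = seed + 5L)
  dates <- envDates(stack)
  predDates <- dates[unique(round(seq(10, length(dates) - 5,
                                      length.out = nPredDates)))]
  maps <- predictMaps(boots, stack, predDates)

  # held-out cells: sea cells never visited by a presence
  pres <- gridded[gridded$label == "presence", ]
  visited <- matrix(FALSE, length(envLon(stack)), length(envLat(stack)))
  visited[cbind(pres$ix, pres$iy)] <- TRUE
  heldOut <- !visited & !landMask(stack)
  predVals <- numeric(0); truthVals <- numeric(0)
  for (di in seq_along(predDates)) {
    ts <- truthSuitability(truth, stack, predDates[di])
    pm <- maps@median[, , di]
    ok <- heldOut & is.finite(pm) & is.finite(ts)
    predVals <- c(predVals, pm[ok])
    truthVals <- c(truthVals, ts[ok])
  }
  rho <- cor(predVals, truthVals, method = "spearman")

  accTab <- buildAccessTable(gridded, stack)
  acc <- fitAccessibility(accTab, nBoot = nBoot, seed = seed + 6L)
  dgrid <- seq(acc@boundary[1], acc@boundary[2], length.out = 200)
  Pall <- predictAccess(acc, dgrid, member = "all")
  monotone <- apply(Pall, 2, function(v) all(diff(v) <= 1e-8))

  weighted <- weightPredictions(maps, acc, stack)
  zeroIce <- vapply(seq_along(predDates), function(di) {
    sic <- envLayer(stack, "SIC", predDates[di])
    w <- weighted[, , di]
    idx <- !is.na(sic) & sic > 0.15 & !is.na(w)
    !any(w[idx] != 0)
  }, logical(1))

  list(cvAUC = tune$cv$meanAUC,
       devianceExplained = tune$cv$devianceExplained,
       influence = ri,
       truthCovariates = truthCovs,
       influenceAboveRandom = infAbove,
       spearmanHeldOut = rho,
       accessMonotone = monotone,
       weightedZeroIce = zeroIce,
       screen = screen, tune = tune, maps = maps, weighted = weighted,
       stack = stack, truth = truth, gen = gen,
       nRecords = nrow(matched))
}

#' State-space smoothing benefit experiment
#'
#' Simulates correlated-random-walk tracks with irregular Argos-class
#' observation noise and compares the smoothed-position RMSE against the
#' raw-observation RMSE, both measured against the known truth.
#'
#' @param nTracks Number of replicate tracks.
#' @param nSteps 6-h lattice steps per track.
#' @param gamma,sigmaKm CRW velocity persistence and innovation SD (km per
#'   6 h step).
#' @param noise [argosNoiseSpec()] for observation errors.
#' @param obsMeanGapHours Mean observation gap (h).
#' @param seed Integer seed.
#' @return data.frame with per-replicate `rmseSmoothed` and `rmseRaw` (km).
#' @export
ssmBenefitExperiment <- function(nTracks = 20, nSteps = 40, gamma = 0.8,
                                 sigmaKm = 3, noise = argosNoiseSpec(),
                                 obsMeanGapHours = 2, seed = 1L) {
  .withSeed(seed, {
    lon0 <- -60; lat0 <- -62
    out <- data.frame(rmseSmoothed = numeric(nTracks),
                      rmseRaw = numeric(nTracks))
    for (r in seq_len(nTracks)) {
      vx <- vy <- 0; x <- y <- 0
      xs <- numeric(nSteps + 1); ys <- numeric(nSteps + 1)
      for (k in seq_len(nSteps)) {
        vx <- gamma * vx + rnorm(1, 0, sigmaKm)
        vy <- gamma * vy + rnorm(1, 0, sigmaKm)
        x <- x + vx; y <- y + vy
        xs[k + 1] <- x; ys[k + 1] <- y
      }
      tl <- seq(0, nSteps) * 6 * 3600
      tObs <- sort(runif(max(8, round(nSteps * 6 / obsMeanGapHours)),
                         0, max(tl)))
      xo <- approx(tl, xs, tObs)$y
      yo <- approx(tl, ys, tObs)$y
      cls <- sample(setdiff(names(noise$freq), "Z"), length(tObs),
                    replace = TRUE,
                    prob = noise$freq[setdiff(names(noise$freq), "Z")])
      sdv <- noise$sdKm[cls]
      xn <- xo + rnorm(length(tObs), 0, sdv)
      yn <- yo + rnorm(length(tObs), 0, sdv)
      ll <- .unprojectKm(xn, yn, lon0, lat0)
      segment <- data.frame(
        id = sprintf("sim%02d", r),
        time = as.POSIXct("2019-03-01", tz = "UTC") + tObs,
        lon = ll$lon, lat = ll$lat, lc = cls)
      reg <- suppressWarnings(fitCRWSSM(segment, noise = noise))
      pr <- .projectKm(reg$lon, reg$lat, lon0, lat0)
      # map the lattice back to simulation seconds
      tReg <- as.numeric(reg$time) - as.numeric(as.POSIXct("2019-03-01",
                                                           tz = "UTC"))
      truthX <- approx(tl, xs, tReg)$y
      truthY <- approx(tl, ys, tReg)$y
      out$rmseSmoothed[r] <- sqrt(mean((pr$x - truthX)^2 +
                                         (pr$y - truthY)^2))
      out$rmseRaw[r] <- sqrt(mean((xn - xo)^2 + (yn - yo)^2))
    }
    out
  })
}
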