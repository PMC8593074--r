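# Synthetic study system: a winter shelf-sea world with seasonal sea-ice
# advance, a coastal land mask with haul-out sites, and seals moving by a
# habitat-biased correlated random walk observed through Argos-class noise.
# Every generator is a pure function of (config, seed).

#' Configuration of the synthetic world
#'
#' Defines the grid, calendar and the parameters of the simulated
#' environmental fields. Defaults emulate a 6 x 6 degree maritime-Antarctic
#' shelf region over 120 winter days with sea ice advancing equatorward.
#'
#' @param lonMin,lonMax,latMin,latMax Grid bounds (degrees).
#' @param cellDeg Cell size in degrees (default 0.1).
#' @param startDate First simulated day (UTC).
#' @param nDays Number of daily layers (>= 2).
#' @param corLengthCells Spatial correlation length of the random fields, in
#'   cells.
#' @param iceEdgeLatStart Latitude of the 15% ice contour on day 1.
#' @param iceSeasonalAmplitude Northward advance of the ice edge over the
#'   simulation, in degrees of latitude; 0 freezes the ice field in time.
#' @param sstRange,salRange Approximate south-to-north ranges of sea-surface
#'   temperature (degC) and salinity (PSU).
#' @param landBandDeg Width of the southern coastal land band (degrees).
#' @param islandRadiusDeg Radius of the haul-out island (degrees).
#' @param islandLon,islandLat Island centre; defaults to mid-longitude, 1.2
#'   degrees south of the northern bound.
#' @param chlMissingFraction Fraction of sea chlorophyll values set missing
#'   (emulates sparse ocean-colour coverage).
#' @param seed Integer seed making the world reproducible.
#' @return A list of class `"SyntheticWorldConfig"`.
#' @export
syntheticWorldConfig <- function(lonMin = -63, lonMax = -57,
                                 latMin = -66, latMax = -60,
                                 cellDeg = 0.1,
                                 startDate = as.Date("2019-03-01"),
                                 nDays = 120L,
                                 corLengthCells = 6,
                                 iceEdgeLatStart = -65.4,
                                 iceSeasonalAmplitude = 3.2,
                                 sstRange = c(-1.8, 2.0),
                                 salRange = c(32.2, 34.2),
                                 landBandDeg = 0.3,
                                 islandRadiusDeg = 0.25,
                                 islandLon = NULL, islandLat = NULL,
                                 chlMissingFraction = 0.006,
                                 seed = 1L) {
  stopifnot(cellDeg > 0, nDays >= 2)
  nlon <- round((lonMax - lonMin) / cellDeg)
  nlat <- round((latMax - latMin) / cellDeg)
  if (nlon < 2 || nlat < 2)
    stop("degenerate grid: bounds must span at least 2 cells per axis")
  cfg <- list(
    lonMin = lonMin, lonMax = lonMax, latMin = latMin, latMax = latMax,
    cellDeg = cellDeg, startDate = as.Date(startDate), nDays = as.integer(nDays),
    corLengthCells = corLengthCells,
    iceEdgeLatStart = iceEdgeLatStart,
    iceSeasonalAmplitude = iceSeasonalAmplitude,
    sstRange = sstRange, salRange = salRange,
    landBandDeg = landBandDeg, islandRadiusDeg = islandRadiusDeg,
    islandLon = if (is.null(islandLon)) (lonMin + lonMax) / 2 else islandLon,
    islandLat = if (is.null(islandLat)) latMax - 1.2 else islandLat,
    chlMissingFraction = chlMissingFraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "SyntheticWorldConfig"
  cfg
}

#' Generate the synthetic environmental stack
#'
#' Builds daily fields for SST, SAL, SIC, SIT, SSH, U, V, CHL and MLD plus a
#' static bathymetry (BAT, GEBCO sign convention: negative at sea) and the
#' land mask, on the common grid. Chlorophyll is stored log(x+1)-transformed.
#' The 15% sea-ice contour advances equatorward over the simulated winter;
#' sea-ice thickness is generated as a monotone function of ice fraction
#' plus small noise (so a collinearity screen should discard it).
#'
#' @param config A [syntheticWorldConfig()].
#' @return An [EnvStack-class].
#' @export
generateEnvStack <- function(config) {
  stopifnot(inherits(config, "SyntheticWorldConfig"))
  .withSeed(config$seed, {
    cs <- config$cellDeg
    lon <- seq(config$lonMin + cs / 2, config$lonMax - cs / 2, by = cs)
    lat <- seq(config$latMin + cs / 2, config$latMax - cs / 2, by = cs)
    nlon <- length(lon); nlat <- length(lat)
    dates <- config$startDate + seq_len(config$nDays) - 1L

    # land: southern coastal band plus a haul-out island
    land <- matrix(FALSE, nlon, nlat)
    land[, lat < config$latMin + config$landBandDeg] <- TRUE
    dIsl <- outer(lon, lat, function(lo, la)
      sqrt(((lo - config$islandLon) * cos(la * pi / 180))^2 +
             (la - config$islandLat)^2))
    land[dIsl <= config$islandRadiusDeg] <- TRUE

    # distance to land (km) shapes the bathymetry
    allOpen <- matrix(TRUE, nlon, nlat)
    dLand <- grid_distance_cpp(allOpen, land, lon, lat)
    bat <- -(120 + 40 * pmin(dLand, 30)) + 250 * .smoothField(nlon, nlat, config$corLengthCells)
    bat[!land] <- pmin(bat[!land], -10)
    bat[land] <- 60

    sig <- config$corLengthCells
    latFrac <- matrix(rep((lat - config$latMin) / (config$latMax - config$latMin),
                          each = nlon), nlon, nlat)
    tFrac <- if (config$nDays > 1) (seq_len(config$nDays) - 1) / (config$nDays - 1)
             else 0

    newF <- function() .smoothField(nlon, nlat, sig)
    ar <- 0.85; inn <- sqrt(1 - ar^2)
    fSST <- newF(); fSAL <- newF(); fSSH <- newF(); fU <- newF(); fV <- newF()
    fCHL <- newF(); fMLD <- newF()
    epsIce <- newF()            # static: zero seasonal amplitude => static SIC

    dyn <- lapply(setNames(nm = c("SST", "SAL", "SIC", "SIT", "SSH", "U", "V",
                                  "CHL", "MLD")),
                  function(nm) array(NA_real_, c(nlon, nlat, config$nDays)))

    for (k in seq_len(config$nDays)) {
      if (k > 1) {
        fSST <- ar * fSST + inn * newF(); fSAL <- ar * fSAL + inn * newF()
        fSSH <- ar * fSSH + inn * newF(); fU <- ar * fU + inn * newF()
        fV <- ar * fV + inn * newF(); fCHL <- ar * fCHL + inn * newF()
        fMLD <- ar * fMLD + inn * newF()
      }
      edgeLat <- config$iceEdgeLatStart + config$iceSeasonalAmplitude * tFrac[k]
      sic <- plogis((edgeLat - (latFrac * (config$latMax - config$latMin) +
                                  config$latMin) + 0.35 * epsIce) / 0.25)
      sic <- pmin(pmax(sic, 0), 1)
      sst <- config$sstRange[1] +
        diff(config$sstRange) * latFrac + 1.1 * fSST - 1.2 * tFrac[k]
      sst <- pmax(sst, -1.9)
      sal <- config$salRange[1] + diff(config$salRange) * latFrac + 0.6 * fSAL
      ssh <- 0.25 * fSSH
      u <- 0.18 * fU; v <- 0.18 * fV
      chl <- exp(-0.6 + 0.9 * fCHL)   # mg/m3, right-skewed
      mld <- pmax(35 + 22 * fMLD + 45 * tFrac[k], 5)
      sit <- pmax(sic * (2.0 + 0.15 * fSSH), 0)

      for (nm in c("SST", "SAL", "SIC", "SIT", "SSH", "U", "V", "CHL", "MLD")) {
        m <- switch(nm, SST = sst, SAL = sal, SIC = sic, SIT = sit, SSH = ssh,
                    U = u, V = v, CHL = log1p(chl), MLD = mld)
        m[land] <- NA_real_
        dyn[[nm]][, , k] <- m
      }
    }

    # sparse chlorophyll coverage
    if (config$chlMissingFraction > 0) {
      seaIdx <- which(!land)
      nMiss <- round(config$chlMissingFraction * length(seaIdx) * config$nDays)
      if (nMiss > 0) {
        cells <- sample(seaIdx, nMiss, replace = TRUE)
        days <- sample.int(config$nDays, nMiss, replace = TRUE)
        dyn$CHL[cbind(arrayInd(cells, c(nlon, nlat)), days)] <- NA_real_
      }
    }

    new("EnvStack", lon = lon, lat = lat, dates = dates,
        static = list(BAT = bat), dynamic = dyn, land = land,
        transformed = "CHL")
  })
}

#' Truth model: habitat preference and movement rules
#'
#' The true suitability is a logistic combination of named stack covariates
#' (standardised over sea cells and days); movement prefers high-suitability
#' candidate steps with weight `exp(prefStrength * suitability)`, so
#' `prefStrength = 0` gives an unbiased correlated random walk.
#'
#' @param stack The [EnvStack-class] the seals live in.
#' @param coef Named coefficients on standardised covariates; names must be
#'   stack layers.
#' @param intercept Intercept of the logistic suitability.
#' @param prefStrength Movement bias towards high suitability (>= 0).
#' @param stepMeanKm,stepShape Gamma step-length distribution per 6-h step.
#' @param turnSdDeg SD of the wrapped-normal turning angle (degrees).
#' @param departureHour,arrivalHour Mean local solar hour of haul-out
#'   departures (evening) and arrivals (morning).
#' @param tripMeanLogDays,tripLogSd,tripTrend Log-normal trip-duration
#'   schedule: `meanlog = tripMeanLogDays + tripTrend * daysSinceStart`,
#'   emulating trips lengthening as winter advances.
#' @param pSameSite Probability a trip returns to its departure haul-out.
#' @return A list of class `"TruthModel"`.
#' @export
truthModel <- function(stack, coef = c(SST = -2.0, CHL = 1.5, BAT = 1.0),
                       intercept = 0, prefStrength = 8,
                       stepMeanKm = 15, stepShape = 2, turnSdDeg = 40,
                       departureHour = 19.5, arrivalHour = 7.5,
                       tripMeanLogDays = log(1.0), tripLogSd = 0.8,
                       tripTrend = 0.08, pSameSite = 35 / 243) {
  stopifnot(is(stack, "EnvStack"), prefStrength >= 0)
  missing <- setdiff(names(coef), envLayerNames(stack))
  if (length(missing))
    stop("truth model references covariates absent from the world: ",
         paste(missing, collapse = ", "))
  # standardisation constants over sea cells (subsampled days for dynamics)
  days <- envDates(stack)
  pick <- days[unique(pmax(1, round(seq(1, length(days), length.out = 8))))]
  stats <- lapply(setNames(nm = names(coef)), function(nm) {
    vals <- if (nm %in% names(stack@static)) {
      envLayer(stack, nm)[!landMask(stack)]
    } else {
      unlist(lapply(pick, function(d) envLayer(stack, nm, d)[!landMask(stack)]))
    }
    c(mean = mean(vals, na.rm = TRUE), sd = max(sd(vals, na.rm = TRUE), 1e-9))
  })
  out <- list(coef = coef, intercept = intercept, stats = stats,
              prefStrength = prefStrength, stepMeanKm = stepMeanKm,
              stepShape = stepShape, turnSdDeg = turnSdDeg,
              departureHour = departureHour, arrivalHour = arrivalHour,
              tripMeanLogDays = tripMeanLogDays, tripLogSd = tripLogSd,
              tripTrend = tripTrend, pSameSite = pSameSite)
  class(out) <- "TruthModel"
  out
}

#' True suitability map for one day
#'
#' @param truth A [truthModel()].
#' @param stack The [EnvStack-class].
#' @param date Day to evaluate.
#' @return Matrix `[lon, lat]` of suitability in `[0, 1]`; `NA` on land.
#' @export
truthSuitability <- function(truth, stack, date) {
  stopifnot(inherits(truth, "TruthModel"))
  eta <- matrix(truth$intercept, length(envLon(stack)), length(envLat(stack)))
  for (nm in names(truth$coef)) {
    m <- if (nm %in% names(stack@static)) envLayer(stack, nm)
         else envLayer(stack, nm, date)
    z <- (m - truth$stats[[nm]]["mean"]) / truth$stats[[nm]]["sd"]
    z[is.na(z)] <- 0
    eta <- eta + truth$coef[[nm]] * z
  }
  s <- plogis(eta)
  s[landMask(stack)] <- NA_real_
  s
}

#' Argos location-class error model
#'
#' Isotropic positional error SD (km) and relative frequency per Argos
#' location class. Class Z positions are invalid and carry arbitrary error;
#' they are discarded by the track filter. The SD ladder is configuration,
#' not a measured fact.
#'
#' @param sdKm Named error SDs (km) for classes 3, 2, 1, 0, A, B, Z.
#' @param freq Named class frequencies (normalised to sum to 1).
#' @return A list of class `"ArgosNoiseSpec"`.
#' @export
argosNoiseSpec <- function(sdKm = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                    `0` = 4, A = 6, B = 10, Z = 80),
                           freq = c(`3` = 0.10, `2` = 0.15, `1` = 0.20,
                                    `0` = 0.15, A = 0.15, B = 0.20,
                                    Z = 0.05)) {
  stopifnot(all(sdKm >= 0), all(freq >= 0), sum(freq) > 0)
  freq <- freq / sum(freq)
  out <- list(sdKm = sdKm, freq = freq)
  class(out) <- "ArgosNoiseSpec"
  out
}

# haul-out sites: coastal sea cells next to island land, spread in longitude
.defaultSites <- function(stack, n = 3) {
  land <- landMask(stack)
  nlon <- nrow(land); nlat <- ncol(land)
  # island cells = land in the northern half
  northern <- land & matrix(rep(seq_len(nlat) > nlat / 2, each = nlon),
                            nlon, nlat)
  coastal <- which(northern, arr.ind = TRUE)
  if (nrow(coastal) == 0) coastal <- which(land, arr.ind = TRUE)
  seaNbr <- t(apply(coastal, 1, function(rc) {
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      i <- rc[1] + d[1]; j <- rc[2] + d[2]
      if (i >= 1 && i <= nlon && j >= 1 && j <= nlat && !land[i, j])
        return(c(i, j))
    }
    c(NA_integer_, NA_integer_)
  }))
  ok <- !is.na(seaNbr[, 1])
  seaNbr <- unique(seaNbr[ok, , drop = FALSE])
  if (nrow(seaNbr) == 0) stop("no coastal sea cells found for haul-out sites")
  ord <- order(envLon(stack)[seaNbr[, 1]])
  pickRows <- seaNbr[ord[unique(round(seq(1, nrow(seaNbr),
                                          length.out = min(n, nrow(seaNbr)))))],
                     , drop = FALSE]
  data.frame(site = seq_len(nrow(pickRows)),
             lon = envLon(stack)[pickRows[, 1]],
             lat = envLat(stack)[pickRows[, 2]])
}

# next timestamp after `after` whose local solar hour is drawn around
# `hourMean` (local = UTC + lon/15)
.nextAtLocalHour <- function(after, lon, hourMean, hourSd) {
  h <- rnorm(1, hourMean, hourSd) %% 24
  utcH <- (h - lon / 15) %% 24
  base <- as.POSIXct(format(after, "%Y-%m-%d", tz = "UTC"), tz = "UTC")
  cand <- base + utcH * 3600
  while (cand <= after) cand <- cand + 86400
  cand
}

#' Simulate tracked seals
#'
#' Simulates `n` individuals alternating haul-out residency with at-sea trips
#' on a 6-hour lattice. Movement is a correlated random walk biased towards
#' high true suitability by weighted sampling among candidate steps; trips
#' depart in the evening and arrive in the morning (local solar time), with
#' durations lengthening over the season. Observations are irregular
#' Argos-style fixes: the true position at the fix time plus class-dependent
#' isotropic noise. Dive-tagged individuals also yield daily dive records.
#'
#' @param stack The [EnvStack-class] world (must cover the tracking period).
#' @param truth A [truthModel()].
#' @param n Number of individuals.
#' @param noise An [argosNoiseSpec()].
#' @param seed Integer seed.
#' @param durationRange Track duration range in days (clipped to the world).
#' @param obsMeanGapHours Mean gap between Argos fixes (h).
#' @param nCandidates Candidate steps scored per move.
#' @param nDiveTags Number of individuals carrying depth sensors.
#' @param sites Optional haul-out site table (`site`, `lon`, `lat`).
#' @return List with elements `obs` (Argos fixes: `id`, `time`, `lon`, `lat`,
#'   `lc`), `truth` (true 6-h paths with `hauledOut` flag), `trips` (true
#'   trip log), `dives`, `sites`, and `suitUsedAvail` (per-individual mean
#'   suitability of chosen vs offered candidate steps, for bias checks).
#' @export
generateTracks <- function(stack, truth, n = 15, noise = argosNoiseSpec(),
                           seed = 1L, durationRange = c(26, 197),
                           obsMeanGapHours = 2, nCandidates = 20,
                           nDiveTags = max(0L, round(n / 3)),
                           sites = NULL) {
  stopifnot(is(stack, "EnvStack"), inherits(truth, "TruthModel"))
  missing <- setdiff(names(truth$coef), envLayerNames(stack))
  if (length(missing))
    stop("truth model references covariates absent from the world: ",
         paste(missing, collapse = ", "))
  .withSeed(seed, {
    if (is.null(sites)) sites <- .defaultSites(stack)
    dates <- envDates(stack)
    worldStart <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")
    worldEnd <- as.POSIXct(paste(dates[length(dates)], "23:59:59"), tz = "UTC")
    maxDays <- as.integer(length(dates)) - 1L
    suitCache <- new.env(parent = emptyenv())
    suitAt <- function(date) {
      key <- format(date)
      if (is.null(suitCache[[key]]))
        suitCache[[key]] <- truthSuitability(truth, stack, date)
      suitCache[[key]]
    }
    cellSuit <- function(lon, lat, date) {
      s <- suitAt(date)
      ci <- cellIndex(stack, lon, lat)
      out <- rep(NA_real_, length(lon))
      ok <- !is.na(ci$ix) & !is.na(ci$iy)
      out[ok] <- s[cbind(ci$ix[ok], ci$iy[ok])]
      out
    }
    maxStep <- truth$stepMeanKm * 2.5
    turnSd <- truth$turnSdDeg * pi / 180

    obsL <- list(); truthL <- list(); tripL <- list(); diveL <- list()
    usedAvail <- data.frame(id = character(), used = numeric(),
                            avail = numeric())

    for (ind in seq_len(n)) {
      id <- sprintf("seal%02d", ind)
      dur <- .sample1(seq(min(durationRange[1], maxDays),
                          min(durationRange[2], maxDays)))
      t0 <- worldStart + runif(1, 0, 48) * 3600
      tEnd <- min(t0 + dur * 86400, worldEnd)
      lattice <- seq(t0, tEnd, by = 6 * 3600)
      site <- sites[sample.int(nrow(sites), 1), ]
      pos <- matrix(NA_real_, length(lattice), 2)  # lon, lat
      hauled <- logical(length(lattice))
      heading <- runif(1, -pi, pi)
      cur <- c(site$lon, site$lat)
      sumUsed <- 0; sumAvail <- 0; nSteps <- 0

      tCursor <- t0
      k <- 1L
      while (tCursor < tEnd && k <= length(lattice)) {
        # haul-out residency until the next evening departure
        rest <- rlnorm(1, log(10), 0.5) * 3600
        dep <- .nextAtLocalHour(tCursor + rest, site$lon,
                                truth$departureHour, 1.5)
        daysSince <- as.numeric(difftime(dep, worldStart, units = "days"))
        tripDur <- min(rlnorm(1, truth$tripMeanLogDays +
                                truth$tripTrend * daysSince,
                              truth$tripLogSd), 90)
        arr <- dep + tripDur * 86400
        arr <- .nextAtLocalHour(arr - 12 * 3600, site$lon,
                                truth$arrivalHour, 1.5)
        if (arr <= dep + 2 * 3600) arr <- arr + 86400
        if (arr > tEnd) arr <- tEnd
        dest <- if (runif(1) < truth$pSameSite || nrow(sites) == 1) site
                else sites[.sample1(setdiff(seq_len(nrow(sites)), site$site)), ]

        while (k <= length(lattice) && lattice[k] < dep) {
          pos[k, ] <- c(site$lon, site$lat); hauled[k] <- TRUE; k <- k + 1L
        }
        # trip on the 6-h lattice
        cur <- c(site$lon, site$lat)
        tripPos <- NULL
        transitLeft <- 0L; transitHeading <- heading
        while (k <= length(lattice) && lattice[k] < arr) {
          date <- as.Date(lattice[k], tz = "UTC")
          stepsLeft <- max(1, ceiling(as.numeric(difftime(arr, lattice[k],
                                                          units = "hours")) / 6))
          dDest <- haversineKm(cur[1], cur[2], dest$lon, dest$lat)
          mustHome <- stepsLeft * truth$stepMeanKm < 1.4 * dDest
          # directed multi-day relocations between foraging areas: pick the
          # long-range bearing with the best habitat (uniform when the
          # preference strength is zero)
          if (!mustHome && transitLeft == 0L && runif(1) < 0.05) {
            bearings <- seq(0, 2 * pi, length.out = 13)[-13]
            far <- .unprojectKm(120 * cos(bearings), 120 * sin(bearings),
                                cur[1], cur[2])
            okB <- atSea(stack, far$lon, far$lat)
            if (any(okB)) {
              sv <- cellSuit(far$lon[okB], far$lat[okB], date)
              sv[is.na(sv)] <- 0
              pickB <- sample(seq_along(sv), 1,
                              prob = exp(truth$prefStrength * sv))
              transitHeading <- bearings[okB][pickB]
              transitLeft <- 4L + rpois(1, 8)
            }
          }
          if (!mustHome && transitLeft > 0L) {
            hd <- transitHeading + rnorm(1, 0, 0.15)
            stepKm <- truth$stepMeanKm * runif(1, 0.8, 1.3)
            nxt <- .unprojectKm(stepKm * cos(hd), stepKm * sin(hd),
                                cur[1], cur[2])
            if (atSea(stack, nxt$lon, nxt$lat)) {
              cur <- c(nxt$lon, nxt$lat); heading <- hd
              transitLeft <- transitLeft - 1L
            } else {
              transitLeft <- 0L
            }
            pos[k, ] <- cur
            tripPos <- rbind(tripPos, cur)
            k <- k + 1L
            next
          }
          if (mustHome) {
            # steer home
            hd <- .stepHeading(cur[1], cur[2], dest$lon, dest$lat)
            stepKm <- min(maxStep, dDest)
            nxt <- .unprojectKm(stepKm * cos(hd), stepKm * sin(hd),
                                cur[1], cur[2])
            if (!atSea(stack, nxt$lon, nxt$lat)) {
              # slide along the coast
              for (tryAng in c(0.5, -0.5, 1, -1, 1.5, -1.5)) {
                nxt2 <- .unprojectKm(stepKm * cos(hd + tryAng),
                                     stepKm * sin(hd + tryAng),
                                     cur[1], cur[2])
                if (atSea(stack, nxt2$lon, nxt2$lat)) { nxt <- nxt2; break }
              }
            }
            if (atSea(stack, nxt$lon, nxt$lat)) {
              cur <- c(nxt$lon, nxt$lat); heading <- hd
            }
          } else {
            # area-restricted search: high suitability slows the seal and
            # loosens heading persistence (vanishes when prefStrength = 0)
            sHere <- cellSuit(cur[1], cur[2], date)
            if (is.na(sHere)) sHere <- 0
            slow <- exp(-0.4 * truth$prefStrength * sHere)
            base <- rgamma(nCandidates, shape = truth$stepShape,
                           scale = truth$stepMeanKm / truth$stepShape)
            steps <- slow * base
            turns <- rnorm(nCandidates, 0, turnSd * (1 + 1.5 * (1 - slow)))
            # transit bursts: long, omnidirectional candidate steps that
            # ignore the local foraging slowdown, enabling directed moves
            # towards better habitat at the perception range
            scout <- runif(nCandidates) < 0.3
            steps[scout] <- base[scout] * 3
            turns[scout] <- runif(sum(scout), -pi, pi)
            hds <- heading + turns
            cand <- .unprojectKm(steps * cos(hds), steps * sin(hds),
                                 cur[1], cur[2])
            valid <- atSea(stack, cand$lon, cand$lat)
            if (!any(valid)) {
              turns <- runif(nCandidates, -pi, pi)
              hds <- heading + turns
              cand <- .unprojectKm(steps * cos(hds), steps * sin(hds),
                                   cur[1], cur[2])
              valid <- atSea(stack, cand$lon, cand$lat)
            }
            if (any(valid)) {
              sv <- cellSuit(cand$lon[valid], cand$lat[valid], date)
              sv[is.na(sv)] <- 0
              w <- exp(truth$prefStrength * sv)
              pick <- sample(seq_along(w), 1, prob = w)
              iv <- which(valid)[pick]
              sumUsed <- sumUsed + sv[pick]
              sumAvail <- sumAvail + mean(sv)
              nSteps <- nSteps + 1
              cur <- c(cand$lon[iv], cand$lat[iv])
              heading <- hds[iv]
            }
          }
          pos[k, ] <- cur
          tripPos <- rbind(tripPos, cur)
          k <- k + 1L
        }
        if (!is.null(tripPos)) {
          tripL[[length(tripL) + 1L]] <- data.frame(
            id = id, departure = dep, arrival = arr,
            fromSite = site$site, toSite = dest$site,
            durationDays = as.numeric(difftime(arr, dep, units = "days")),
            roundTrip = site$site == dest$site,
            midLon = mean(tripPos[, 1]), midLat = mean(tripPos[, 2]),
            midDate = as.Date(dep + (arr - dep) / 2, tz = "UTC")
          )
        }
        site <- dest
        tCursor <- arr
      }
      while (k <= length(lattice)) {   # finish hauled out
        pos[k, ] <- c(site$lon, site$lat); hauled[k] <- TRUE; k <- k + 1L
      }

      truthL[[ind]] <- data.frame(id = id, time = lattice,
                                  lon = pos[, 1], lat = pos[, 2],
                                  hauledOut = hauled)
      usedAvail <- rbind(usedAvail, data.frame(
        id = id, used = if (nSteps > 0) sumUsed / nSteps else NA_real_,
        avail = if (nSteps > 0) sumAvail / nSteps else NA_real_))

      # --- Argos observations ---
      tObs <- numeric(0)
      tc <- as.numeric(t0)
      while (tc < as.numeric(tEnd)) {
        gap <- if (runif(1) < 0.06) runif(1, 20, 110)
               else rexp(1, 1 / (obsMeanGapHours * 3600))
        tc <- tc + gap
        tObs <- c(tObs, tc)
      }
      tObs <- tObs[tObs <= as.numeric(tEnd)]
      if (length(tObs) < 2) next
      tl <- as.numeric(lattice)
      oLon <- approx(tl, pos[, 1], xout = tObs, rule = 2)$y
      oLat <- approx(tl, pos[, 2], xout = tObs, rule = 2)$y
      lc <- sample(names(noise$freq), length(tObs), replace = TRUE,
                   prob = noise$freq)
      sdv <- noise$sdKm[lc]
      oLat2 <- oLat + rnorm(length(tObs), 0, sdv / 110.574)
      oLon2 <- oLon + rnorm(length(tObs), 0, sdv /
                              (111.320 * cos(oLat * pi / 180)))
      obsL[[ind]] <- data.frame(
        id = id,
        time = as.POSIXct(tObs, origin = "1970-01-01", tz = "UTC"),
        lon = oLon2, lat = oLat2, lc = lc, trueLon = oLon, trueLat = oLat)

      # --- dives ---
      if (ind <= nDiveTags) {
        trackDates <- unique(as.Date(lattice[!hauled], tz = "UTC"))
        if (length(trackDates)) {
          dv <- do.call(rbind, lapply(trackDates, function(d) {
            since <- as.numeric(d - dates[1])
            m <- max(8, rnorm(1, 40 + 0.35 * since, 8))
            depths <- c(m, m * rbeta(5, 2, 1))
            data.frame(id = id, date = d, depth_m = depths)
          }))
          diveL[[length(diveL) + 1L]] <- dv
        }
      }
    }

    list(obs = do.call(rbind, obsL),
         truth = do.call(rbind, truthL),
         trips = do.call(rbind, tripL),
         dives = if (length(diveL)) do.call(rbind, diveL) else NULL,
         sites = sites,
         suitUsedAvail = usedAvail)
  })
}

#' Simulate haul-out transect counts
#'
#' Per haul-out and census, a Poisson total of seals is spread over parallel
#' beach transects and classified by a multinomial over age classes. Default
#' class composition approximates juveniles 49.7%, sub-adults 36.5%, adults
#' 13.7%.
#'
#' @param nHaulouts,nCensuses,nTransects Survey design (7 transects per
#'   census by default).
#' @param meanTotals Expected seals per haul-out per census (recycled).
#' @param classProbs Named class probabilities (normalised; must be >= 0).
#' @param seed Integer seed.
#' @return `data.frame` with `haulout`, `census`, `transect` and per-class
#'   counts.
#' @export
generateTransectCounts <- function(nHaulouts = 3, nCensuses = 2,
                                   nTransects = 7,
                                   meanTotals = c(52, 140, 79),
                                   classProbs = c(juvenile = 0.497,
                                                  subadult = 0.365,
                                                  adult = 0.137),
                                   seed = 1L) {
  stopifnot(nHaulouts >= 1, nTransects >= 1)
  if (any(classProbs < 0)) stop("negative class probabilities")
  if (sum(classProbs) <= 0) stop("class probabilities must sum > 0")
  classProbs <- classProbs / sum(classProbs)
  meanTotals <- rep_len(meanTotals, nHaulouts)
  .withSeed(seed, {
    rows <- list()
    for (h in seq_len(nHaulouts)) for (cns in seq_len(nCensuses)) {
      total <- if (meanTotals[h] > 0) rpois(1, meanTotals[h]) else 0L
      perTransect <- if (total > 0)
        as.integer(rmultinom(1, total, rep(1, nTransects)))
      else integer(nTransects)
      for (tr in seq_len(nTransects)) {
        cls <- if (perTransect[tr] > 0)
          as.integer(rmultinom(1, perTransect[tr], classProbs))
        else integer(length(classProbs))
        rows[[length(rows) + 1L]] <- data.frame(
          haulout = h, census = cns, transect = tr,
          juveniles = cls[1], subadults = cls[2], adults = cls[3])
      }
    }
    do.call(rbind, rows)
  })
}
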