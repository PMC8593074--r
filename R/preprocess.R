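# Argos track cleaning and regularization. Tracks are data.frames with
# columns id, time (POSIXct UTC), lon, lat, lc (Argos class 3/2/1/0/A/B/Z)
# and optional extras, sorted by time within individual.

.checkSorted <- function(track) {
  if (nrow(track) > 1) {
    for (ind in unique(track$id)) {
      tt <- track$time[track$id == ind]
      if (is.unsorted(as.numeric(tt)))
        stop("track must be sorted by time within individual")
    }
  }
  invisible(track)
}

#' Remove near-duplicate Argos fixes
#'
#' Sequential scan per individual keeping the first fix of any run: a fix is
#' dropped iff it occurs `window` seconds or less after the most recently
#' kept fix of the same individual.
#'
#' @param track Sorted track data.frame.
#' @param window Threshold in seconds (default 120 s, i.e. 2 minutes or
#'   less).
#' @return The thinned track (a subsequence of the input).
#' @export
removeNearDuplicates <- function(track, window = 120) {
  .checkSorted(track)
  if (nrow(track) == 0) return(track)
  keepRows <- unlist(lapply(split(seq_len(nrow(track)), track$id), function(ix) {
    tt <- as.numeric(track$time[ix])
    keep <- logical(length(ix))
    lastKept <- -Inf
    for (k in seq_along(ix)) {
      if (tt[k] - lastKept > window) {
        keep[k] <- TRUE
        lastKept <- tt[k]
      }
    }
    ix[keep]
  }), use.names = FALSE)
  track[sort(keepRows), , drop = FALSE]
}

# implied great-circle speeds (m/s) between consecutive fixes
.trackSpeeds <- function(lon, lat, tt) {
  n <- length(lon)
  d <- haversineKm(lon[-n], lat[-n], lon[-1], lat[-1]) * 1000
  dt <- diff(tt)
  d / pmax(dt, 1e-9)
}

# inner angle (degrees) at the middle fix of each consecutive triple, via the
# planar law of cosines on great-circle side lengths, plus the two leg
# lengths (km). Returns NA angles at the two track ends.
.spikeGeometry <- function(lon, lat) {
  n <- length(lon)
  ang <- rep(NA_real_, n); leg1 <- rep(NA_real_, n); leg2 <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    a <- haversineKm(lon[i - 1], lat[i - 1], lon[i], lat[i])
    c2 <- haversineKm(lon[i], lat[i], lon[i + 1], lat[i + 1])
    b <- haversineKm(lon[i - 1], lat[i - 1], lon[i + 1], lat[i + 1])
    cosA <- (a^2 + c2^2 - b^2) / pmax(2 * a * c2, 1e-12)
    ang[i] <- acos(pmin(pmax(cosA, -1), 1)) * 180 / pi
    leg1[i] <- a; leg2[i] <- c2
  }
  list(angle = ang, leg1 = leg1, leg2 = leg2)
}

#' Speed-distance-angle filter
#'
#' Removes invalid (class Z) fixes, fixes implying unrealistic travel speeds,
#' and spike fixes: an internal fix whose inner turning angle is below an
#' angle threshold while both adjacent legs exceed the paired length
#' threshold. Spike removal and speed checks are iterated to convergence, so
#' the retained track satisfies all rules simultaneously.
#'
#' @param track Sorted track data.frame (near-duplicates already removed).
#' @param vmax Maximum plausible speed in m/s (default 3).
#' @param spikeRules Two-column matrix of (angle degrees, leg km) pairs;
#'   default removes spikes sharper than 15 degrees with legs > 2.5 km and
#'   sharper than 25 degrees with legs > 5 km.
#' @return Filtered track, a subsequence of the input.
#' @export
sdaFilter <- function(track, vmax = 3,
                      spikeRules = cbind(angle = c(15, 25),
                                         dist = c(2.5, 5))) {
  .checkSorted(track)
  if ("lc" %in% names(track)) track <- track[track$lc != "Z", , drop = FALSE]
  if (nrow(track) == 0) return(track)
  out <- lapply(split(track, track$id), function(tr) {
    if (nrow(tr) < 2) return(tr)
    repeat {
      n <- nrow(tr)
      if (n < 2) break
      spd <- .trackSpeeds(tr$lon, tr$lat, as.numeric(tr$time))
      bad <- which(spd > vmax)
      if (length(bad)) {
        # a bad fix typically violates on both adjacent legs; drop the fix
        # involved in most violations (ties: the later fix)
        involve <- tabulate(c(bad, bad + 1), nbins = n)
        involve[1] <- involve[1] - 0.5   # prefer keeping the anchor fix
        drop <- max(which(involve == max(involve)))
        tr <- tr[-drop, , drop = FALSE]
        next
      }
      if (n >= 3) {
        g <- .spikeGeometry(tr$lon, tr$lat)
        isSpike <- rep(FALSE, n)
        for (r in seq_len(nrow(spikeRules)))
          isSpike <- isSpike | (!is.na(g$angle) &
                                  g$angle < spikeRules[r, 1] &
                                  g$leg1 > spikeRules[r, 2] &
                                  g$leg2 > spikeRules[r, 2])
        if (any(isSpike)) {
          tr <- tr[-which(isSpike)[1], , drop = FALSE]
          next
        }
      }
      break
    }
    tr
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a track at large data gaps
#'
#' Gaps strictly in excess of `maxGapDays` split the track into segments
#' treated independently downstream; a gap of exactly `maxGapDays` does not
#' split.
#'
#' @param track Sorted track data.frame (single individual or several).
#' @param maxGapDays Gap threshold in days (default 7).
#' @return List of track segments; concatenating them reconstructs the
#'   input. Each segment carries a `segment` column `"<id>_<k>"`.
#' @export
splitOnGaps <- function(track, maxGapDays = 7) {
  .checkSorted(track)
  segs <- list()
  for (ind in unique(track$id)) {
    tr <- track[track$id == ind, , drop = FALSE]
    gaps <- diff(as.numeric(tr$time)) > maxGapDays * 86400
    segId <- cumsum(c(1L, as.integer(gaps)))
    for (s in unique(segId)) {
      part <- tr[segId == s, , drop = FALSE]
      part$segment <- sprintf("%s_%d", ind, s)
      rownames(part) <- NULL
      segs[[length(segs) + 1L]] <- part
    }
  }
  segs
}

# ---------------------------------------------------------------------------
# Correlated-random-walk state-space smoother
#
# Discrete-time CRW on a local planar projection: per dimension the state is
# (position, velocity km/6h); over an interval of f six-hour units
#   x' = x + f * v
#   v' = gamma^f * v + eta,  Var(eta) = sigma^2 * f
# Observations are position plus Gaussian error with class-fixed SD.
# gamma and sigma are estimated by maximum likelihood (Kalman filter), and
# states at the regular 6-h lattice are extracted from a fixed-interval
# (RTS) smoother.
# ---------------------------------------------------------------------------

# Kalman filter + RTS smoother for one dimension over event times.
# obsIdx[i] = event index of observation i.
.kalman1d <- function(z, tau, eventDt6, obsIdx, gamma, sigma, x0, v0,
                      smooth = TRUE) {
  nE <- length(eventDt6) + 1L
  m <- matrix(0, nE, 2); P <- array(0, c(2, 2, nE))
  mPred <- matrix(0, nE, 2); PPred <- array(0, c(2, 2, nE))
  m[1, ] <- c(x0, v0)
  P[, , 1] <- diag(c(tau[1]^2 + 1, 4))
  mPred[1, ] <- m[1, ]; PPred[, , 1] <- P[, , 1]
  Tmats <- vector("list", nE - 1L)
  ll <- 0
  obsAt <- split(seq_along(z), obsIdx)
  applyObs <- function(k, mk, Pk) {
    for (i in obsAt[[as.character(k)]]) {
      S <- Pk[1, 1] + tau[i]^2
      K <- Pk[, 1] / S
      innov <- z[i] - mk[1]
      ll <<- ll - 0.5 * (log(2 * pi * S) + innov^2 / S)
      mk <- mk + K * innov
      Pk <- Pk - outer(K, K) * S
    }
    list(m = mk, P = Pk)
  }
  if (!is.null(obsAt[["1"]])) {
    up <- applyObs(1L, m[1, ], P[, , 1])
    m[1, ] <- up$m; P[, , 1] <- up$P
  }
  for (k in 2:nE) {
    f <- eventDt6[k - 1]
    Tk <- matrix(c(1, 0, f, gamma^f), 2, 2)
    Q <- matrix(c(1e-8, 0, 0, sigma^2 * f), 2, 2)
    Tmats[[k - 1L]] <- Tk
    mp <- as.vector(Tk %*% m[k - 1, ])
    Pp <- Tk %*% P[, , k - 1] %*% t(Tk) + Q
    mPred[k, ] <- mp; PPred[, , k] <- Pp
    if (!is.null(obsAt[[as.character(k)]])) {
      up <- applyObs(k, mp, Pp)
      m[k, ] <- up$m; P[, , k] <- up$P
    } else {
      m[k, ] <- mp; P[, , k] <- Pp
    }
  }
  if (!smooth) return(list(ll = ll))
  ms <- m; Ps <- P
  for (k in (nE - 1L):1L) {
    Ck <- P[, , k] %*% t(Tmats[[k]]) %*% solve(PPred[, , k + 1] +
                                                 diag(1e-10, 2))
    ms[k, ] <- m[k, ] + as.vector(Ck %*% (ms[k + 1, ] - mPred[k + 1, ]))
    Ps[, , k] <- P[, , k] + Ck %*% (Ps[, , k + 1] - PPred[, , k + 1]) %*% t(Ck)
  }
  list(ll = ll, m = ms, P = Ps)
}

#' Regularize a track segment with a CRW state-space smoother
#'
#' Estimates positions on the regular 6-hour lattice spanning the segment,
#' with per-position uncertainty, under a correlated-random-walk process
#' model and Argos-class-fixed Gaussian measurement error. Velocity
#' persistence and process variance are estimated by maximum likelihood;
#' optimisation is retried from new starting values on failure and
#' non-converged segments are flagged.
#'
#' @param segment One track segment (single individual, sorted).
#' @param stepHours Lattice spacing in hours (default 6).
#' @param noise An [argosNoiseSpec()] giving per-class error SDs (km).
#' @param maxRetries Re-initialisations attempted on failed convergence.
#' @return data.frame `id`, `segment`, `time`, `lon`, `lat`, `seKm` with
#'   attributes `gamma`, `sigma`, `converged`.
#' @export
fitCRWSSM <- function(segment, stepHours = 6, noise = argosNoiseSpec(),
                      maxRetries = 3) {
  .checkSorted(segment)
  if (nrow(segment) < 4)
    stop("segment must have at least 4 fixes")
  tt <- as.numeric(segment$time)
  stepSec <- stepHours * 3600
  if (tt[length(tt)] - tt[1] < 2 * stepSec)
    stop("segment must span at least 2 lattice steps")
  lonRef <- mean(segment$lon); latRef <- mean(segment$lat)
  pr <- .projectKm(segment$lon, segment$lat, lonRef, latRef)
  tau <- if ("lc" %in% names(segment))
    pmax(noise$sdKm[as.character(segment$lc)], 1e-3)
  else rep(1, nrow(segment))
  tau[is.na(tau)] <- max(noise$sdKm, 1)

  lattice <- seq(tt[1], tt[length(tt)], by = stepSec)
  events <- sort(unique(c(tt, lattice)))
  obsIdx <- match(tt, events)
  eventDt6 <- diff(events) / stepSec
  latticeIdx <- match(lattice, events)

  negll <- function(par) {
    g <- plogis(par[1]); s <- exp(par[2])
    a <- .kalman1d(pr$x, tau, eventDt6, obsIdx, g, s, pr$x[1], 0,
                   smooth = FALSE)$ll
    b <- .kalman1d(pr$y, tau, eventDt6, obsIdx, g, s, pr$y[1], 0,
                   smooth = FALSE)$ll
    v <- -(a + b)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(c(qlogis(0.7), log(3)), c(qlogis(0.3), log(8)),
                 c(qlogis(0.9), log(1)), c(qlogis(0.5), log(15)))
  fit <- NULL; converged <- FALSE
  for (st in starts[seq_len(min(maxRetries + 1L, length(starts)))]) {
    f <- tryCatch(optim(st, negll, method = "Nelder-Mead",
                        control = list(maxit = 400)),
                  error = function(e) NULL)
    if (!is.null(f) && is.finite(f$value)) {
      if (is.null(fit) || f$value < fit$value) fit <- f
      if (f$convergence == 0) { converged <- TRUE; fit <- f; break }
    }
  }
  if (is.null(fit)) {
    warning("CRW state-space fit failed to converge; segment excluded")
    return(NULL)
  }
  if (!converged)
    warning("CRW state-space fit flagged as non-converged; best value kept")
  g <- plogis(fit$par[1]); s <- exp(fit$par[2])
  sx <- .kalman1d(pr$x, tau, eventDt6, obsIdx, g, s, pr$x[1], 0)
  sy <- .kalman1d(pr$y, tau, eventDt6, obsIdx, g, s, pr$y[1], 0)
  xs <- sx$m[latticeIdx, 1]; ys <- sy$m[latticeIdx, 1]
  se <- sqrt(pmax((sx$P[1, 1, latticeIdx] + sy$P[1, 1, latticeIdx]) / 2, 0))
  ll <- .unprojectKm(xs, ys, lonRef, latRef)
  out <- data.frame(
    id = segment$id[1],
    segment = if ("segment" %in% names(segment)) segment$segment[1]
              else paste0(segment$id[1], "_1"),
    time = as.POSIXct(lattice, origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat, seKm = se)
  attr(out, "gamma") <- g
  attr(out, "sigma") <- s
  attr(out, "converged") <- converged
  out
}

# connected components of the land mask (4-neighbour flood fill)
.landComponents <- function(land) {
  comp <- matrix(0L, nrow(land), ncol(land))
  cur <- 0L
  for (start in which(land & comp == 0L)) {
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    nlon <- nrow(land)
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      i <- (c0 - 1L) %% nlon + 1L; j <- (c0 - 1L) %/% nlon + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 >= 1 && i2 <= nlon && j2 >= 1 && j2 <= ncol(land)) {
          c2 <- i2 + (j2 - 1L) * nlon
          if (land[c2] && comp[c2] == 0L) {
            comp[c2] <- cur
            queue <- c(queue, c2)
          }
        }
      }
    }
  }
  comp
}

#' Detect haul-out intervals on a regularized track
#'
#' A reproducible surrogate for visual haul-out identification: maximal runs
#' of positions within `radiusKm` of a land-cell centre (honouring a logical
#' `dry` column when present) lasting at least `minHours`.
#'
#' @param reg Regularized track (from [fitCRWSSM()]).
#' @param stack [EnvStack-class] providing the land mask.
#' @param radiusKm Coast proximity radius (default 5 km).
#' @param minHours Minimum residency duration (default 6 h).
#' @param sites Optional site table (`site`, `lon`, `lat`); haul-outs are
#'   labelled by the nearest site, otherwise by nearest land component.
#' @return data.frame of intervals: `id`, `segment`, `start`, `end`, `site`,
#'   `lon`, `lat`; zero rows if the track never approaches the coast.
#' @export
detectHaulouts <- function(reg, stack, radiusKm = 5, minHours = 6,
                           sites = NULL) {
  if (is.null(reg) || nrow(reg) == 0)
    return(data.frame(id = character(), segment = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      site = integer(), lon = numeric(), lat = numeric()))
  land <- landMask(stack)
  landIdx <- which(land, arr.ind = TRUE)
  if (nrow(landIdx) == 0) return(detectHaulouts(reg[0, ], stack))
  ll <- cbind(envLon(stack)[landIdx[, 1]], envLat(stack)[landIdx[, 2]])
  nearDist <- vapply(seq_len(nrow(reg)), function(k) {
    min(haversineKm(reg$lon[k], reg$lat[k], ll[, 1], ll[, 2]))
  }, numeric(1))
  # distance to the coast is taken to the land-cell boundary: centre
  # distance minus half the cell diagonal at the position's latitude
  cs <- envCellSize(stack)
  halfDiag <- 0.5 * sqrt((cs * 111.320 * cos(reg$lat * pi / 180))^2 +
                           (cs * 110.574)^2)
  near <- pmax(nearDist - halfDiag, 0) <= radiusKm
  if ("dry" %in% names(reg)) near <- near & reg$dry
  r <- rle(near)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  comp <- NULL
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (as.numeric(difftime(reg$time[i1], reg$time[i0], units = "hours")) <
        minHours) next
    mlon <- mean(reg$lon[i0:i1]); mlat <- mean(reg$lat[i0:i1])
    if (!is.null(sites)) {
      siteId <- sites$site[which.min(haversineKm(mlon, mlat, sites$lon,
                                                 sites$lat))]
    } else {
      if (is.null(comp)) comp <- .landComponents(land)
      j <- which.min(haversineKm(mlon, mlat, ll[, 1], ll[, 2]))
      siteId <- comp[landIdx[j, 1], landIdx[j, 2]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = reg$id[1],
      segment = if ("segment" %in% names(reg)) reg$segment[1] else NA,
      start = reg$time[i0], end = reg$time[i1],
      site = siteId, lon = mlon, lat = mlat)
  }
  if (!length(rows)) return(detectHaulouts(reg[0, ], stack))
  do.call(rbind, rows)
}

#' Segment trips between haul-outs
#'
#' One trip per inter-haul-out gap containing at least one at-sea position.
#' A trip is a round trip iff it departs from and arrives at the same
#' haul-out.
#'
#' @param reg Regularized track.
#' @param haulouts Non-overlapping, sorted intervals from
#'   [detectHaulouts()].
#' @return data.frame of trips: `id`, `departure`, `arrival`, `fromSite`,
#'   `toSite`, `durationDays`, `roundTrip`, `midLon`, `midLat`, `midDate`.
#' @export
segmentTrips <- function(reg, haulouts) {
  empty <- data.frame(id = character(), departure = as.POSIXct(character(), tz = "UTC"),
                      arrival = as.POSIXct(character(), tz = "UTC"),
                      fromSite = integer(), toSite = integer(),
                      durationDays = numeric(), roundTrip = logical(),
                      midLon = numeric(), midLat = numeric(),
                      midDate = as.Date(character()))
  if (is.null(haulouts) || nrow(haulouts) < 2) return(empty)
  haulouts <- haulouts[order(haulouts$start), , drop = FALSE]
  if (any(haulouts$start[-1] < haulouts$end[-nrow(haulouts)]))
    stop("haul-out intervals must be non-overlapping")
  rows <- list()
  for (k in seq_len(nrow(haulouts) - 1L)) {
    dep <- haulouts$end[k]; arr <- haulouts$start[k + 1L]
    atSeaIdx <- which(reg$time > dep & reg$time < arr)
    if (!length(atSeaIdx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = reg$id[1], departure = dep, arrival = arr,
      fromSite = haulouts$site[k], toSite = haulouts$site[k + 1L],
      durationDays = as.numeric(difftime(arr, dep, units = "days")),
      roundTrip = !is.na(haulouts$site[k]) &
        haulouts$site[k] == haulouts$site[k + 1L],
      midLon = mean(reg$lon[atSeaIdx]), midLat = mean(reg$lat[atSeaIdx]),
      midDate = as.Date(dep + (arr - dep) / 2, tz = "UTC"))
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
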