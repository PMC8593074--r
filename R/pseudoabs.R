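# Availability null model: first-order vector-autoregressive pseudo-tracks
# that preserve an observed track's step-length and turning structure while
# being independent of the environment, plus the daily 0.1-degree gridding,
# the 2-day presence-adjacency filter, and 1:1 stratified sampling.

#' Fit a VAR(1) movement model to a regularized segment
#'
#' The state vector on the 6-h lattice is (step length km, sin of turning
#' angle, cos of turning angle); a first-order vector autoregression with
#' Gaussian innovations is fitted by least squares. The autoregressive
#' matrix is shrunk if needed so the system is stationary (spectral radius
#' < 1).
#'
#' @param reg Regularized track segment with at least 10 regular steps.
#' @return List of class `"MovementModel"`: `A`, `intercept`, `Sigma`,
#'   `start` (first position/heading/state), plus diagnostics `stepMeanKm`,
#'   `stepSdKm`, `turnAutocorrelation`, `n`.
#' @export
fitMovementModel <- function(reg) {
  n <- nrow(reg)
  if (n < 12) stop("segment too short: need >= 10 regular steps")
  s <- haversineKm(reg$lon[-n], reg$lat[-n], reg$lon[-1], reg$lat[-1])
  hd <- .stepHeading(reg$lon[-n], reg$lat[-n], reg$lon[-1], reg$lat[-1])
  turn <- .wrapAngle(diff(hd))
  z <- cbind(s = s[-1], sinT = sin(turn), cosT = cos(turn))
  zPrev <- z[-nrow(z), , drop = FALSE]
  zNext <- z[-1, , drop = FALSE]
  X <- cbind(1, zPrev)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # degenerate segment (e.g. constant velocity): keep the mean state
    A <- matrix(0, 3, 3)
    intercept <- colMeans(z)
    Sigma <- diag(1e-10, 3)
  } else {
    B <- qr.coef(qrX, zNext)
    intercept <- B[1, ]
    A <- t(B[-1, , drop = FALSE])
    resid <- zNext - X %*% B
    Sigma <- crossprod(resid) / max(nrow(resid) - ncol(X), 1)
    ev <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (ev >= 1) A <- A * (0.98 / ev)
  }
  sinT <- sin(turn)
  turnAC <- if (var(sinT) > 1e-10 && length(sinT) > 2) {
    cor(sinT[-length(sinT)], sinT[-1])
  } else {
    mean(cos(turn))   # persistence convention for degenerate headings
  }
  out <- list(A = A, intercept = intercept, Sigma = Sigma,
              start = list(lon = reg$lon[1], lat = reg$lat[1],
                           heading = hd[1], z = z[1, ]),
              stepMeanKm = mean(s), stepSdKm = sd(s),
              turnAutocorrelation = turnAC, n = n)
  class(out) <- "MovementModel"
  out
}

#' Simulate availability pseudo-tracks
#'
#' Draws `n` simulated tracks from the fitted VAR(1) movement model, each
#' with the template's timestamps, starting at the template's first
#' location, and with every position restricted to sea cells. Land
#' violations trigger per-step rejection sampling (up to `maxAttempts`
#' draws, then a widened innovation proposal); a persistently stuck
#' simulation is abandoned with a warning and replaced.
#'
#' @param model A [fitMovementModel()] fit.
#' @param template The regularized segment the simulations mirror.
#' @param n Number of pseudo-tracks (study default 50).
#' @param stack [EnvStack-class] providing the land mask, or `NULL` for an
#'   all-sea world.
#' @param seed Integer seed.
#' @param maxAttempts Per-step rejection budget before widening.
#' @return List of `n` data.frames (`id`, `sim`, `time`, `lon`, `lat`).
#' @export
simulatePseudoTracks <- function(model, template, n = 50, stack = NULL,
                                 seed = 1L, maxAttempts = 100L) {
  stopifnot(inherits(model, "MovementModel"))
  nPos <- nrow(template)
  if (!is.null(stack) && !atSea(stack, template$lon[1], template$lat[1]))
    stop("template's first fix must be at sea")
  .withSeed(seed, {
    R <- tryCatch(chol(model$Sigma + diag(1e-12, 3)),
                  error = function(e) diag(sqrt(diag(model$Sigma) + 1e-12)))
    seaOk <- function(lon, lat)
      is.null(stack) || atSea(stack, lon, lat)
    sims <- vector("list", n)
    simCount <- 0L; totalTries <- 0L
    while (simCount < n) {
      totalTries <- totalTries + 1L
      if (totalTries > 20L * n) {
        warning("pseudo-track simulation persistently blocked by the land ",
                "mask; returning fewer simulations")
        sims <- sims[seq_len(simCount)]
        break
      }
      lon <- numeric(nPos); lat <- numeric(nPos)
      lon[1] <- template$lon[1]; lat[1] <- template$lat[1]
      heading <- model$start$heading
      z <- model$start$z
      ok <- TRUE
      for (k in seq_len(nPos - 1L)) {
        placed <- FALSE
        for (phase in 1:2) {
          widen <- if (phase == 1) 1 else 2
          for (a in seq_len(maxAttempts)) {
            eps <- as.vector(rnorm(3) %*% R) * widen
            zNew <- model$intercept + as.vector(model$A %*% z) + eps
            stepKm <- max(zNew[1], 0)
            theta <- atan2(zNew[2], zNew[3])
            hNew <- heading + theta
            nxt <- .unprojectKm(stepKm * cos(hNew), stepKm * sin(hNew),
                                lon[k], lat[k])
            if (seaOk(nxt$lon, nxt$lat)) {
              lon[k + 1L] <- nxt$lon; lat[k + 1L] <- nxt$lat
              heading <- hNew; z <- zNew
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      simCount <- simCount + 1L
      sims[[simCount]] <- data.frame(
        id = template$id[1], sim = simCount, time = template$time,
        lon = lon, lat = lat)
    }
    sims
  })
}

#' Grid presences and pseudo-absences daily
#'
#' Assigns every position to a 0.1-degree grid cell (half-open convention)
#' and a UTC date, and deduplicates to one record per (individual, date,
#' cell, label). Positions outside the grid are dropped with a message.
#'
#' @param tracks Real (regularized) tracks: presences.
#' @param simTracks List or data.frame of simulated tracks: pseudo-absences.
#' @param stack [EnvStack-class] defining the grid.
#' @return `data.table` with `id`, `date`, `ix`, `iy`, `cellLon`, `cellLat`,
#'   `label` (`"presence"`/`"pseudo_absence"`).
#' @export
gridLocations <- function(tracks, simTracks, stack) {
  simDf <- if (is.data.frame(simTracks)) simTracks
           else if (length(simTracks)) do.call(rbind, simTracks) else NULL
  gridOne <- function(df, label) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    ci <- cellIndex(stack, df$lon, df$lat)
    bad <- is.na(ci$ix) | is.na(ci$iy)
    if (any(bad))
      message(sum(bad), " position(s) outside the study grid dropped")
    data.table::data.table(
      id = df$id[!bad],
      date = as.Date(df$time[!bad], tz = "UTC"),
      ix = ci$ix[!bad], iy = ci$iy[!bad], label = label)
  }
  g <- data.table::rbindlist(list(gridOne(tracks, "presence"),
                                  gridOne(simDf, "pseudo_absence")),
                             use.names = TRUE)
  g <- unique(g, by = c("id", "date", "ix", "iy", "label"))
  g[, `:=`(cellLon = envLon(stack)[ix], cellLat = envLat(stack)[iy])]
  data.table::setkey(g, id, date)
  g[]
}

#' Filter contradictory pseudo-absences
#'
#' Removes any pseudo-absence whose cell lies in the Moore neighbourhood
#' (3 x 3 block, the cell itself included) of a presence cell of ANY
#' individual on any date within `windowDays` (inclusive). Presences are
#' never removed; re-applying the filter is a no-op.
#'
#' @param g Gridded locations from [gridLocations()].
#' @param windowDays Temporal window in days (default 2).
#' @return Filtered `data.table`, a subset of the input.
#' @export
filterContradictions <- function(g, windowDays = 2) {
  pres <- g[label == "presence"]
  abs_ <- g[label == "pseudo_absence"]
  if (nrow(pres) == 0 || nrow(abs_) == 0) return(g)
  offs <- data.table::CJ(di = -1:1, dj = -1:1, dd = -windowDays:windowDays)
  blocked <- pres[, .(ix, iy, date)][
    , .(ix = ix + rep(offs$di, each = .N),
        iy = iy + rep(offs$dj, each = .N),
        date = date + rep(offs$dd, each = .N))]
  blocked <- unique(blocked)
  data.table::setkey(blocked, ix, iy, date)
  drop <- !is.na(blocked[abs_, on = c("ix", "iy", "date"), which = TRUE])
  data.table::rbindlist(list(pres, abs_[!drop]), use.names = TRUE)[]
}

#' Balanced 1:1 stratified sampling of pseudo-absences
#'
#' Within each (individual, date) stratum draws exactly
#' `min(#presences, #pseudo-absences)` pseudo-absences without replacement
#' and keeps all presences. Strata with too few absences keep what remains
#' (shortfall logged); strata with no presences contribute no absences.
#'
#' @param g Filtered gridded locations.
#' @param seed Integer seed.
#' @return `data.table` with a binary `response` column (1 = presence).
#' @export
sampleBalanced <- function(g, seed = 1L) {
  .withSeed(seed, {
    parts <- lapply(split(g, by = c("id", "date"), drop = TRUE), function(st) {
      pres <- st[label == "presence"]
      abs_ <- st[label == "pseudo_absence"]
      nTake <- min(nrow(pres), nrow(abs_))
      if (nrow(pres) > 0 && nrow(abs_) < nrow(pres))
        message(sprintf("stratum %s %s: absence shortfall of %d",
                        st$id[1], format(st$date[1]),
                        nrow(pres) - nrow(abs_)))
      takeAbs <- if (nTake > 0) abs_[sample.int(nrow(abs_), nTake)] else abs_[0]
      data.table::rbindlist(list(pres, takeAbs))
    })
    out <- data.table::rbindlist(parts, use.names = TRUE)
    out[, response := as.integer(label == "presence")]
    data.table::setkey(out, id, date)
    out[]
  })
}
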