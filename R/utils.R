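# Shared geodesy and small numerical helpers. All distances are great-circle
# (haversine) kilometres on a sphere of radius 6371 km; speeds are m/s.

.EARTH_RADIUS_KM <- 6371

#' Great-circle distance between points
#'
#' Haversine distance in kilometres. Vectorised over all arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

# Initial bearing (radians, 0 = east, counter-clockwise) of the great-circle
# leg from point 1 to point 2, on a local planar approximation. Adequate for
# the sub-degree step lengths handled here.
.stepHeading <- function(lon1, lat1, lon2, lat2) {
  dx <- (lon2 - lon1) * 111.320 * cos((lat1 + lat2) / 2 * pi / 180)
  dy <- (lat2 - lat1) * 110.574
  atan2(dy, dx)
}

# Wrap an angle (radians) into (-pi, pi].
.wrapAngle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# Local equirectangular projection (km) around a reference point, and its
# inverse. Used for the state-space smoother and movement models, where a
# segment spans at most a few degrees.
.projectKm <- function(lon, lat, lonRef, latRef) {
  list(
    x = (lon - lonRef) * 111.320 * cos(latRef * pi / 180),
    y = (lat - latRef) * 110.574
  )
}

.unprojectKm <- function(x, y, lonRef, latRef) {
  list(
    lon = lonRef + x / (111.320 * cos(latRef * pi / 180)),
    lat = latRef + y / 110.574
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param scores Numeric predictions (any monotone scale).
#' @param labels 0/1 response.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
aucScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Bernoulli deviance of probabilities p against 0/1 response.
.bernoulliDeviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so generators are pure functions of (config, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Gaussian-smoothed white noise field with unit variance; `sigma` is the
# correlation length in cells. Separable kernel convolution (replicated
# edges) applied as banded-matrix products; kernel matrices are memoised.
.smoothMatCache <- new.env(parent = emptyenv())

.smoothMat <- function(n, sigma) {
  key <- paste(n, sigma)
  if (!is.null(.smoothMatCache[[key]])) return(.smoothMatCache[[key]])
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- pmin(pmax(seq_len(n) + d, 1L), n)  # replicate edges
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + k[d + half + 1L]
  }
  .smoothMatCache[[key]] <- M
  M
}

.smoothField <- function(n1, n2, sigma) {
  z <- matrix(rnorm(n1 * n2), n1, n2)
  if (sigma <= 0) return(z)
  z <- .smoothMat(n1, sigma) %*% z %*% t(.smoothMat(n2, sigma))
  s <- sd(as.vector(z))
  if (s > 0) z / s else z
}

# Month key "YYYY-MM" for a Date vector.
.monthKey <- function(d) format(d, "%Y-%m")

# sample one element of a vector (safe for length-1 vectors)
.sample1 <- function(v) v[sample.int(length(v), 1L)]
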