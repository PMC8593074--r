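# Independent oracles used to cross-check the implementation. These use
# different code paths (geosphere, igraph, stats::isoreg, plain R tree
# walking) than the functions they validate.

# great-circle distance oracle (geosphere when available, else spherical law
# of cosines -- a different formula from the package's haversine)
oracleDistKm <- function(lon1, lat1, lon2, lat2) {
  if (requireNamespace("geosphere", quietly = TRUE)) {
    geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                             r = 6371000) / 1000
  } else {
    r <- pi / 180
    d <- sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
    6371 * acos(pmin(pmax(d, -1), 1))
  }
}

# brute-force check that a filtered track satisfies the SDA rules
sdaViolations <- function(track, vmax = 3,
                          rules = cbind(angle = c(15, 25),
                                        dist = c(2.5, 5))) {
  n <- nrow(track)
  bad <- 0L
  if (n >= 2) {
    d <- oracleDistKm(track$lon[-n], track$lat[-n],
                      track$lon[-1], track$lat[-1]) * 1000
    sp <- d / pmax(diff(as.numeric(track$time)), 1e-9)
    bad <- bad + sum(sp > vmax + 1e-9)
  }
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      a <- oracleDistKm(track$lon[i - 1], track$lat[i - 1],
                        track$lon[i], track$lat[i])
      c2 <- oracleDistKm(track$lon[i], track$lat[i],
                         track$lon[i + 1], track$lat[i + 1])
      b <- oracleDistKm(track$lon[i - 1], track$lat[i - 1],
                        track$lon[i + 1], track$lat[i + 1])
      ang <- acos(min(max((a^2 + c2^2 - b^2) / max(2 * a * c2, 1e-12), -1),
                      1)) * 180 / pi
      for (r in seq_len(nrow(rules)))
        if (ang < rules[r, 1] - 1e-9 && a > rules[r, 2] && c2 > rules[r, 2])
          bad <- bad + 1L
    }
  }
  bad
}

# Dijkstra oracle on the sea graph via igraph (virtual zero-weight source)
edgeDistOracle <- function(sic, land, lon, lat, threshold = 0.15) {
  nlon <- length(lon); nlat <- length(lat)
  open <- !land
  id <- function(i, j) (j - 1L) * nlon + i
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- seq_len(nlon); jj <- seq_len(nlat)
    gi <- expand.grid(i = ii, j = jj)
    i2 <- gi$i + di; j2 <- gi$j + dj
    ok <- i2 >= 1 & i2 <= nlon & j2 >= 1 & j2 <= nlat
    ok[ok] <- open[cbind(gi$i[ok], gi$j[ok])] & open[cbind(i2[ok], j2[ok])]
    from <- c(from, id(gi$i[ok], gi$j[ok]))
    to <- c(to, id(i2[ok], j2[ok]))
    w <- c(w, oracleDistKm(lon[gi$i[ok]], lat[gi$j[ok]],
                           lon[i2[ok]], lat[j2[ok]]))
  }
  src <- which(open & !is.na(sic) & sic > threshold)
  nV <- nlon * nlat + 1L
  virt <- nV
  from <- c(from, rep(virt, length(src)))
  to <- c(to, src)
  w <- c(w, rep(0, length(src)))
  g <- igraph::make_empty_graph(n = nV, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = virt)[1, seq_len(nlon * nlat)]
  out <- matrix(d, nlon, nlat)
  out[!open] <- NA_real_
  out
}

# plain-R walk through the stored tree matrices (independent of the C++
# predictor)
predictBRT_R <- function(fit, X, nTrees = length(fit@trees)) {
  X <- as.matrix(X)
  eta <- rep(fit@init, nrow(X))
  for (t in seq_len(nTrees)) {
    tm <- fit@trees[[t]]
    for (r in seq_len(nrow(X))) {
      node <- 1L
      while (tm[node, 1] >= 0) {
        j <- tm[node, 1] + 1L
        x <- X[r, j]
        goLeft <- if (is.na(x)) tm[node, 5] > 0.5 else x <= tm[node, 2]
        node <- if (goLeft) tm[node, 3] + 1L else tm[node, 4] + 1L
      }
      eta[r] <- eta[r] + tm[node, 6]
    }
  }
  plogis(eta)
}

# sunrise-equation daylength with a higher-accuracy declination (different
# formula from the package's cosine approximation)
daylengthOracle <- function(lat, date) {
  d <- as.integer(format(as.Date(date), "%j"))
  delta <- -asin(0.39779 * cos((0.98565 * (d + 10) +
                                  1.914 * sin(0.98565 * (d - 2) * pi / 180)) *
                                 pi / 180))
  x <- -tan(lat * pi / 180) * tan(delta)
  x <- pmin(pmax(x, -1), 1)
  2 * acos(x) * 180 / pi / 15
}
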