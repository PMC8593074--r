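# Shared fixtures: a small synthetic world (20 x 20 cells, 12 days) built
# once per test run, plus simple track constructors.

.fixtures <- new.env()

smallWorld <- function() {
  if (is.null(.fixtures$world)) {
    cfg <- syntheticWorldConfig(lonMin = -61, lonMax = -59,
                                latMin = -62, latMax = -60,
                                nDays = 12L, islandLat = -60.6,
                                iceEdgeLatStart = -61.8,
                                iceSeasonalAmplitude = 1.2,
                                seed = 99L)
    .fixtures$world <- deriveCovariates(generateEnvStack(cfg))
  }
  .fixtures$world
}

smallTruth <- function(prefStrength = 10) {
  truthModel(smallWorld(), prefStrength = prefStrength)
}

# a track data.frame from vectors of seconds-offsets, lon, lat
makeTrack <- function(tsec, lon, lat, lc = "3", id = "a") {
  data.frame(id = id,
             time = as.POSIXct("2019-03-01", tz = "UTC") + tsec,
             lon = lon, lat = lat, lc = lc)
}

# straight slow track along a meridian: `speed` m/s at 6-h spacing
straightTrack <- function(n = 10, speedMS = 1, lat0 = -61, lon0 = -60) {
  dt <- 6 * 3600
  dKm <- speedMS * dt / 1000
  lat <- lat0 + (seq_len(n) - 1) * dKm / 110.574
  makeTrack((seq_len(n) - 1) * dt, rep(lon0, n), lat)
}

# regular 6-h lattice track from planar km coordinates
kmTrack <- function(x, y, lon0 = -60, lat0 = -61, id = "a") {
  lon <- lon0 + x / (111.320 * cos(lat0 * pi / 180))
  lat <- lat0 + y / 110.574
  makeTrack((seq_along(x) - 1) * 6 * 3600, lon, lat, id = id)
}
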