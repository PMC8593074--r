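# Availability null model: VAR(1) movement fits, land-constrained
# pseudo-track simulation, daily gridding, the 2-day adjacency filter and
# 1:1 stratified sampling.

test_that("movement model reproduces step statistics of a stochastic track", {
  set.seed(2)
  n <- 120
  s <- pmax(rnorm(n, 10, 2), 0.5)
  turn <- rnorm(n, 0, 0.3)
  hd <- cumsum(c(0.3, turn[-1]))
  x <- cumsum(c(0, s * cos(hd)))
  y <- cumsum(c(0, s * sin(hd)))
  tr <- kmTrack(x, y)
  mm <- fitMovementModel(tr)
  sims <- simulatePseudoTracks(mm, tr, n = 10, stack = NULL, seed = 9L)
  simSteps <- unlist(lapply(sims, function(sm) {
    haversineKm(sm$lon[-nrow(sm)], sm$lat[-nrow(sm)],
                sm$lon[-1], sm$lat[-1])
  }))
  expect_equal(mean(simSteps), mm$stepMeanKm, tolerance = 0.2)
  # pooled simulated step lengths match the template distribution
  ks <- suppressWarnings(stats::ks.test(simSteps,
                                        haversineKm(tr$lon[-n], tr$lat[-n],
                                                    tr$lon[-1], tr$lat[-1])))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate straight segment gives tiny innovations and full
          heading persistence", {
  tr <- kmTrack(seq(0, 200, by = 10), rep(0, 21))
  mm <- fitMovementModel(tr)
  expect_lt(max(diag(mm$Sigma)), 1e-4)
  expect_equal(mm$turnAutocorrelation, 1, tolerance = 1e-6)
})

test_that("reversing zig-zag yields negative turning autocorrelation", {
  # alternating +90/-90 degree turns
  hd <- cumsum(rep(c(pi / 2, -pi / 2), 15))
  x <- cumsum(c(0, 10 * cos(hd)))
  y <- cumsum(c(0, 10 * sin(hd)))
  mm <- fitMovementModel(kmTrack(x, y))
  expect_lt(mm$turnAutocorrelation, -0.5)
})

test_that("movement model requires at least 10 regular steps", {
  expect_error(fitMovementModel(straightTrack(8)), "short")
})

test_that("pseudo-tracks start at the template start, keep its timestamps,
          and stay at sea", {
  st <- smallWorld()
  gen <- generateTracks(st, smallTruth(), n = 1, seed = 13L,
                        durationRange = c(9, 10))
  reg <- suppressWarnings(suppressMessages(preprocessTracks(gen$obs)))[[1]]
  k0 <- which(atSea(st, reg$lon, reg$lat))[1]
  tmpl <- reg[k0:nrow(reg), ]
  mm <- fitMovementModel(tmpl)
  sims <- simulatePseudoTracks(mm, tmpl, n = 5, stack = st, seed = 3L)
  expect_length(sims, 5L)
  for (sm in sims) {
    expect_equal(nrow(sm), nrow(tmpl))
    expect_identical(sm$time, tmpl$time)
    expect_equal(sm$lon[1], tmpl$lon[1])
    expect_equal(sm$lat[1], tmpl$lat[1])
    expect_true(all(atSea(st, sm$lon, sm$lat)))
  }
})

test_that("a single-point template simulates the single fixed point", {
  tmpl <- straightTrack(1)
  mm <- fitMovementModel(straightTrack(15))
  sims <- simulatePseudoTracks(mm, tmpl, n = 3, stack = NULL, seed = 1L)
  for (sm in sims) {
    expect_equal(nrow(sm), 1L)
    expect_equal(sm$lon, tmpl$lon)
  }
})

test_that("gridding deduplicates per day and cell and uses the half-open
          convention", {
  st <- smallWorld()
  cs <- envCellSize(st)
  lon0 <- envLon(st)[3]; lat0 <- envLat(st)[3]
  tr <- makeTrack(c(0, 3600), c(lon0, lon0 + cs / 4), c(lat0, lat0))
  g <- gridLocations(tr, list(), st)
  expect_equal(nrow(g), 1L)   # same cell, same day -> one presence
  # a position exactly on the lower boundary belongs to the cell above it
  edge <- makeTrack(0, envLon(st)[3] - cs / 2, lat0)
  ge <- gridLocations(edge, list(), st)
  expect_equal(ge$ix, 3L)
  # fixes straddling midnight UTC produce two dated records
  mid <- makeTrack(c(86300, 86500), c(lon0, lon0), c(lat0, lat0))
  gm <- gridLocations(mid, list(), st)
  expect_equal(nrow(gm), 2L)
  expect_equal(as.integer(diff(gm$date)), 1L)
})

test_that("contradiction filter removes Moore-adjacent pseudo-absences
          within the 2-day window", {
  st <- smallWorld()
  mk <- function(ix, iy, date, label)
    data.table::data.table(id = "a", date = as.Date(date), ix = ix, iy = iy,
                           label = label,
                           cellLon = envLon(st)[ix], cellLat = envLat(st)[iy])
  pres <- mk(10L, 10L, "2019-03-05", "presence")
  sameCell <- mk(10L, 10L, "2019-03-05", "pseudo_absence")
  diagLater <- mk(11L, 11L, "2019-03-07", "pseudo_absence")
  farSameDay <- mk(13L, 10L, "2019-03-05", "pseudo_absence")
  g <- rbind(pres, sameCell, diagLater, farSameDay)
  out <- filterContradictions(g, windowDays = 2)
  expect_equal(nrow(out[out$label == "pseudo_absence", ]), 1L)
  expect_equal(out[out$label == "pseudo_absence", ]$ix, 13L)
  # presences never removed; filter idempotent
  expect_equal(nrow(out[out$label == "presence", ]), 1L)
  expect_equal(filterContradictions(out, 2), out)
})

test_that("contradiction filter matches a brute-force oracle", {
  set.seed(12)
  st <- smallWorld()
  n <- 120
  g <- data.table::data.table(
    id = sample(c("a", "b"), n, TRUE),
    date = as.Date("2019-03-01") + sample(0:9, n, TRUE),
    ix = sample(3:18, n, TRUE), iy = sample(3:18, n, TRUE),
    label = sample(c("presence", "pseudo_absence"), n, TRUE,
                   prob = c(0.3, 0.7)))
  g$cellLon <- envLon(st)[g$ix]; g$cellLat <- envLat(st)[g$iy]
  g <- unique(g, by = c("id", "date", "ix", "iy", "label"))
  out <- filterContradictions(g, windowDays = 2)
  pres <- g[g$label == "presence", ]
  keepOracle <- vapply(seq_len(nrow(g)), function(r) {
    if (g$label[r] == "presence") return(TRUE)
    !any(abs(pres$ix - g$ix[r]) <= 1 & abs(pres$iy - g$iy[r]) <= 1 &
           abs(as.integer(pres$date - g$date[r])) <= 2)
  }, logical(1))
  expect_equal(nrow(out), sum(keepOracle))
  expect_setequal(paste(out$id, out$date, out$ix, out$iy, out$label),
                  paste(g$id, g$date, g$ix, g$iy, g$label)[keepOracle])
})

test_that("balanced sampling draws min(presences, absences) per stratum", {
  st <- smallWorld()
  mkN <- function(n, iy0, label)
    data.table::data.table(id = "a", date = as.Date("2019-03-05"),
                           ix = seq_len(n), iy = iy0, label = label,
                           cellLon = envLon(st)[seq_len(n)],
                           cellLat = envLat(st)[iy0])
  g <- rbind(mkN(4, 4L, "presence"), mkN(10, 8L, "pseudo_absence"))
  out <- sampleBalanced(g, seed = 2L)
  expect_equal(sum(out$response == 0), 4L)
  expect_equal(sum(out$response == 1), 4L)
  g2 <- rbind(mkN(4, 4L, "presence"), mkN(2, 8L, "pseudo_absence"))
  expect_message(out2 <- sampleBalanced(g2, seed = 2L), "shortfall")
  expect_equal(sum(out2$response == 0), 2L)
  g3 <- mkN(5, 8L, "pseudo_absence")
  out3 <- sampleBalanced(g3, seed = 2L)
  expect_equal(nrow(out3), 0L)
})

test_that("after sampling, absences never outnumber presences globally", {
  st <- smallWorld()
  set.seed(5)
  n <- 300
  g <- data.table::data.table(
    id = sample(c("a", "b", "c"), n, TRUE),
    date = as.Date("2019-03-01") + sample(0:5, n, TRUE),
    ix = sample(3:18, n, TRUE), iy = sample(3:18, n, TRUE),
    label = sample(c("presence", "pseudo_absence"), n, TRUE))
  g$cellLon <- envLon(st)[g$ix]; g$cellLat <- envLat(st)[g$iy]
  g <- unique(g, by = c("id", "date", "ix", "iy", "label"))
  out <- suppressMessages(sampleBalanced(g, seed = 3L))
  expect_lte(sum(out$response == 0), sum(out$response == 1))
})
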