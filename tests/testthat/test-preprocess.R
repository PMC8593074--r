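# Track cleaning: near-duplicate thinning, the speed-distance-angle filter,
# gap splitting, CRW state-space regularization, haul-out detection and trip
# segmentation.

test_that("near-duplicate removal keeps the first fix of a run", {
  tr <- makeTrack(c(0, 90), c(-60, -60), c(-61, -61))
  expect_equal(nrow(removeNearDuplicates(tr)), 1L)
  # 60 s fix dropped; 130 s fix kept (130 s after the last KEPT fix at 0)
  tr3 <- makeTrack(c(0, 60, 130), rep(-60, 3), rep(-61, 3))
  out <- removeNearDuplicates(tr3)
  expect_equal(as.numeric(out$time) - as.numeric(out$time[1]), c(0, 130))
  expect_equal(nrow(removeNearDuplicates(tr3[0, ])), 0L)
  unsorted <- tr3[c(2, 1, 3), ]
  expect_error(removeNearDuplicates(unsorted), "sorted")
})

test_that("near-duplicate removal is idempotent and returns a subsequence", {
  set.seed(1)
  tr <- makeTrack(cumsum(runif(50, 10, 400)), rnorm(50, -60, 0.1),
                  rnorm(50, -61, 0.1))
  once <- removeNearDuplicates(tr)
  expect_identical(removeNearDuplicates(once), once)
  expect_true(all(paste(once$time, once$lon) %in% paste(tr$time, tr$lon)))
})

test_that("speed filter removes fixes implying > 3 m/s", {
  # 0.1 degree along a meridian = 11.06 km in 1 h = 3.07 m/s
  tr <- makeTrack(c(0, 3600), c(-60, -60), c(-61, -60.9))
  out <- sdaFilter(tr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$lat, -61)
})

test_that("slow straight tracks pass unchanged; class Z is removed", {
  tr <- straightTrack(12, speedMS = 1)
  expect_identical(sdaFilter(tr), tr)
  tr$lc[5] <- "Z"
  expect_equal(nrow(sdaFilter(tr)), 11L)
})

test_that("a perpendicular spike with long legs is removed", {
  # straight slow track with one fix displaced 6 km sideways: inner angle
  # 2 * atan(1/6) = 19 degrees < 25 with both legs 6.1 km > 5 km
  x <- seq(0, 10, by = 1)        # 1 km per 6 h (slow)
  y <- rep(0, length(x))
  y[6] <- 6
  tr <- kmTrack(x, y)
  out <- sdaFilter(tr)
  expect_equal(nrow(out), length(x) - 1L)
  expect_false(any(abs(out$lat - (-61 + 6 / 110.574)) < 1e-9))
})

test_that("sda filter output is a subsequence, idempotent, and satisfies the
          speed bound by brute force", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    tr <- makeTrack(cumsum(runif(n, 1800, 21600)),
                    -60 + cumsum(rnorm(n, 0, 0.05)),
                    -61 + cumsum(rnorm(n, 0, 0.05)),
                    lc = sample(c("3", "1", "B", "Z"), n, replace = TRUE))
    out <- sdaFilter(tr)
    expect_true(all(paste(out$time) %in% paste(tr$time)))
    expect_identical(sdaFilter(out), out)
    expect_equal(sdaViolations(out), 0L)
  }
})

test_that("gap splitting is strict about 'in excess of 7 days'", {
  base <- straightTrack(6)
  gap8 <- base
  gap8$time[4:6] <- gap8$time[4:6] + 8 * 86400
  expect_length(splitOnGaps(gap8), 2L)
  gap7 <- base
  gap7$time[4:6] <- gap7$time[4:6] + (7 * 86400 - 6 * 3600)
  expect_length(splitOnGaps(gap7), 1L)
  expect_length(splitOnGaps(base), 1L)
  # concatenation reconstructs the input
  parts <- splitOnGaps(gap8)
  rebuilt <- do.call(rbind, parts)
  expect_equal(rebuilt$time, gap8$time)
  expect_equal(rebuilt$lat, gap8$lat)
})

test_that("CRW smoother reproduces a noiseless straight lattice track", {
  tr <- straightTrack(12, speedMS = 0.5)
  reg <- suppressWarnings(fitCRWSSM(tr))
  expect_equal(nrow(reg), 12L)
  expect_equal(as.numeric(diff(reg$time)), rep(6, 11), tolerance = 1e-9)
  expect_lt(max(haversineKm(reg$lon, reg$lat, tr$lon, tr$lat)), 0.3)
})

test_that("CRW smoother output lies on the 6-h lattice and needs >= 4 fixes", {
  set.seed(3)
  tsec <- sort(runif(40, 0, 5 * 86400))
  tr <- makeTrack(tsec, -60 + cumsum(rnorm(40, 0, 0.01)),
                  -61 + cumsum(rnorm(40, 0, 0.01)), lc = "1")
  reg <- suppressWarnings(fitCRWSSM(tr))
  expect_equal(as.numeric(reg$time[1]), as.numeric(tr$time[1]))
  expect_true(all(abs(diff(as.numeric(reg$time)) - 21600) < 1e-6))
  expect_error(fitCRWSSM(tr[1:3, ]), "4 fixes")
})

test_that("smoothing reduces positional error on a noisy simulated track", {
  res <- ssmBenefitExperiment(nTracks = 3, nSteps = 30, seed = 5L)
  expect_true(all(res$rmseSmoothed < res$rmseRaw))
})

test_that("haul-out detection finds coastal residencies", {
  st <- smallWorld()
  sites <- generateTracks(st, smallTruth(), n = 1, seed = 1L,
                          durationRange = c(8, 9))$sites
  # never approaches the coast
  offshore <- straightTrack(10, speedMS = 0.2, lat0 = -61.4, lon0 = -60.5)
  expect_equal(nrow(detectHaulouts(offshore, st)), 0L)
  # two days parked at a site, a 3-day loop at sea, then two more days
  s1 <- sites[1, ]
  park1 <- makeTrack((0:7) * 21600, rep(s1$lon, 8), rep(s1$lat, 8))
  loop <- makeTrack((8:19) * 21600, s1$lon + seq(0.1, 0.5, length.out = 12),
                    rep(-61.4, 12))
  park2 <- makeTrack((20:27) * 21600, rep(s1$lon, 8), rep(s1$lat, 8))
  reg <- rbind(park1, loop, park2)
  ho <- detectHaulouts(reg, st, sites = sites)
  expect_equal(nrow(ho), 2L)
  expect_equal(ho$site, c(s1$site, s1$site))
})

test_that("trips are segmented between haul-outs with round-trip flags", {
  st <- smallWorld()
  reg <- straightTrack(20, speedMS = 0.3)
  ho <- data.frame(id = "a",
                   start = reg$time[c(1, 15)], end = reg$time[c(3, 18)],
                   site = c(1L, 1L))
  trips <- segmentTrips(reg, ho)
  expect_equal(nrow(trips), 1L)
  expect_true(trips$roundTrip)
  ho$site <- c(1L, 2L)
  expect_false(segmentTrips(reg, ho)$roundTrip)
  # a single haul-out block yields no trips
  expect_equal(nrow(segmentTrips(reg, ho[1, ])), 0L)
  expect_true(all(trips$durationDays > 0))
})
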