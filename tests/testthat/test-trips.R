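# Trip statistics, daylength, dive-depth aggregation and haul-out
# demography.

test_that("tagging summary: per-tag values aggregate as published", {
  tab <- taggingTable()
  expect_equal(nrow(tab), 15L)
  expect_equal(pooledTripCount(tab), 243)
  expect_equal(maxTrackDuration(tab), 197)
  expect_equal(retainedTagCount(tab), 14L)
})

test_that("trip duration summaries: single trip and fixture durations", {
  one <- data.frame(id = "a", durationDays = 3)
  td <- tripDurations(one)
  expect_equal(td$pooled$meanDays, 3)
  expect_equal(td$pooled$range, c(3, 3))
  many <- data.frame(id = c("a", "a", "b"), durationDays = c(1, 3, 5))
  td2 <- tripDurations(many)
  expect_equal(td2$perIndividual$trips, c(2, 1))
  expect_equal(td2$perIndividual$meanDays, c(2, 5))
  expect_equal(td2$pooled$trips, 3)
})

test_that("departure/arrival histograms conserve mass and sit in the right
          local-time bins", {
  # departures at 20:00 local at lon -60 => 24:00 UTC
  dep <- as.POSIXct("2019-03-02 00:00:00", tz = "UTC") + (0:9) * 86400
  arr <- dep + 11 * 3600
  trips <- data.frame(id = "a", departure = dep, arrival = arr,
                      midLon = -60)
  h <- departureArrivalHistogram(trips)
  expect_equal(sum(h$departure), 10)
  expect_equal(sum(h$arrival), 10)
  expect_equal(unname(h$departure[21]), 10)   # bin [20, 21) local
})

test_that("the synthetic schedule departs in the evening and arrives in the
          morning", {
  st <- smallWorld()
  gen <- generateTracks(st, smallTruth(), n = 6, seed = 17L,
                        durationRange = c(9, 10))
  tl <- gen$trips
  tl$midLon <- vapply(tl$fromSite, function(s)
    gen$sites$lon[gen$sites$site == s], numeric(1))
  h <- departureArrivalHistogram(tl)
  depMode <- as.numeric(sub("\\[(\\d+).*", "\\1",
                            names(which.max(h$departure))))
  arrMode <- as.numeric(sub("\\[(\\d+).*", "\\1",
                            names(which.max(h$arrival))))
  expect_true(depMode >= 17 && depMode <= 22)
  expect_true(arrMode >= 5 && arrMode <= 10)
})

test_that("daylength: equatorial equinox, polar night clamp, and agreement
          with an ephemeris-style oracle", {
  expect_equal(daylength(0, as.Date("2019-03-21")), 12, tolerance = 0.2)
  expect_equal(daylength(-70, as.Date("2019-06-15")), 0)
  expect_equal(daylength(-70, as.Date("2019-12-15")), 24)
  set.seed(2)
  lats <- runif(40, -55, 55)
  dates <- as.Date("2019-01-01") + sample(0:364, 40, TRUE)
  expect_lt(max(abs(daylength(lats, dates) - daylengthOracle(lats, dates))),
            0.2)
})

test_that("daylength-duration correlation: exact linear, permutation null,
          and the winter lengthening of synthetic trips", {
  lat <- -62
  dates <- as.Date("2019-03-10") + seq(0, 90, by = 5)
  dl <- daylength(lat, dates)
  trips <- data.frame(id = "a", durationDays = 30 - 2 * dl,
                      midDate = dates, midLat = lat)
  expect_equal(correlateDaylength(trips)$r, -1, tolerance = 1e-12)
  set.seed(3)
  permuted <- trips
  rs <- replicate(30, {
    permuted$durationDays <- sample(trips$durationDays)
    correlateDaylength(permuted)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  # generator trips lengthen as days shorten
  st <- smallWorld()
  gen <- generateTracks(st, smallTruth(), n = 8, seed = 19L,
                        durationRange = c(10, 11))
  expect_lt(correlateDaylength(gen$trips)$r, 0)
})

test_that("daily maximum depth aggregation matches hand computation and is
          order invariant", {
  dv <- data.frame(id = rep(c("a", "b"), each = 4),
                   date = as.Date(rep(c("2019-03-01", "2019-04-01"), 4)),
                   depth_m = c(10, 40, 20, 35, 15, 70, 25, 60))
  out <- dailyMaxDepth(dv)
  expect_equal(out$deepest, 70)
  m <- out$monthly
  expect_equal(m$meanMaxDepth[m$month == "2019-03"], mean(c(20, 25)))
  expect_equal(m$sdMaxDepth[m$month == "2019-04"], sd(c(40, 70)))
  shuffled <- dailyMaxDepth(dv[sample(nrow(dv)), ])
  expect_equal(shuffled$monthly, out$monthly)
  expect_equal(dailyMaxDepth(rbind(dv, dv))$monthly, out$monthly)
  expect_error(dailyMaxDepth(data.frame(id = "a", date = Sys.Date(),
                                        depth_m = -5)), "negative")
})

test_that("demography summary pools totals and percentages correctly", {
  counts <- generateTransectCounts(seed = 23L)
  ds <- demographySummary(counts)
  expect_equal(ds$pooledTotal, sum(unlist(counts[c("juveniles", "subadults",
                                                   "adults")])))
  # per-census proportions sum to 100
  expect_equal(sum(ds$composition$meanPct) > 99.9 &&
                 sum(ds$composition$meanPct) < 100.1, TRUE)
  singleClass <- data.frame(haulout = 1, census = 1, transect = 1,
                            juveniles = 7, subadults = 0, adults = 0)
  dsc <- demographySummary(singleClass)
  expect_equal(dsc$composition$meanPct, c(100, 0, 0))
})
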