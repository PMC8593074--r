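# Derived covariates (slope, gradients, EKE, ice-edge distance), bilinear
# regridding, 15-km covariate matching and the Spearman collinearity screen.

test_that("slope of a constant field is zero and of a plane is analytic", {
  lon <- seq(-60.95, -60.05, by = 0.1)
  lat <- seq(-61.95, -61.05, by = 0.1)
  flat <- matrix(5, 10, 10)
  expect_true(all(computeSlope(flat, lon, lat) == 0))
  # ramp of 1 m per 1000 m northwards: slope = atan(0.001) = 0.0573 deg
  yM <- matrix(rep(lat * 110574, each = 10), 10, 10)
  ramp <- yM * 0.001
  slp <- computeSlope(ramp, lon, lat)
  expect_equal(mean(slp[3:8, 3:8]), atan(0.001) * 180 / pi,
               tolerance = 0.01)
  expect_error(computeSlope(matrix(NA_real_, 3, 3), lon[1:3], lat[1:3]),
               "missing")
})

test_that("slope agrees with central differences on a smooth field", {
  lon <- seq(-60.975, -60.025, by = 0.05)
  lat <- seq(-61.975, -61.025, by = 0.05)
  xM <- matrix(rep(lon, length(lat)), length(lon), length(lat))
  yM <- matrix(rep(lat, each = length(lon)), length(lon), length(lat))
  z <- 500 * sin(xM * 4) * cos(yM * 4)
  slp <- computeSlope(z, lon, lat)
  # central-difference oracle
  dx <- 0.05 * 111320 * cos(lat * pi / 180)
  dy <- 0.05 * 110574
  n1 <- length(lon); n2 <- length(lat)
  gx <- (z[3:n1, ] - z[1:(n1 - 2), ]) /
    (2 * matrix(rep(dx, each = n1 - 2), n1 - 2, n2))
  gy <- (z[, 3:n2] - z[, 1:(n2 - 2)]) / (2 * dy)
  oracle <- atan(sqrt(gx[, 2:(n2 - 1)]^2 + gy[2:(n1 - 1), ]^2)) * 180 / pi
  inner <- slp[2:(n1 - 1), 2:(n2 - 1)]
  relErr <- abs(inner - oracle) / pmax(oracle, 1e-6)
  expect_lt(median(relErr), 0.1)
})

test_that("gradient responds monotonically to front sharpness", {
  lon <- seq(-60.95, -60.05, by = 0.1)
  lat <- seq(-61.95, -61.05, by = 0.1)
  front <- function(width) {
    yM <- matrix(rep(seq_along(lat), each = 10), 10, 10)
    2 * plogis((yM - 5) / width)
  }
  expect_equal(max(computeGradient(matrix(1, 10, 10), lon, lat)), 0)
  sharp <- max(computeGradient(front(0.5), lon, lat))
  mild <- max(computeGradient(front(2), lon, lat))
  expect_gt(sharp, mild)
})

test_that("EKE is the closed form 0.5 (U^2 + V^2)", {
  expect_equal(computeEKE(matrix(0, 2, 2), matrix(0, 2, 2)),
               matrix(0, 2, 2))
  expect_equal(computeEKE(matrix(1, 2, 2), matrix(1, 2, 2))[1, 1], 1)
  expect_equal(computeEKE(matrix(3, 1, 1), matrix(4, 1, 1))[1, 1], 12.5)
  expect_error(computeEKE(matrix(0, 2, 2), matrix(0, 3, 3)), "match")
})

test_that("ice-edge distance: zero inside ice, one step to a neighbour,
          all-open-water case flagged", {
  lon <- seq(-60.95, -60.05, by = 0.1)
  lat <- seq(-61.95, -61.05, by = 0.1)
  land <- matrix(FALSE, 10, 10)
  sic <- matrix(0, 10, 10)
  sic[1, 1] <- 0.2
  d <- distanceToIceEdge(sic, land, lon, lat)
  expect_equal(d[1, 1], 0)
  expect_equal(d[2, 1], haversineKm(lon[1], lat[1], lon[2], lat[1]),
               tolerance = 1e-9)
  expect_message(dAll <- distanceToIceEdge(matrix(0, 10, 10), land, lon, lat),
                 "no sea-ice")
  expect_true(all(is.na(dAll)))
})

test_that("ice-edge distance equals an igraph Dijkstra oracle on random
          masks and obeys the triangle inequality", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:8) {
    n1 <- sample(8:16, 1); n2 <- sample(8:16, 1)
    lon <- -61 + (seq_len(n1) - 0.5) * 0.1
    lat <- -62 + (seq_len(n2) - 0.5) * 0.1
    land <- matrix(runif(n1 * n2) < 0.25, n1, n2)
    sic <- matrix(runif(n1 * n2, 0, 0.4), n1, n2)
    sic[land] <- NA
    d <- distanceToIceEdge(sic, land, lon, lat)
    o <- edgeDistOracle(sic, land, lon, lat)
    expect_equal(d, o, tolerance = 1e-9)
  }
})

test_that("bilinear regrid: identity, midpoint, and exactness on affine
          fields", {
  srcLon <- seq(-61, -60, by = 0.1)
  srcLat <- seq(-62, -61, by = 0.1)
  m <- outer(srcLon, srcLat, function(a, b) 3 * a - 2 * b + 1)
  expect_equal(regridBilinear(m, srcLon, srcLat, srcLon, srcLat), m)
  two <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(regridBilinear(two, c(0, 1), c(0, 1), 0.5, 0.5)[1, 1], 0.5)
  dstLon <- seq(-60.97, -60.03, by = 0.07)
  dstLat <- seq(-61.98, -61.02, by = 0.035)
  out <- regridBilinear(m, srcLon, srcLat, dstLon, dstLat)
  expect_equal(out, outer(dstLon, dstLat, function(a, b) 3 * a - 2 * b + 1),
               tolerance = 1e-9)
  expect_error(regridBilinear(m, srcLon, srcLat, 10, 10), "disjoint")
})

test_that("covariate matching averages within 15 km and tolerates missing
          chlorophyll", {
  st <- smallWorld()
  rec <- data.table::data.table(id = "a", date = envDates(st)[2],
                                ix = 10L, iy = 10L,
                                cellLon = envLon(st)[10],
                                cellLat = envLat(st)[10],
                                label = "presence", response = 1L)
  # a uniform synthetic layer matches to the constant for any radius
  stU <- st
  stU@static$UNIF <- matrix(7, 20, 20)
  m1 <- matchCovariates(rec, stU, covariates = "UNIF", radiusKm = 15)
  expect_equal(m1$UNIF, 7)
  # radius below half a cell returns the record's own cell value
  m2 <- matchCovariates(rec, st, covariates = "BAT", radiusKm = 1)
  expect_equal(m2$BAT, envLayer(st, "BAT")[10, 10])
  # hand-computed two-cell mean
  stT <- st
  two <- matrix(NA_real_, 20, 20); two[10, 10] <- 2; two[11, 10] <- 4
  stT@static$TWO <- two
  m3 <- matchCovariates(rec, stT, covariates = "TWO", radiusKm = 15)
  expect_equal(m3$TWO, 3)
  # date outside the stack errors
  recBad <- rec; recBad$date <- envDates(st)[1] - 40
  expect_error(matchCovariates(recBad, st, covariates = "BAT"), "date")
})

test_that("matching is invariant to record order and bounded by the
          neighbourhood extremes", {
  st <- smallWorld()
  set.seed(4)
  n <- 25
  recs <- data.table::data.table(
    id = "a", date = sample(envDates(st), n, TRUE),
    ix = sample(5:16, n, TRUE), iy = sample(5:16, n, TRUE))
  recs$cellLon <- envLon(st)[recs$ix]; recs$cellLat <- envLat(st)[recs$iy]
  a <- matchCovariates(recs, st, covariates = c("SST", "CHL"))
  perm <- sample(n)
  b <- matchCovariates(recs[perm], st, covariates = c("SST", "CHL"))
  expect_equal(a$SST[perm], b$SST)
  sstAll <- st@dynamic$SST
  expect_true(all(a$SST <= max(sstAll, na.rm = TRUE) + 1e-9 &
                    a$SST >= min(sstAll, na.rm = TRUE) - 1e-9, na.rm = TRUE))
})

test_that("collinearity screen drops duplicates but not independent or
          constant covariates", {
  set.seed(6)
  tab <- data.frame(BAT = rnorm(200), SST = rnorm(200), CHL = rnorm(200))
  tab$SIT <- tab$BAT + rnorm(200, 0, 1e-6)   # exact duplicate in rank
  tab$CONST <- 1
  scr <- collinearityScreen(tab, c("BAT", "SIT", "SST", "CHL", "CONST"))
  expect_equal(scr$dropped$dropped, "SIT")
  expect_true(all(c("BAT", "SST", "CHL") %in% scr$kept))
  expect_true("CONST" %in% scr$undefined)
  expect_true("CONST" %in% scr$kept)
  none <- collinearityScreen(tab, c("BAT", "SST", "CHL"))
  expect_equal(nrow(none$dropped), 0L)
})

test_that("synthetic worlds carry an SIT layer the screen discards for SIC", {
  st <- smallWorld()
  set.seed(8)
  recs <- data.table::data.table(
    id = "a", date = sample(envDates(st), 150, TRUE),
    ix = sample(2:19, 150, TRUE), iy = sample(2:19, 150, TRUE))
  recs$cellLon <- envLon(st)[recs$ix]; recs$cellLat <- envLat(st)[recs$iy]
  m <- matchCovariates(recs, st, covariates = c("SIC", "SIT", "SST"))
  scr <- collinearityScreen(m, c("SIC", "SIT", "SST"))
  expect_true("SIT" %in% scr$dropped$dropped)
  expect_true("SIC" %in% scr$kept)
})
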