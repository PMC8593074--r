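# Boosted regression trees: boosting behaviour, relative influence, partial
# dependence, blocked cross-validation tuning, the bootstrap ensemble and
# prediction maps.

simData <- function(n = 400, seed = 1) {
  set.seed(seed)
  d <- data.frame(id = sample(paste0("s", 1:4), n, TRUE),
                  x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$response <- rbinom(n, 1, plogis(2 * d$x1 - 1.5 * d$x2))
  d
}

test_that("a perfectly separable covariate drives training AUC to 1", {
  set.seed(2)
  d <- data.frame(x = c(rnorm(100, -2), rnorm(100, 2)),
                  response = rep(0:1, each = 100))
  fit <- fitBRT(d, "x", nTrees = 200, treeComplexity = 1,
                learningRate = 0.1, bagFraction = 1, seed = 1)
  expect_gt(aucScore(predictBRT(fit, d), d$response), 0.999)
})

test_that("zero trees predict the training prevalence", {
  d <- simData(200)
  fit <- fitBRT(d, c("x1", "x2"), nTrees = 50, seed = 1)
  expect_equal(unique(round(predictBRT(fit, d, nTrees = 0), 10)),
               round(mean(d$response), 10))
})

test_that("single-class responses are rejected", {
  d <- data.frame(x = rnorm(50), response = 1)
  expect_error(fitBRT(d, "x"), "single-class")
})

test_that("relative influences are non-negative, sum to 100, and are zero
          for unused covariates", {
  d <- simData()
  d$never <- 0   # constant, cannot be split on
  fit <- fitBRT(d, c("x1", "x2", "x3", "never"), nTrees = 300,
                treeComplexity = 2, learningRate = 0.05, seed = 2)
  ri <- relativeInfluence(fit)
  expect_true(all(ri >= 0))
  expect_equal(sum(ri), 100, tolerance = 1e-9)
  expect_equal(unname(ri["never"]), 0)
  single <- fitBRT(d, "x1", nTrees = 50, treeComplexity = 1, seed = 1)
  expect_equal(unname(relativeInfluence(single)["x1"]), 100)
})

test_that("on a pure-noise response the random control is as influential as
          real covariates", {
  set.seed(9)
  d <- data.frame(x1 = rnorm(400), x2 = rnorm(400), x3 = rnorm(400),
                  response = rbinom(400, 1, 0.5))
  d <- addRandomControl(d, seed = 4)
  fit <- fitBRT(d, c("x1", "x2", "x3", "RAND"), nTrees = 200,
                treeComplexity = 2, learningRate = 0.05, seed = 3)
  ri <- relativeInfluence(fit)
  # no covariate dwarfs the control under the null
  expect_lt(max(ri) / max(ri["RAND"], 1), 8)
  expect_gt(ri["RAND"], 5)
})

test_that("boosting is deterministic and, without bagging, invariant to row
          order", {
  d <- simData(300, seed = 5)
  f1 <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 100, seed = 7)
  f2 <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 100, seed = 7)
  expect_identical(f1@trees, f2@trees)
  perm <- sample(nrow(d))
  fa <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 60, bagFraction = 1,
               seed = 1)
  fb <- fitBRT(d[perm, ], c("x1", "x2", "x3"), nTrees = 60, bagFraction = 1,
               seed = 99)
  expect_equal(predictBRT(fa, d), predictBRT(fb, d), tolerance = 1e-10)
})

test_that("compiled predictions equal a plain-R tree walk, with and without
          missing values", {
  d <- simData(150, seed = 8)
  d$x1[sample(150, 15)] <- NA
  fit <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 80, treeComplexity = 3,
                seed = 2)
  expect_equal(predictBRT(fit, d), predictBRT_R(fit, d[c("x1", "x2", "x3")]),
               tolerance = 1e-12)
})

test_that("partial dependence is flat for ignored covariates and monotone
          for a monotone signal", {
  set.seed(11)
  d <- data.frame(x = rnorm(400), junk = rnorm(400))
  d$response <- rbinom(400, 1, plogis(2 * d$x))
  # a covariate the trees never split on has an exactly flat curve
  d$flat <- 1
  fitF <- fitBRT(d, c("x", "flat"), nTrees = 100, treeComplexity = 1,
                 learningRate = 0.05, seed = 1)
  pdFlat <- partialDependence(fitF, "flat", values = c(0, 1, 2))
  expect_equal(diff(range(pdFlat$yhat)), 0)
  # a noise covariate moves the curve only slightly in a short run
  fit <- fitBRT(d, c("x", "junk"), nTrees = 80, treeComplexity = 1,
                learningRate = 0.05, seed = 1)
  pdJunk <- partialDependence(fit, "junk",
                              values = quantile(d$junk, c(.1, .5, .9)))
  expect_lt(diff(range(pdJunk$yhat)), 0.15)
  pdX <- partialDependence(fit, "x")
  expect_gt(cor(pdX$value, pdX$yhat, method = "spearman"), 0.95)
  expect_error(partialDependence(fit, "nope"), "unknown")
})

test_that("partial dependence matches direct averaging by brute force", {
  d <- simData(150, seed = 3)
  fit <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 60, treeComplexity = 2,
                seed = 4)
  vals <- quantile(d$x1, c(0.2, 0.5, 0.8), names = FALSE)
  pd <- partialDependence(fit, "x1", values = vals)
  oracle <- vapply(vals, function(v) {
    X <- d[c("x1", "x2", "x3")]
    X$x1 <- v
    plogis(mean(qlogis(predictBRT_R(fit, X))))
  }, numeric(1))
  expect_equal(pd$yhat, oracle, tolerance = 1e-10)
})

test_that("blocked tuning uses one fold per individual and respects the
          tie-break priorities", {
  d <- simData(500, seed = 12)
  tune <- tuneBRT(d, c("x1", "x2", "x3"), foldColumn = "id",
                  grid = brtGrid(treeComplexity = c(1, 3),
                                 learningRate = c(0.1, 0.05),
                                 bagFraction = 0.6, maxTrees = 200,
                                 treeStep = 50),
                  minTrees = 100, seed = 1)
  expect_equal(tune$cv$nFolds, length(unique(d$id)))
  expect_setequal(names(tune$cv$foldAUC), unique(d$id))
  expect_gt(tune$cv$meanAUC, 0.7)
  expect_true(tune$config$nTrees > 100)
  # ties prefer larger learning rates, then smaller complexity, then fewer
  # trees: force a tie by flattening the AUC table and re-selecting
  expect_warning(tuneBRT(d[d$id %in% c("s1", "s2"), ],
                         c("x1", "x2"), foldColumn = "id",
                         grid = brtGrid(1, 0.1, 0.5, maxTrees = 100,
                                        treeStep = 50),
                         minTrees = 1000, seed = 1),
                 "relaxed")
})

test_that("the default hyperparameter grid matches the published candidate
          sets (36 combinations)", {
  g <- brtGrid()
  expect_equal(length(g$treeComplexity) * length(g$learningRate) *
                 length(g$bagFraction), 36L)
  expect_equal(max(g$maxTrees), 10000)
  expect_equal(g$treeStep, 50)
  p <- brtPreset("paper2019")
  expect_equal(p$nTrees, 1050)
  expect_equal(p$treeComplexity, 5)
})

test_that("bootstrap ensemble resamples half the data and summaries are
          bounded by the member predictions", {
  d <- simData(200, seed = 13)
  fits <- bootstrapEnsemble(d, c("x1", "x2", "x3"),
                            config = list(nTrees = 50, treeComplexity = 2,
                                          learningRate = 0.05,
                                          bagFraction = 0.6),
                            n = 7, seed = 2)
  expect_length(fits, 7L)
  preds <- vapply(fits, function(f) predictBRT(f, d), numeric(nrow(d)))
  med <- apply(preds, 1, median)
  expect_true(all(med >= apply(preds, 1, min) - 1e-12 &
                    med <= apply(preds, 1, max) + 1e-12))
})

test_that("prediction maps: constant fields give constant maps, identical
          fits give zero CI range, monthly means are exact", {
  st <- smallWorld()
  d <- simData(200, seed = 14)
  names(d)[names(d) == "x1"] <- "SST"
  names(d)[names(d) == "x2"] <- "CHL"
  fit <- fitBRT(d, c("SST", "CHL"), nTrees = 40, seed = 1,
                keepData = FALSE)
  fits <- list(fit, fit, fit)
  dts <- envDates(st)[2:4]
  maps <- predictMaps(fits, st, dts)
  expect_true(all(maps@median >= 0 & maps@median <= 1, na.rm = TRUE))
  expect_true(all(maps@ciRange == 0, na.rm = TRUE))
  expect_true(all(is.na(maps@median[, , 1][landMask(st)])))
  mm <- monthlyMean(maps)
  expect_length(mm, 1L)
  expect_equal(mm[["2019-03"]],
               apply(maps@median, c(1, 2), mean))
  expect_error(predictMaps(fits, st, envDates(st)[1] - 100), "outside")
})

test_that("JSON round-trip preserves BRT predictions and influence", {
  d <- simData(120, seed = 21)
  fit <- fitBRT(d, c("x1", "x2", "x3"), nTrees = 30, treeComplexity = 2,
                seed = 1)
  path <- tempfile(fileext = ".json")
  writeBRT(fit, path)
  back <- readBRT(path)
  expect_equal(predictBRT(back, d), predictBRT(fit, d), tolerance = 1e-12)
  expect_equal(relativeInfluence(back), relativeInfluence(fit))
})
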