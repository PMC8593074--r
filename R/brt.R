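# Bernoulli boosted regression trees: stagewise gradient boosting of the
# Bernoulli deviance with depth-limited least-squares trees, bagged rows and
# shrinkage; leave-one-individual-out block cross-validation with staged
# tree-count scans; relative influence, partial dependence, and the
# half-data bootstrap ensemble behind the prediction maps.

#' Hyperparameter grid for BRT tuning
#'
#' The default candidate sets scan tree counts 50-10,000 in 50-tree
#' increments, tree complexity 1/3/5, learning rate 0.005/0.001/0.05/0.01
#' and bag fraction 0.5/0.6/0.7 (36 combinations).
#'
#' @param treeComplexity,learningRate,bagFraction Candidate values.
#' @param maxTrees,treeStep Tree-count scan.
#' @return List of class `"brtGrid"`.
#' @export
brtGrid <- function(treeComplexity = c(1, 3, 5),
                    learningRate = c(0.005, 0.001, 0.05, 0.01),
                    bagFraction = c(0.5, 0.6, 0.7),
                    maxTrees = 10000, treeStep = 50) {
  g <- list(treeComplexity = treeComplexity, learningRate = learningRate,
            bagFraction = bagFraction, maxTrees = maxTrees,
            treeStep = treeStep)
  class(g) <- "brtGrid"
  g
}

#' Named BRT configuration presets
#'
#' `"paper2019"` is the configuration selected by the original winter
#' fur-seal analysis: 1050 trees, tree complexity 5, learning rate 0.01,
#' bag fraction 0.5.
#'
#' @param name Preset name.
#' @return List with `nTrees`, `treeComplexity`, `learningRate`,
#'   `bagFraction`.
#' @export
brtPreset <- function(name = "paper2019") {
  switch(name,
         paper2019 = list(nTrees = 1050, treeComplexity = 5,
                          learningRate = 0.01, bagFraction = 0.5),
         stop("unknown preset: ", name))
}

.asMatrixX <- function(data, covariates) {
  X <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  X
}


#' Fit a Bernoulli boosted regression tree model
#'
#' Stagewise gradient boosting: at each iteration a regression tree with at
#' most `treeComplexity` splits is fitted to the current Bernoulli gradient
#' on a random `bagFraction` subsample, shrunk by `learningRate` and added
#' to the ensemble. Missing covariate values are routed to the majority
#' child at each split. Deterministic under a fixed seed.
#'
#' @param data Table with the response and covariate columns.
#' @param covariates Covariate column names.
#' @param response Response column name (0/1).
#' @param nTrees,treeComplexity,learningRate,bagFraction Boosting
#'   parameters.
#' @param minNode Minimum observations per terminal node.
#' @param seed Integer seed for the bagging stream.
#' @param keepData Keep the training matrix (needed for partial
#'   dependence).
#' @return A [BRTFit-class].
#' @export
fitBRT <- function(data, covariates, response = "response",
                   nTrees = 1000, treeComplexity = 3, learningRate = 0.01,
                   bagFraction = 0.5, minNode = 5, seed = 1L,
                   keepData = TRUE) {
  y <- as.numeric(as.data.frame(data)[[response]])
  if (length(unique(y[!is.na(y)])) < 2)
    stop("single-class response: cannot fit a Bernoulli model")
  X <- .asMatrixX(data, covariates)
  fit <- gbm_fit_cpp(X, y, as.integer(nTrees), as.integer(treeComplexity),
                     learningRate, bagFraction, as.integer(minNode),
                     as.integer(seed))
  imp <- fit$importance
  rownames(imp) <- covariates
  new("BRTFit",
      trees = fit$trees, init = fit$init, varNames = covariates,
      importanceMatrix = imp,
      config = list(nTrees = nTrees, treeComplexity = treeComplexity,
                    learningRate = learningRate, bagFraction = bagFraction,
                    minNode = minNode, seed = seed),
      trainX = if (keepData) X else matrix(0, 0, length(covariates)),
      trainSignature = c(nrow(X), ncol(X), sum(X[!is.na(X)]), sum(y)))
}

#' Predict from a BRT fit
#'
#' @param fit A [BRTFit-class].
#' @param newdata Table or matrix with the training covariates.
#' @param nTrees Use only the first `nTrees` trees (default: all); 0 gives
#'   the intercept-only prediction (the training prevalence on the
#'   response scale).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @return Numeric vector of predictions.
#' @export
predictBRT <- function(fit, newdata, nTrees = NULL, type = "response") {
  stopifnot(is(fit, "BRTFit"))
  X <- if (is.matrix(newdata)) newdata else .asMatrixX(newdata, fit@varNames)
  eta <- gbm_predict_staged_cpp(X, fit@trees, fit@init,
                                as.integer(if (is.null(nTrees))
                                  length(fit@trees) else nTrees))[, 1]
  if (type == "response") plogis(eta) else eta
}

#' Relative influence of covariates
#'
#' Per covariate, the sum of squared-error reductions over all splits using
#' it, normalised to sum to 100%. Unused covariates get exactly 0.
#'
#' @param fit A [BRTFit-class].
#' @param nTrees Restrict to the first `nTrees` trees.
#' @return Named numeric vector summing to 100 (all-zero if no splits).
#' @export
relativeInfluence <- function(fit, nTrees = NULL) {
  stopifnot(is(fit, "BRTFit"))
  k <- if (is.null(nTrees)) ncol(fit@importanceMatrix) else nTrees
  g <- rowSums(fit@importanceMatrix[, seq_len(k), drop = FALSE])
  tot <- sum(g)
  if (tot <= 0) return(setNames(rep(0, length(g)), fit@varNames))
  setNames(100 * g / tot, fit@varNames)
}

#' Partial dependence of the model on one covariate
#'
#' For each grid value, the model prediction averaged over the training
#' rows with that covariate fixed at the value (averaged on the logit
#' scale, then inverse-transformed).
#'
#' @param fit A [BRTFit-class] fitted with `keepData = TRUE`.
#' @param covariate Covariate name.
#' @param values Evaluation grid (default: 25 quantiles of the training
#'   values).
#' @param nTrees Restrict to the first `nTrees` trees.
#' @return data.frame with `value` and `yhat` (probability scale).
#' @export
partialDependence <- function(fit, covariate, values = NULL, nTrees = NULL) {
  stopifnot(is(fit, "BRTFit"))
  j <- match(covariate, fit@varNames)
  if (is.na(j)) stop("unknown covariate: ", covariate)
  if (nrow(fit@trainX) == 0)
    stop("fit was built with keepData = FALSE; no training rows to average")
  if (is.null(values))
    values <- unique(quantile(fit@trainX[, j], probs = seq(0, 1, length.out = 25),
                              na.rm = TRUE, names = FALSE))
  nT <- as.integer(if (is.null(nTrees)) length(fit@trees) else nTrees)
  yhat <- vapply(values, function(v) {
    X <- fit@trainX
    X[, j] <- v
    mean(gbm_predict_staged_cpp(X, fit@trees, fit@init, nT)[, 1])
  }, numeric(1))
  data.frame(value = values, yhat = plogis(yhat))
}

#' Tune a BRT by leave-one-individual-out cross-validation
#'
#' For every (tree complexity, learning rate, bag fraction) combination the
#' staged ensemble is evaluated on each held-out individual every
#' `treeStep` trees -- all data of the held-out individual (presences and
#' its simulations' pseudo-absences) are excluded from training. The
#' combination with more than 1000 trees maximising the mean
#' cross-validated AUC is selected; ties prefer larger learning rates, then
#' smaller tree complexities, then fewer trees. Cross-validated deviance
#' explained is pooled over folds against fold-specific intercept-only
#' models.
#'
#' @param data Table with response, covariates and an individual id column.
#' @param covariates Covariate names.
#' @param response Response column.
#' @param foldColumn Column defining the blocks (default `"id"`).
#' @param grid A [brtGrid()].
#' @param minTrees Selection constraint (default > 1000; relaxed with a
#'   warning when no candidate qualifies).
#' @param seed Integer seed.
#' @return List of class `"brtTune"`: `config` (selected parameters),
#'   `cv` (per-fold AUC at the selection, mean AUC, deviance explained),
#'   `scan` (mean AUC per combination and tree count), `fit` (final model
#'   refitted on all data).
#' @export
tuneBRT <- function(data, covariates, response = "response",
                    foldColumn = "id", grid = brtGrid(), minTrees = 1000,
                    seed = 1L) {
  df <- as.data.frame(data)
  folds <- unique(df[[foldColumn]])
  if (length(folds) < 2) stop("need at least 2 individuals for blocked CV")
  stages <- seq(grid$treeStep, grid$maxTrees, by = grid$treeStep)
  combos <- expand.grid(treeComplexity = grid$treeComplexity,
                        learningRate = grid$learningRate,
                        bagFraction = grid$bagFraction)
  y <- as.numeric(df[[response]])
  scan <- list()
  aucArr <- array(NA_real_, c(nrow(combos), length(stages), length(folds)))
  devArr <- array(NA_real_, c(nrow(combos), length(stages)))
  nullDev <- 0
  for (ci in seq_len(nrow(combos))) {
    devTot <- numeric(length(stages))
    nd <- 0
    for (fi in seq_along(folds)) {
      test <- df[[foldColumn]] == folds[fi]
      train <- df[!test, , drop = FALSE]
      if (length(unique(train[[response]])) < 2) next
      fit <- fitBRT(train, covariates, response,
                    nTrees = grid$maxTrees,
                    treeComplexity = combos$treeComplexity[ci],
                    learningRate = combos$learningRate[ci],
                    bagFraction = combos$bagFraction[ci],
                    seed = seed + fi, keepData = FALSE)
      Xte <- .asMatrixX(df[test, , drop = FALSE], covariates)
      etas <- gbm_predict_staged_cpp(Xte, fit@trees, fit@init,
                                     as.integer(stages))
      yte <- y[test]
      p0 <- mean(train[[response]])
      nd <- nd + .bernoulliDeviance(yte, rep(p0, length(yte)))
      for (si in seq_along(stages)) {
        aucArr[ci, si, fi] <- aucScore(etas[, si], yte)
        devTot[si] <- devTot[si] + .bernoulliDeviance(yte, plogis(etas[, si]))
      }
    }
    devArr[ci, ] <- devTot
    if (ci == 1) nullDev <- nd
  }
  meanAUC <- apply(aucArr, c(1, 2), mean, na.rm = TRUE)
  # selection: > minTrees, maximise AUC; ties -> larger lr, smaller tc,
  # fewer trees
  eligible <- stages > minTrees
  if (!any(eligible)) {
    warning("no candidate tree count exceeds ", minTrees,
            "; constraint relaxed")
    eligible <- rep(TRUE, length(stages))
  }
  cand <- expand.grid(ci = seq_len(nrow(combos)), si = which(eligible))
  cand$auc <- meanAUC[cbind(cand$ci, cand$si)]
  cand$lr <- combos$learningRate[cand$ci]
  cand$tc <- combos$treeComplexity[cand$ci]
  cand$trees <- stages[cand$si]
  cand <- cand[is.finite(cand$auc), , drop = FALSE]
  ord <- order(-cand$auc, -cand$lr, cand$tc, cand$trees)
  best <- cand[ord[1], ]
  config <- list(nTrees = best$trees,
                 treeComplexity = combos$treeComplexity[best$ci],
                 learningRate = combos$learningRate[best$ci],
                 bagFraction = combos$bagFraction[best$ci])
  foldAUC <- setNames(aucArr[best$ci, best$si, ], as.character(folds))
  devExpl <- 1 - devArr[best$ci, best$si] / nullDev
  finalFit <- fitBRT(df, covariates, response,
                     nTrees = config$nTrees,
                     treeComplexity = config$treeComplexity,
                     learningRate = config$learningRate,
                     bagFraction = config$bagFraction, seed = seed)
  out <- list(config = config,
              cv = list(foldAUC = foldAUC,
                        meanAUC = mean(foldAUC, na.rm = TRUE),
                        devianceExplained = devExpl,
                        nFolds = length(folds)),
              scan = list(combos = combos, stages = stages,
                          meanAUC = meanAUC),
              fit = finalFit)
  class(out) <- "brtTune"
  out
}

#' @export
print.brtTune <- function(x, ...) {
  cat(sprintf(
    "BRT tuning: %d folds; selected trees=%d tc=%d lr=%g bag=%g\n",
    x$cv$nFolds, x$config$nTrees, x$config$treeComplexity,
    x$config$learningRate, x$config$bagFraction))
  cat(sprintf("  CV AUC %.3f, deviance explained %.1f%%\n",
              x$cv$meanAUC, 100 * x$cv$devianceExplained))
  invisible(x)
}

#' Half-data bootstrap ensemble of BRT fits
#'
#' Fits the model `n` times, each on a resample of size floor(N/2) drawn
#' with replacement from the rows; single-class resamples are redrawn (the
#' number of redraws is reported via a message).
#'
#' @param data Training table.
#' @param covariates,response As in [fitBRT()].
#' @param config List with `nTrees`, `treeComplexity`, `learningRate`,
#'   `bagFraction` (e.g. from [tuneBRT()] or [brtPreset()]).
#' @param n Number of fits (study default 50).
#' @param seed Integer seed.
#' @return List of [BRTFit-class] objects.
#' @export
bootstrapEnsemble <- function(data, covariates, response = "response",
                              config, n = 50, seed = 1L) {
  df <- as.data.frame(data)
  N <- nrow(df)
  m <- floor(N / 2)
  .withSeed(seed, {
    redraws <- 0L
    fits <- vector("list", n)
    for (b in seq_len(n)) {
      repeat {
        idx <- sample.int(N, m, replace = TRUE)
        if (length(unique(df[[response]][idx])) >= 2) break
        redraws <- redraws + 1L
      }
      fits[[b]] <- fitBRT(df[idx, , drop = FALSE], covariates, response,
                          nTrees = config$nTrees,
                          treeComplexity = config$treeComplexity,
                          learningRate = config$learningRate,
                          bagFraction = config$bagFraction,
                          seed = seed + b, keepData = FALSE)
    }
    if (redraws > 0)
      message(redraws, " single-class bootstrap resample(s) redrawn")
    fits
  })
}

#' Daily ensemble prediction maps
#'
#' Predicts habitat suitability for every sea cell on the requested dates
#' from each bootstrap fit, and summarises per cell and day by the median
#' and the 95% confidence-interval range of the ensemble. The
#' random-number control covariate, when present, is fixed at its training
#' mean (50.5). Land cells and cells with missing covariates are `NA`.
#'
#' @param fits List of [BRTFit-class] (e.g. from [bootstrapEnsemble()]).
#' @param stack The [EnvStack-class] with all model covariates.
#' @param dates Dates to predict (must lie within the stack).
#' @param randName Name of the random control column (set to 50.5).
#' @return An [EnsemblePrediction-class].
#' @export
predictMaps <- function(fits, stack, dates, randName = "RAND") {
  dates <- as.Date(dates)
  if (any(!dates %in% envDates(stack)))
    stop("dates outside the stack's range")
  covs <- fits[[1]]@varNames
  lon <- envLon(stack); lat <- envLat(stack)
  nlon <- length(lon); nlat <- length(lat)
  sea <- which(!landMask(stack))
  med <- array(NA_real_, c(nlon, nlat, length(dates)))
  cir <- array(NA_real_, c(nlon, nlat, length(dates)))
  for (di in seq_along(dates)) {
    X <- matrix(NA_real_, length(sea), length(covs),
                dimnames = list(NULL, covs))
    for (cj in seq_along(covs)) {
      nm <- covs[cj]
      if (nm == randName) {
        X[, cj] <- 50.5
      } else {
        m <- envLayer(stack, nm,
                      date = if (nm %in% names(stack@static)) NULL
                             else dates[di])
        X[, cj] <- m[sea]
      }
    }
    preds <- vapply(fits, function(f)
      plogis(gbm_predict_staged_cpp(X, f@trees, f@init,
                                    as.integer(length(f@trees)))[, 1]),
      numeric(nrow(X)))
    mm <- apply(preds, 1, median)
    qq <- apply(preds, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    layerM <- matrix(NA_real_, nlon, nlat); layerM[sea] <- mm
    layerC <- matrix(NA_real_, nlon, nlat); layerC[sea] <- qq[2, ] - qq[1, ]
    med[, , di] <- layerM
    cir[, , di] <- layerC
  }
  new("EnsemblePrediction", lon = lon, lat = lat, dates = dates,
      median = med, ciRange = cir, nFits = length(fits))
}

#' Monthly means of daily prediction maps
#'
#' Averages the daily maps over exactly the days available in each calendar
#' month.
#'
#' @param pred An [EnsemblePrediction-class].
#' @param what `"median"` or `"ciRange"`.
#' @return Named list of `[lon, lat]` matrices, one per `"YYYY-MM"`.
#' @export
monthlyMean <- function(pred, what = c("median", "ciRange")) {
  what <- match.arg(what)
  arr <- slot(pred, what)
  keys <- .monthKey(pred@dates)
  lapply(split(seq_along(keys), keys), function(ix) {
    apply(arr[, , ix, drop = FALSE], c(1, 2), mean)
  })
}
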