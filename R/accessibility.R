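# Accessibility as a monotone non-increasing function of distance beyond
# the sea-ice edge: binomial regression on an I-spline basis with
# sign-constrained coefficients, bootstrapped 50 times on half the data,
# then used to weight the habitat-suitability maps (ice interior forced
# inaccessible).

# I-spline basis of `degree` with the given interior knots on [a, b]:
# I_j(x) = sum_{m >= j} B_m(x) over order-(degree+1) B-splines, dropping the
# first column (identically 1). Each column is monotone increasing 0 -> 1.
.isplineBasis <- function(x, interior, boundary, degree = 3L) {
  k <- degree
  knots <- c(rep(boundary[1], k + 1L), interior, rep(boundary[2], k + 1L))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  B <- splines::splineDesign(knots, xc, ord = k + 1L)
  S <- t(apply(B, 1, function(row) rev(cumsum(rev(row)))))
  if (nrow(B) == 1) S <- matrix(S, nrow = 1)
  S[, -1, drop = FALSE]
}

#' Build the cell-level accessibility table
#'
#' Every open-water cell of the study grid receives a binary response --
#' 1 if any observed or simulated location fell in the cell during the
#' study, 0 otherwise -- and its distance beyond the ice edge (km,
#' averaged over the study days on which the cell was open water).
#'
#' @param gridded Gridded locations from [gridLocations()] (presences and
#'   pseudo-absences together mark visited cells).
#' @param stack [EnvStack-class] with the EDGE layer derived.
#' @return data.frame with `ix`, `iy`, `response`, `edgeKm`, `meanSIC`.
#' @export
buildAccessTable <- function(gridded, stack) {
  if (!"EDGE" %in% names(stack@dynamic))
    stop("derive the EDGE layer first (deriveCovariates)")
  land <- landMask(stack)
  sea <- which(!land, arr.ind = TRUE)
  edge <- apply(stack@dynamic$EDGE, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  sicM <- apply(stack@dynamic$SIC, c(1, 2), mean, na.rm = TRUE)
  visited <- matrix(FALSE, nrow(land), ncol(land))
  visited[cbind(gridded$ix, gridded$iy)] <- TRUE
  data.frame(ix = sea[, 1], iy = sea[, 2],
             response = as.integer(visited[sea]),
             edgeKm = edge[sea], meanSIC = sicM[sea])
}

# penalised Bernoulli deviance fit of eta = alpha - beta' I(d), beta >= 0
.fitMonotone <- function(d, y, interior, boundary, degree, lambda) {
  B <- .isplineBasis(d, interior, boundary, degree)
  nb <- ncol(B)
  obj <- function(par) {
    eta <- par[1] - as.vector(B %*% par[-1])
    p <- plogis(eta)
    .bernoulliDeviance(y, p) / length(y) + lambda * sum(par[-1]^2)
  }
  gr <- function(par) {
    eta <- par[1] - as.vector(B %*% par[-1])
    p <- plogis(eta)
    r <- p - y
    c(2 * sum(r) / length(y),
      -2 * as.vector(crossprod(B, r)) / length(y) + 2 * lambda * par[-1])
  }
  st <- c(qlogis(pmin(pmax(mean(y), 0.01), 0.99)), rep(0.1, nb))
  f <- optim(st, obj, gr, method = "L-BFGS-B",
             lower = c(-Inf, rep(0, nb)),
             control = list(maxit = 500))
  list(alpha = f$par[1], beta = pmax(f$par[-1], 0), value = f$value)
}

#' Fit the bootstrap family of accessibility curves
#'
#' Each of `nBoot` fits is a binomial regression of the binary access
#' response on distance beyond the ice edge, with the fitted probability
#' constrained to be monotone non-increasing (logistic model on an I-spline
#' basis with non-negative coefficients entering with a negative sign).
#' Fits use half the data sampled with replacement. The ridge penalty is
#' chosen once on the full table by 2-fold cross-validated deviance over a
#' small fixed grid.
#'
#' @param table From [buildAccessTable()] (columns `response`, `edgeKm`).
#' @param nBoot Number of bootstrap members (study default 50).
#' @param seed Integer seed.
#' @param nKnots Interior knots (quantiles of the distances).
#' @param degree Spline degree.
#' @param lambdaGrid Candidate ridge penalties.
#' @return An [AccessibilityCurve-class].
#' @export
fitAccessibility <- function(table, nBoot = 50, seed = 1L, nKnots = 4,
                             degree = 3L, lambdaGrid = c(0, 1e-4, 1e-2, 1)) {
  tab <- table[is.finite(table$edgeKm), , drop = FALSE]
  y <- tab$response
  if (length(unique(y)) < 2)
    stop("accessibility response is single-class")
  d <- tab$edgeKm
  boundary <- c(0, max(d) * 1.001 + 1e-6)
  interior <- unique(quantile(d[d > 0], probs = seq_len(nKnots) /
                                (nKnots + 1), names = FALSE))
  interior <- interior[interior > boundary[1] & interior < boundary[2]]
  .withSeed(seed, {
    lambda <- if (length(lambdaGrid) > 1) {
      half <- sample.int(length(y)) <= length(y) / 2
      cvDev <- vapply(lambdaGrid, function(lm) {
        dev <- 0
        for (tr in list(half, !half)) {
          f <- .fitMonotone(d[tr], y[tr], interior, boundary, degree, lm)
          B <- .isplineBasis(d[!tr], interior, boundary, degree)
          p <- plogis(f$alpha - as.vector(B %*% f$beta))
          dev <- dev + .bernoulliDeviance(y[!tr], p)
        }
        dev
      }, numeric(1))
      lambdaGrid[which.min(cvDev)]
    } else lambdaGrid
    n <- length(y); m <- floor(n / 2)
    alphas <- numeric(nBoot)
    betas <- matrix(0, length(interior) + degree, nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, m, replace = TRUE)
        if (length(unique(y[idx])) >= 2) break
      }
      f <- .fitMonotone(d[idx], y[idx], interior, boundary, degree, lambda)
      alphas[b] <- f$alpha
      betas[, b] <- f$beta
    }
    new("AccessibilityCurve", knots = interior, boundary = boundary,
        degree = as.integer(degree), alpha = alphas, beta = betas,
        lambda = lambda)
  })
}

#' Evaluate accessibility curves
#'
#' @param curve An [AccessibilityCurve-class].
#' @param distance Distances beyond the ice edge (km).
#' @param member `NULL` for the median over the bootstrap family, an index
#'   for one member, or `"all"` for the full matrix.
#' @return Access probabilities in `[0, 1]` (matrix if `member = "all"`).
#' @export
predictAccess <- function(curve, distance, member = NULL) {
  stopifnot(is(curve, "AccessibilityCurve"))
  B <- .isplineBasis(distance, curve@knots, curve@boundary, curve@degree)
  etas <- outer(rep(1, length(distance)), curve@alpha) - B %*% curve@beta
  P <- plogis(etas)
  if (identical(member, "all")) return(P)
  if (!is.null(member)) return(P[, member])
  apply(P, 1, median)
}

#' Weight habitat suitability by accessibility
#'
#' Per cell and day: `weighted = suitability * accessibility(distance
#' beyond the ice edge)`, evaluated on that day's EDGE layer; cells with
#' ice fraction above `sicThreshold` are set to 0 (not accessible); land
#' stays `NA`.
#'
#' @param pred [EnsemblePrediction-class] habitat maps.
#' @param curve [AccessibilityCurve-class].
#' @param stack [EnvStack-class] with SIC and EDGE layers.
#' @param sicThreshold Ice-fraction cut-off (default 0.15).
#' @return Array `[lon, lat, day]` of weighted suitability in `[0, 1]`.
#' @export
weightPredictions <- function(pred, curve, stack, sicThreshold = 0.15) {
  if (any(!pred@dates %in% envDates(stack)))
    stop("prediction dates missing from the stack")
  out <- array(NA_real_, dim(pred@median))
  for (di in seq_along(pred@dates)) {
    sic <- envLayer(stack, "SIC", pred@dates[di])
    edge <- envLayer(stack, "EDGE", pred@dates[di])
    hab <- pred@median[, , di]
    w <- matrix(NA_real_, nrow(hab), ncol(hab))
    okEdge <- is.finite(edge)
    w[okEdge] <- predictAccess(curve, edge[okEdge])
    res <- hab * w
    res[!is.na(sic) & sic > sicThreshold] <- 0
    out[, , di] <- res
  }
  out
}
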