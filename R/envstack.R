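# Derived environmental covariates on the common 0.1-degree grid, covariate
# matching to presence/absence records, and the Spearman collinearity
# screen. Canonical covariate order (used for screen tie-breaks):

.COVARIATE_ORDER <- c("BAT", "SLP", "SIC", "EDGE", "SIT", "SST", "SSTg",
                      "SAL", "SALg", "SSH", "EKE", "CHL", "MLD")

# pad a matrix by replicating edges (used by the Horn stencil)
.padReplicate <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Terrain slope of a gridded field (Horn's method)
#'
#' Eight-neighbour finite-difference slope in degrees, with cell dimensions
#' corrected for latitude (east-west metres shrink with cos(lat)). Edge
#' cells use replicated neighbours; missing neighbours are replaced by the
#' centre value so isolated gaps do not propagate.
#'
#' @param m Matrix `[lon, lat]` of values in metres (or any unit; the slope
#'   of an SST field is a "gradient" in the same degrees-of-inclination
#'   sense, with 1 unit treated as 1 m).
#' @param lon,lat Cell-centre coordinates (degrees).
#' @return Matrix of slope in degrees; `NA` where the centre is `NA`.
#' @export
computeSlope <- function(m, lon, lat) {
  if (all(is.na(m))) stop("all-missing raster")
  nlon <- length(lon); nlat <- length(lat)
  stopifnot(all(dim(m) == c(nlon, nlat)))
  cellDeg <- diff(lon[1:2])
  p <- .padReplicate(m)
  idx <- function(di, dj) p[(2 + di):(nlon + 1 + di),
                            (2 + dj):(nlat + 1 + dj), drop = FALSE]
  ctr <- m
  nb <- function(di, dj) {
    v <- idx(di, dj)
    v[is.na(v)] <- ctr[is.na(v)]
    v
  }
  dxM <- matrix(rep(cellDeg * 111320 * cos(lat * pi / 180), each = nlon),
                nlon, nlat)
  dyM <- cellDeg * 110574
  gx <- ((nb(1, -1) + 2 * nb(1, 0) + nb(1, 1)) -
           (nb(-1, -1) + 2 * nb(-1, 0) + nb(-1, 1))) / (8 * dxM)
  gy <- ((nb(-1, 1) + 2 * nb(0, 1) + nb(1, 1)) -
           (nb(-1, -1) + 2 * nb(0, -1) + nb(1, -1))) / (8 * dyM)
  out <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  out[is.na(m)] <- NA_real_
  out
}

#' @rdname computeSlope
#' @export
computeGradient <- computeSlope

#' Eddy kinetic energy from surface velocity
#'
#' `EKE = 0.5 * (U^2 + V^2)` cellwise, in m^2/s^2. The log(x+1) transform
#' used for modelling is applied separately at stack-assembly time.
#'
#' @param u,v Co-registered velocity component matrices (m/s).
#' @return Matrix of EKE.
#' @export
computeEKE <- function(u, v) {
  if (!all(dim(u) == dim(v))) stop("U and V shapes do not match")
  0.5 * (u^2 + v^2)
}

#' Distance to the sea-ice edge
#'
#' For each open-water sea cell, the shortest-path distance (km) to the
#' nearest cell with ice fraction above `threshold`, where paths traverse
#' sea cells only (8-connected, great-circle edge lengths; land blocks
#' propagation). Cells above the threshold get distance 0; land cells are
#' `NA`; open cells unreachable from any ice cell are `Inf`.
#'
#' @param sic Ice-fraction matrix `[lon, lat]` in `[0, 1]`.
#' @param land Logical land mask.
#' @param lon,lat Cell-centre coordinates.
#' @param threshold Ice-edge concentration (default 0.15, i.e. the 15%
#'   contour).
#' @return Matrix of distances in km, or all-`NA` (with a message) when no
#'   cell exceeds the threshold.
#' @export
distanceToIceEdge <- function(sic, land, lon, lat, threshold = 0.15) {
  stopifnot(all(dim(sic) == dim(land)))
  open <- !land
  src <- open & !is.na(sic) & sic > threshold
  if (!any(src)) {
    message("no sea-ice cells above the threshold; distances undefined")
    out <- matrix(NA_real_, nrow(sic), ncol(sic))
    return(out)
  }
  grid_distance_cpp(open, src, lon, lat)
}

#' Bilinear regridding
#'
#' Interpolates a source raster to target cell centres using the four
#' enclosing source cells; exact on affine fields and the identity on
#' matching grids. Missing source cells propagate missing; target points
#' outside the source hull are `NA`.
#'
#' @param m Source matrix `[lon, lat]`.
#' @param srcLon,srcLat Source cell centres (strictly increasing).
#' @param dstLon,dstLat Target cell centres.
#' @return Matrix `[dstLon, dstLat]`.
#' @export
regridBilinear <- function(m, srcLon, srcLat, dstLon, dstLat) {
  if (max(dstLon) < min(srcLon) || min(dstLon) > max(srcLon) ||
      max(dstLat) < min(srcLat) || min(dstLat) > max(srcLat))
    stop("source and target grids are disjoint")
  n1 <- length(dstLon); n2 <- length(dstLat)
  out <- matrix(NA_real_, n1, n2)
  i0 <- findInterval(dstLon, srcLon)
  j0 <- findInterval(dstLat, srcLat)
  for (a in seq_len(n1)) {
    ia <- i0[a]
    for (b in seq_len(n2)) {
      jb <- j0[b]
      if (ia < 1 || ia >= length(srcLon)) {
        if (dstLon[a] == srcLon[length(srcLon)]) { iaa <- length(srcLon) - 1L }
        else next
      } else iaa <- ia
      if (jb < 1 || jb >= length(srcLat)) {
        if (dstLat[b] == srcLat[length(srcLat)]) { jbb <- length(srcLat) - 1L }
        else next
      } else jbb <- jb
      wx <- (dstLon[a] - srcLon[iaa]) / (srcLon[iaa + 1] - srcLon[iaa])
      wy <- (dstLat[b] - srcLat[jbb]) / (srcLat[jbb + 1] - srcLat[jbb])
      q <- m[iaa:(iaa + 1), jbb:(jbb + 1)]
      out[a, b] <- (1 - wx) * (1 - wy) * q[1, 1] + wx * (1 - wy) * q[2, 1] +
        (1 - wx) * wy * q[1, 2] + wx * wy * q[2, 2]
    }
  }
  out
}

#' Add derived covariate layers to a stack
#'
#' Computes seabed slope (SLP) from bathymetry, daily SST and salinity
#' gradients (SSTg, SALg), eddy kinetic energy (EKE, stored
#' log(x+1)-transformed), and distance to the sea-ice edge (EDGE, km).
#' Layers already present are not recomputed; the transform record prevents
#' double log-transformation.
#'
#' @param stack An [EnvStack-class] with BAT, SST, SAL, SIC, U, V.
#' @param gradients Also derive SSTg/SALg (default TRUE).
#' @return The augmented [EnvStack-class].
#' @export
deriveCovariates <- function(stack, gradients = TRUE) {
  lon <- envLon(stack); lat <- envLat(stack)
  nd <- length(envDates(stack))
  if (!"SLP" %in% names(stack@static) && "BAT" %in% names(stack@static)) {
    slp <- computeSlope(stack@static$BAT, lon, lat)
    slp[landMask(stack)] <- NA_real_
    stack@static$SLP <- slp
  }
  dimd <- c(length(lon), length(lat), nd)
  addDyn <- function(stack, nm, fun) {
    if (nm %in% names(stack@dynamic)) return(stack)
    arr <- array(NA_real_, dimd)
    for (k in seq_len(nd)) arr[, , k] <- fun(k)
    stack@dynamic[[nm]] <- arr
    stack
  }
  if (all(c("U", "V") %in% names(stack@dynamic))) {
    stack <- addDyn(stack, "EKE", function(k)
      log1p(computeEKE(stack@dynamic$U[, , k], stack@dynamic$V[, , k])))
    if (!"EKE" %in% stack@transformed)
      stack@transformed <- c(stack@transformed, "EKE")
  }
  if ("SIC" %in% names(stack@dynamic)) {
    land <- landMask(stack)
    stack <- addDyn(stack, "EDGE", function(k)
      distanceToIceEdge(stack@dynamic$SIC[, , k], land, lon, lat))
  }
  if (gradients) {
    for (pair in list(c("SST", "SSTg"), c("SAL", "SALg"))) {
      if (pair[1] %in% names(stack@dynamic))
        stack <- addDyn(stack, pair[2], function(k)
          computeGradient(stack@dynamic[[pair[1]]][, , k], lon, lat))
    }
  }
  validObject(stack)
  stack
}

#' Match covariates to presence/absence records
#'
#' Each record receives, per covariate, the mean over grid cells whose
#' centres lie within `radiusKm` great-circle km of the record's cell centre
#' (ties at exactly the radius included), from the record's UTC date for
#' dynamic layers. Averaging skips missing cells; records whose
#' neighbourhood is entirely missing get `NA` (tolerated for sparse layers
#' such as CHL).
#'
#' @param records Sampled skeleton from [sampleBalanced()] (needs `date`,
#'   `ix`, `iy`).
#' @param stack The [EnvStack-class].
#' @param covariates Layer names to match (default: all).
#' @param radiusKm Matching radius (default 15).
#' @return The records with one numeric column per covariate.
#' @export
matchCovariates <- function(records, stack, covariates = envLayerNames(stack),
                            radiusKm = 15) {
  records <- data.table::as.data.table(records)
  if (any(!records$date %in% envDates(stack)))
    stop("record dates outside the stack's date range: ",
         paste(unique(records$date[!records$date %in% envDates(stack)]),
               collapse = ", "))
  lon <- envLon(stack); lat <- envLat(stack)
  nlon <- length(lon); nlat <- length(lat)
  cs <- envCellSize(stack)
  # neighbourhood offsets per latitude row
  maxDj <- ceiling(radiusKm / (110.574 * cs))
  offsetsByRow <- lapply(seq_len(nlat), function(j) {
    maxDi <- ceiling(radiusKm / (111.320 * cos(lat[j] * pi / 180) * cs))
    cand <- expand.grid(di = -maxDi:maxDi, dj = -maxDj:maxDj)
    d <- haversineKm(lon[1] + cand$di * cs, lat[j], lon[1],
                     lat[j] + cand$dj * cs)
    # centre-to-centre distance depends only on offsets at this latitude
    cand[d <= radiusKm + 1e-9, , drop = FALSE]
  })
  dateIdx <- match(records$date, envDates(stack))
  vals <- matrix(NA_real_, nrow(records), length(covariates),
                 dimnames = list(NULL, covariates))
  layers <- lapply(setNames(nm = covariates), function(nm) {
    if (nm %in% names(stack@static)) stack@static[[nm]] else stack@dynamic[[nm]]
  })
  isStatic <- vapply(covariates, function(nm) nm %in% names(stack@static),
                     logical(1))
  for (r in seq_len(nrow(records))) {
    i <- records$ix[r]; j <- records$iy[r]
    off <- offsetsByRow[[j]]
    ii <- i + off$di; jj <- j + off$dj
    ok <- ii >= 1 & ii <= nlon & jj >= 1 & jj <= nlat
    idx <- cbind(ii[ok], jj[ok])
    for (c0 in seq_along(covariates)) {
      m <- layers[[c0]]
      v <- if (isStatic[c0]) m[idx] else m[cbind(idx, dateIdx[r])]
      vals[r, c0] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  cbind(records, data.table::as.data.table(vals))
}

#' Append the random-number importance control
#'
#' Adds a covariate of uniform integers on `[1, 100]`; covariates whose
#' relative influence falls at or below this control are flagged as
#' uninformative downstream.
#'
#' @param table Matched covariate table.
#' @param seed Integer seed.
#' @param name Column name (default `"RAND"`).
#' @return The table with the control column appended.
#' @export
addRandomControl <- function(table, seed = 1L, name = "RAND") {
  .withSeed(seed, {
    table[[name]] <- sample.int(100L, nrow(table), replace = TRUE)
    table
  })
}

#' Spearman collinearity screen
#'
#' Computes all pairwise Spearman correlations (average ranks for ties,
#' pairwise-complete observations) among covariate columns, then greedily
#' drops one member of each pair with `|rho| >= threshold` -- keeping the
#' covariate earlier in the canonical order -- until no pair exceeds the
#' threshold. Constant covariates have undefined correlations; they are
#' reported but never dropped automatically.
#'
#' @param table Matched table.
#' @param covariates Columns to screen.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param order Priority order for keeps (default: the canonical covariate
#'   order, unknown names last).
#' @return List with `cor` (the Spearman matrix), `dropped` (data.frame of
#'   drops with the triggering partner and rho), `kept`, and `undefined`
#'   (constant covariates).
#' @export
collinearityScreen <- function(table, covariates, threshold = 0.7,
                               order = .COVARIATE_ORDER) {
  stopifnot(length(covariates) >= 2)
  X <- as.data.frame(table)[, covariates, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 records")
  cm <- suppressWarnings(cor(X, method = "spearman",
                             use = "pairwise.complete.obs"))
  rank0 <- match(covariates, order)
  rank0[is.na(rank0)] <- length(order) + seq_len(sum(is.na(rank0)))
  undefined <- covariates[vapply(X, function(v) var(v, na.rm = TRUE) == 0 ||
                                   all(is.na(v)), logical(1))]
  kept <- covariates
  dropped <- data.frame(dropped = character(), partner = character(),
                        rho = numeric())
  repeat {
    sub <- cm[kept, kept, drop = FALSE]
    diag(sub) <- NA
    sub[is.na(sub)] <- NA
    mx <- suppressWarnings(max(abs(sub), na.rm = TRUE))
    if (!is.finite(mx) || mx < threshold) break
    idx <- which(abs(sub) == mx, arr.ind = TRUE)[1, ]
    a <- kept[idx[1]]; b <- kept[idx[2]]
    loser <- if (rank0[match(a, covariates)] <= rank0[match(b, covariates)]) b
             else a
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped, data.frame(dropped = loser, partner = winner,
                                         rho = sub[idx[1], idx[2]]))
    kept <- setdiff(kept, loser)
  }
  list(cor = cm, dropped = dropped, kept = kept, undefined = undefined)
}
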