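# Central S4 containers: the gridded environmental stack, fitted boosted-tree
# ensembles, bootstrap prediction maps and the monotone accessibility curve.

#' Gridded environmental covariate stack
#'
#' Container for daily environmental fields and static layers on a common
#' regular lon/lat grid (WGS84, cell centres). Matrices are indexed
#' `[lon, lat]`; dynamic layers are arrays `[lon, lat, day]`. Bathymetry
#' follows the GEBCO sign convention: negative below sea level at sea cells.
#'
#' @slot lon,lat Cell-centre coordinates (degrees), strictly increasing.
#' @slot dates Consecutive UTC dates of the dynamic layers.
#' @slot static Named list of `[lon, lat]` matrices (e.g. `BAT`, `SLP`).
#' @slot dynamic Named list of `[lon, lat, day]` arrays (e.g. `SST`, `SIC`).
#' @slot land Logical `[lon, lat]` matrix, `TRUE` on land.
#' @slot transformed Names of layers stored log(x+1)-transformed (recorded so
#'   the transform is applied exactly once).
#' @export
setClass("EnvStack", representation(
  lon = "numeric", lat = "numeric", dates = "Date",
  static = "list", dynamic = "list", land = "matrix",
  transformed = "character"
))

setValidity("EnvStack", function(object) {
  nl <- length(object@lon); nt <- length(object@lat)
  if (nl < 2 || nt < 2) return("grid must have at least 2x2 cells")
  if (is.unsorted(object@lon, strictly = TRUE) ||
      is.unsorted(object@lat, strictly = TRUE))
    return("lon/lat centres must be strictly increasing")
  if (!all(dim(object@land) == c(nl, nt)))
    return("land mask dimensions do not match the grid")
  for (nm in names(object@static))
    if (!all(dim(object@static[[nm]]) == c(nl, nt)))
      return(sprintf("static layer '%s' has wrong dimensions", nm))
  nd <- length(object@dates)
  for (nm in names(object@dynamic)) {
    d <- dim(object@dynamic[[nm]])
    if (length(d) != 3 || !all(d == c(nl, nt, nd)))
      return(sprintf("dynamic layer '%s' has wrong dimensions", nm))
  }
  if ("SIC" %in% names(object@dynamic)) {
    sic <- object@dynamic[["SIC"]]
    if (any(sic < -1e-9 | sic > 1 + 1e-9, na.rm = TRUE))
      return("SIC must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "EnvStack", function(object) {
  cat(sprintf(
    "EnvStack: %d x %d cells (%.2f deg), %d days (%s .. %s)\n",
    length(object@lon), length(object@lat),
    if (length(object@lon) > 1) diff(object@lon[1:2]) else NA_real_,
    length(object@dates), format(min(object@dates)), format(max(object@dates))
  ))
  cat("  static : ", paste(names(object@static), collapse = ", "), "\n")
  cat("  dynamic: ", paste(names(object@dynamic), collapse = ", "), "\n")
  cat(sprintf("  land   : %d of %d cells\n", sum(object@land),
              length(object@land)))
})

#' @describeIn EnvStack Cell-centre longitudes.
#' @param x An `EnvStack`.
#' @export
envLon <- function(x) x@lon

#' @describeIn EnvStack Cell-centre latitudes.
#' @export
envLat <- function(x) x@lat

#' @describeIn EnvStack Dates of the dynamic layers.
#' @export
envDates <- function(x) x@dates

#' @describeIn EnvStack Grid cell size in degrees.
#' @export
envCellSize <- function(x) diff(x@lon[1:2])

#' @describeIn EnvStack Logical land mask (`TRUE` on land).
#' @export
landMask <- function(x) x@land

#' @describeIn EnvStack Names of all available layers.
#' @export
envLayerNames <- function(x) c(names(x@static), names(x@dynamic))

#' Extract a layer from an environmental stack
#'
#' @param x An [EnvStack-class].
#' @param name Layer name.
#' @param date A `Date` (required for dynamic layers, ignored for static).
#' @return A `[lon, lat]` matrix.
#' @export
envLayer <- function(x, name, date = NULL) {
  if (name %in% names(x@static)) return(x@static[[name]])
  if (!name %in% names(x@dynamic))
    stop(sprintf("layer '%s' not found", name))
  if (is.null(date)) stop(sprintf("layer '%s' is dynamic; supply a date", name))
  k <- match(as.Date(date), x@dates)
  if (is.na(k)) stop(sprintf("date %s outside the stack", format(date)))
  x@dynamic[[name]][, , k]
}

#' Map coordinates to grid-cell indices
#'
#' Half-open convention: a point exactly on a cell boundary belongs to the
#' cell whose lower edge it touches.
#'
#' @param x An [EnvStack-class] (or any object with `lon`/`lat` centres).
#' @param lon,lat Coordinates in degrees.
#' @return List with integer vectors `ix`, `iy` (`NA` outside the grid).
#' @export
cellIndex <- function(x, lon, lat) {
  cs <- envCellSize(x)
  # small tolerance keeps exact boundary points in the upper (half-open) cell
  ix <- floor((lon - (x@lon[1] - cs / 2)) / cs + 1e-9) + 1L
  iy <- floor((lat - (x@lat[1] - cs / 2)) / cs + 1e-9) + 1L
  ix[ix < 1L | ix > length(x@lon)] <- NA_integer_
  iy[iy < 1L | iy > length(x@lat)] <- NA_integer_
  list(ix = as.integer(ix), iy = as.integer(iy))
}

#' Is a position on a sea cell of the stack?
#'
#' Positions outside the grid count as not-at-sea.
#'
#' @inheritParams cellIndex
#' @return Logical vector.
#' @export
atSea <- function(x, lon, lat) {
  ci <- cellIndex(x, lon, lat)
  ok <- !is.na(ci$ix) & !is.na(ci$iy)
  out <- logical(length(lon))
  out[ok] <- !x@land[cbind(ci$ix[ok], ci$iy[ok])]
  out
}

#' Boosted regression tree fit
#'
#' Additive ensemble of depth-limited regression trees on the logit scale,
#' fitted by stagewise gradient boosting of the Bernoulli deviance.
#'
#' @slot trees List of node matrices (one per boosting iteration).
#' @slot init Intercept (logit of the training prevalence).
#' @slot varNames Covariate names, in training column order.
#' @slot importanceMatrix Per-variable, per-tree split-gain matrix.
#' @slot config List with `nTrees`, `treeComplexity`, `learningRate`,
#'   `bagFraction`, `minNode`, `seed`.
#' @slot trainX Training covariate matrix (kept for partial dependence;
#'   may be a 0-row matrix for bootstrap members).
#' @slot trainSignature Numeric signature of the training data (rows, columns
#'   and a checksum) for provenance checks.
#' @export
setClass("BRTFit", representation(
  trees = "list", init = "numeric", varNames = "character",
  importanceMatrix = "matrix", config = "list", trainX = "matrix",
  trainSignature = "numeric"
))

setValidity("BRTFit", function(object) {
  if (nrow(object@importanceMatrix) != length(object@varNames))
    return("importance matrix rows must match varNames")
  if (ncol(object@importanceMatrix) != length(object@trees))
    return("importance matrix columns must match the number of trees")
  TRUE
})

setMethod("show", "BRTFit", function(object) {
  cat(sprintf(
    "BRTFit: %d trees, complexity %d, learning rate %g, bag fraction %g\n",
    length(object@trees), object@config$treeComplexity,
    object@config$learningRate, object@config$bagFraction
  ))
  ri <- sort(relativeInfluence(object), decreasing = TRUE)
  cat("  top influences: ",
      paste(sprintf("%s %.1f%%", names(ri)[seq_len(min(5, length(ri)))],
                    ri[seq_len(min(5, length(ri)))]), collapse = ", "), "\n")
})

#' Bootstrap ensemble prediction maps
#'
#' Per-cell, per-day median habitat suitability and 95% confidence-interval
#' range over a family of bootstrap model fits.
#'
#' @slot lon,lat Grid centres.
#' @slot dates Predicted dates.
#' @slot median Array `[lon, lat, day]` of per-cell medians.
#' @slot ciRange Array `[lon, lat, day]` of 95% CI ranges.
#' @slot nFits Number of bootstrap fits summarised.
#' @export
setClass("EnsemblePrediction", representation(
  lon = "numeric", lat = "numeric", dates = "Date",
  median = "array", ciRange = "array", nFits = "integer"
))

setValidity("EnsemblePrediction", function(object) {
  d <- c(length(object@lon), length(object@lat), length(object@dates))
  if (!all(dim(object@median) == d)) return("median array has wrong dims")
  if (!all(dim(object@ciRange) == d)) return("ciRange array has wrong dims")
  if (any(object@median < -1e-9 | object@median > 1 + 1e-9, na.rm = TRUE))
    return("median suitability must lie in [0, 1]")
  if (any(object@ciRange < -1e-9, na.rm = TRUE))
    return("CI range must be non-negative")
  TRUE
})

setMethod("show", "EnsemblePrediction", function(object) {
  cat(sprintf(
    "EnsemblePrediction: %d x %d cells, %d days, %d bootstrap fits\n",
    length(object@lon), length(object@lat), length(object@dates),
    object@nFits
  ))
})

#' Monotone non-increasing accessibility curve
#'
#' Family of bootstrap binomial fits of access probability against distance
#' beyond the sea-ice edge, each constrained to be non-increasing (logistic
#' regression on an I-spline basis with sign-constrained coefficients).
#'
#' @slot knots Interior knots of the I-spline basis (km).
#' @slot boundary Basis support (km).
#' @slot degree Spline degree.
#' @slot alpha Intercepts, one per bootstrap member.
#' @slot beta Non-negative basis coefficients (basis x member); the linear
#'   predictor is `alpha - beta' I(d)`.
#' @slot lambda Ridge penalty used for all members.
#' @export
setClass("AccessibilityCurve", representation(
  knots = "numeric", boundary = "numeric", degree = "integer",
  alpha = "numeric", beta = "matrix", lambda = "numeric"
))

setValidity("AccessibilityCurve", function(object) {
  if (length(object@alpha) != ncol(object@beta))
    return("one intercept per bootstrap member required")
  if (any(object@beta < -1e-9)) return("basis coefficients must be >= 0")
  TRUE
})

setMethod("show", "AccessibilityCurve", function(object) {
  cat(sprintf(
    "AccessibilityCurve: %d bootstrap members, support [%.0f, %.0f] km\n",
    length(object@alpha), object@boundary[1], object@boundary[2]
  ))
})
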