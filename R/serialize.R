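# Plain-JSON serialization of fitted objects: boosted-tree ensembles are
# stored as nested split records, accessibility curves as knots plus
# coefficients, so fits can be archived and reloaded without binary files.

#' Write / read a BRT fit as JSON
#'
#' @param fit A [BRTFit-class].
#' @param path Output file.
#' @return `readBRT` returns the reconstructed [BRTFit-class] (without the
#'   training matrix; partial dependence needs the original data).
#' @export
writeBRT <- function(fit, path) {
  stopifnot(is(fit, "BRTFit"))
  obj <- list(
    init = fit@init,
    varNames = fit@varNames,
    config = fit@config,
    trainSignature = fit@trainSignature,
    importance = unname(apply(fit@importanceMatrix, 2, as.numeric,
                              simplify = FALSE)),
    trees = lapply(fit@trees, function(tm) unname(apply(tm, 1, as.numeric,
                                                        simplify = FALSE)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBRT
#' @export
readBRT <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(obj$trees, function(rows)
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r)))))
  imp <- do.call(cbind, lapply(obj$importance,
                               function(cl) as.numeric(unlist(cl))))
  rownames(imp) <- unlist(obj$varNames)
  new("BRTFit", trees = trees, init = as.numeric(obj$init),
      varNames = as.character(unlist(obj$varNames)),
      importanceMatrix = imp, config = lapply(obj$config, unlist),
      trainX = matrix(0, 0, length(obj$varNames)),
      trainSignature = as.numeric(unlist(obj$trainSignature)))
}

#' Write / read an accessibility curve family as JSON
#'
#' @param curve An [AccessibilityCurve-class].
#' @param path Output file.
#' @return `readAccessibilityCurve` returns the reconstructed object.
#' @export
writeAccessibilityCurve <- function(curve, path) {
  stopifnot(is(curve, "AccessibilityCurve"))
  jsonlite::write_json(list(
    knots = curve@knots, boundary = curve@boundary,
    degree = curve@degree, alpha = curve@alpha,
    beta = unname(apply(curve@beta, 2, as.numeric, simplify = FALSE)),
    lambda = curve@lambda
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAccessibilityCurve
#' @export
readAccessibilityCurve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  beta <- do.call(cbind, lapply(obj$beta,
                                function(cl) as.numeric(unlist(cl))))
  new("AccessibilityCurve", knots = as.numeric(unlist(obj$knots)),
      boundary = as.numeric(unlist(obj$boundary)),
      degree = as.integer(obj$degree),
      alpha = as.numeric(unlist(obj$alpha)), beta = beta,
      lambda = as.numeric(obj$lambda))
}
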