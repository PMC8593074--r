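# Descriptive statistics of foraging trips, daylength, dive depths and
# haul-out demography, plus the published 2019 tagging summary shipped as a
# plain-text table.

#' The 2019 tagging summary table
#'
#' Deployment summaries of the 15 satellite-tagged juvenile and sub-adult
#' male fur seals (standard length, tag type, deployment date, track
#' duration in days, number of trips, and mean/range of trip durations).
#' One dive tag transmitted for only ~48 h.
#'
#' @return data.frame, one row per tag.
#' @export
taggingTable <- function() {
  read.csv(system.file("extdata", "tagging_table_2019.csv",
                       package = "iceSDM"),
           colClasses = c(id = "character"))
}

#' @describeIn taggingTable Total number of trips pooled over tags.
#' @param table A tagging table (default: the shipped one).
#' @export
pooledTripCount <- function(table = taggingTable()) sum(table$trips)

#' @describeIn taggingTable Longest track duration in days.
#' @export
maxTrackDuration <- function(table = taggingTable()) max(table$track_days)

#' @describeIn taggingTable Number of tags retained for analysis: tags
#'   transmitting longer than `minDays` (the excluded tag transmitted ~2
#'   days).
#' @param minDays Retention threshold in days.
#' @export
retainedTagCount <- function(table = taggingTable(), minDays = 3) {
  sum(table$track_days >= minDays)
}

#' Trip duration summaries
#'
#' @param trips Trip table (from [segmentTrips()] or the generator's trip
#'   log) with `id` and `durationDays`.
#' @return List with `perIndividual` (count, mean, min, max per id) and
#'   `pooled` (total trips, mean and range).
#' @export
tripDurations <- function(trips) {
  stopifnot(all(trips$durationDays > 0))
  per <- do.call(rbind, lapply(split(trips, trips$id), function(tr)
    data.frame(id = tr$id[1], trips = nrow(tr),
               meanDays = mean(tr$durationDays),
               minDays = min(tr$durationDays),
               maxDays = max(tr$durationDays))))
  rownames(per) <- NULL
  list(perIndividual = per,
       pooled = list(trips = nrow(trips),
                     meanDays = mean(trips$durationDays),
                     range = range(trips$durationDays)))
}

# local solar hour = UTC hour + lon / 15
.localSolarHour <- function(time, lon) {
  utcH <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60
  (utcH + lon / 15) %% 24
}

#' Departure and arrival time-of-day histograms
#'
#' Counts per local solar hour (longitude/15 offset from UTC) of trip
#' departures and arrivals; total mass equals the number of trips.
#'
#' @param trips Trip table with `departure`, `arrival` and a longitude for
#'   the haul-out (`midLon` used as the local-time reference).
#' @param binHours Bin width in hours (default 1).
#' @return List of two named count vectors, `departure` and `arrival`.
#' @export
departureArrivalHistogram <- function(trips, binHours = 1) {
  breaks <- seq(0, 24, by = binHours)
  mk <- function(h) {
    cut0 <- cut(h, breaks, right = FALSE, include.lowest = TRUE)
    table(cut0)
  }
  list(departure = mk(.localSolarHour(trips$departure, trips$midLon)),
       arrival = mk(.localSolarHour(trips$arrival, trips$midLon)))
}

#' Hours of daylight
#'
#' Sunrise-equation daylength with solar declination
#' `delta = -23.44 * cos(2 * pi * (doy + 10) / 365)` degrees; polar day and
#' night clamp to 24 and 0 h.
#'
#' @param lat Latitude in degrees (|lat| <= 90).
#' @param date A `Date` (vectorised with `lat`).
#' @return Daylength in hours, in `[0, 24]`.
#' @export
daylength <- function(lat, date) {
  stopifnot(all(abs(lat) <= 90))
  doy <- as.integer(format(as.Date(date), "%j"))
  delta <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  x <- -tan(lat * pi / 180) * tan(delta)
  x <- pmin(pmax(x, -1), 1)
  2 * acos(x) * 180 / pi / 15
}

#' Correlation between trip duration and daylength
#'
#' Pearson correlation of per-trip daylength (evaluated at the trip's
#' midpoint date and mean at-sea latitude) with trip duration.
#'
#' @param trips Trip table with `durationDays`, `midDate`, `midLat`.
#' @return List with `r`, `n`, `p`; `r` is `NA` with a message if either
#'   variable has zero variance.
#' @export
correlateDaylength <- function(trips) {
  if (nrow(trips) < 3) stop("need at least 3 trips")
  dl <- daylength(trips$midLat, trips$midDate)
  if (var(dl) == 0 || var(trips$durationDays) == 0) {
    message("zero variance; correlation undefined")
    return(list(r = NA_real_, n = nrow(trips), p = NA_real_))
  }
  ct <- cor.test(dl, trips$durationDays)
  list(r = unname(ct$estimate), n = nrow(trips), p = ct$p.value)
}

#' Daily maximum dive depth summaries
#'
#' Per seal and day the maximum recorded depth; per month the mean and SD
#' of those daily maxima across seal-days; and the single deepest dive.
#' Invariant to record order and duplicated records.
#'
#' @param dives Dive records with `id`, `date`, `depth_m`.
#' @return List with `daily` (id, date, maxDepth), `monthly` (month, mean,
#'   sd, n), `deepest`.
#' @export
dailyMaxDepth <- function(dives) {
  if (any(dives$depth_m < 0)) stop("negative depth record")
  dv <- data.table::as.data.table(unique(dives))
  daily <- dv[, .(maxDepth = max(depth_m)), by = .(id, date)]
  daily[, month := .monthKey(as.Date(date))]
  monthly <- daily[, .(meanMaxDepth = mean(maxDepth), sdMaxDepth = sd(maxDepth),
                       n = .N), by = month]
  data.table::setkey(daily, id, date)
  list(daily = as.data.frame(daily[, .(id, date, maxDepth)]),
       monthly = as.data.frame(monthly[order(month)]),
       deepest = max(daily$maxDepth))
}

#' Haul-out demography summary
#'
#' Per haul-out totals (censuses pooled), the pooled grand total, and
#' per-class percentage composition reported as mean and SD across the
#' individual censuses.
#'
#' @param counts Transect count table from [generateTransectCounts()] (or
#'   any table with `haulout`, `census` and per-class count columns).
#' @param classes Names of the count columns.
#' @return List with `haulOutTotals`, `pooledTotal`, `composition`
#'   (class, meanPct, sdPct); percentages are `NA` with a message for an
#'   all-zero table.
#' @export
demographySummary <- function(counts,
                              classes = c("juveniles", "subadults",
                                          "adults")) {
  stopifnot(all(unlist(counts[classes]) >= 0))
  byHaul <- vapply(split(counts, counts$haulout),
                   function(d) sum(unlist(d[classes])), numeric(1))
  pooled <- sum(byHaul)
  census <- split(counts, interaction(counts$haulout, counts$census,
                                      drop = TRUE))
  pct <- t(vapply(census, function(d) {
    tot <- sum(unlist(d[classes]))
    if (tot == 0) rep(NA_real_, length(classes))
    else 100 * vapply(classes, function(cl) sum(d[[cl]]), numeric(1)) / tot
  }, numeric(length(classes))))
  colnames(pct) <- classes
  if (all(is.na(pct))) message("all-zero table; proportions undefined")
  comp <- data.frame(class = classes,
                     meanPct = colMeans(pct, na.rm = TRUE),
                     sdPct = apply(pct, 2, sd, na.rm = TRUE))
  rownames(comp) <- NULL
  list(haulOutTotals = byHaul, pooledTotal = pooled, composition = comp)
}
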