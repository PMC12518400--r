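# Trajectory segmentation: great-circle distances, flight bouts, and
# autumn-migration departure day / departure moment.

# Mean Earth radius (km); distances are great-circle on this sphere.
.r_earth_km <- 6371.0088
# Kilometres per degree of latitude on that sphere.
.km_per_deg_lat <- pi / 180 * .r_earth_km

#' Great-circle distance in kilometres
#'
#' Haversine distance on the mean-radius sphere (R = 6371.0088 km). At the
#' metre scale relevant for contact detection the spherical error is far
#' below positional error, so no projection is used.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS-84).
#'   Vectors are recycled in the usual way.
#' @return Distance(s) in kilometres.
#' @examples
#' geodesic_km(53, 6, 54, 6) # one degree of latitude ~ 111.2 km
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .r_earth_km * 1000) / 1000
}

.check_coords <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || anyNA(lat) || anyNA(lon)) {
    stop("coordinates must be numeric and non-missing", call. = FALSE)
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a GPS track table
#'
#' A track is a data frame with one row per GPS fix: `bird_id`, `timestamp`
#' (POSIXct, UTC), `lat`, `lon` (degrees) and `gps_speed_kmh` (the logger's
#' instantaneous speed; may be NA). Timestamps must be strictly increasing.
#'
#' @param track A data frame as above.
#' @return The track, invisibly, if valid; otherwise an error.
#' @export
validate_track <- function(track) {
  stopifnot(is.data.frame(track))
  need <- c("bird_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(track))
  if (length(miss) > 0) {
    stop("track lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(track) > 0) {
    if (!inherits(track$timestamp, "POSIXct")) {
      stop("track$timestamp must be POSIXct", call. = FALSE)
    }
    .check_coords(track$lat, track$lon)
    if (nrow(track) > 1 && any(diff(as.numeric(track$timestamp)) <= 0)) {
      stop("track timestamps must be strictly increasing", call. = FALSE)
    }
  }
  invisible(track)
}

# Per-interval average ground speed (km/h) from consecutive positions and
# time gaps; the logger's instantaneous speed field is deliberately not used
# here (robust to speed-field dropout), it is kept for classification only.
.interval_speeds <- function(track) {
  n <- nrow(track)
  if (n < 2) {
    return(data.frame(dist_km = numeric(0), dt_h = numeric(0),
                      speed_kmh = numeric(0)))
  }
  d <- geodesic_km(track$lat[-n], track$lon[-n], track$lat[-1], track$lon[-1])
  dt <- diff(as.numeric(track$timestamp)) / 3600
  data.frame(dist_km = d, dt_h = dt, speed_kmh = d / dt)
}

#' Detect flight bouts
#'
#' A flight bout is a maximal run of consecutive GPS intervals during which
#' the average speed (displacement over elapsed time) is at least 5 km/h.
#' Intervals longer than `max_gap_min` break bouts, so sparse post-departure
#' data do not get stitched into spurious bouts.
#'
#' @param track A track (see [validate_track()]) with >= 2 fixes.
#' @param min_speed_kmh Minimum average interval speed, inclusive (default 5).
#' @param max_gap_min Maximum interval duration allowed inside a bout, in
#'   minutes (default 30).
#' @return A tibble with one row per bout: `start_fix`, `end_fix` (row
#'   indices into the track), `start_time`, `end_time`, `net_displacement_km`
#'   (great-circle distance between the bout's first and last fix) and
#'   `mean_speed_kmh` (path length over elapsed time). Zero rows if no bout.
#' @export
detect_flight_bouts <- function(track, min_speed_kmh = 5, max_gap_min = 30) {
  validate_track(track)
  if (nrow(track) < 2) stop("need at least 2 fixes", call. = FALSE)
  iv <- .interval_speeds(track)
  ok <- iv$speed_kmh >= min_speed_kmh & iv$dt_h <= max_gap_min / 60
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(tibble::tibble(
      start_fix = integer(0), end_fix = integer(0),
      start_time = track$timestamp[0], end_time = track$timestamp[0],
      net_displacement_km = numeric(0), mean_speed_kmh = numeric(0)
    ))
  }
  s <- as.integer(starts[keep])  # first interval index of each bout
  e <- as.integer(ends[keep])    # last interval index; fixes span s .. e+1
  net <- geodesic_km(track$lat[s], track$lon[s],
                     track$lat[e + 1], track$lon[e + 1])
  path <- vapply(seq_along(s), function(i) sum(iv$dist_km[s[i]:e[i]]),
                 numeric(1))
  elap <- vapply(seq_along(s), function(i) sum(iv$dt_h[s[i]:e[i]]),
                 numeric(1))
  tibble::tibble(
    start_fix = s, end_fix = e + 1L,
    start_time = track$timestamp[s], end_time = track$timestamp[e + 1L],
    net_displacement_km = net, mean_speed_kmh = path / elap
  )
}

# UTC calendar day of each fix, with an optional fixed offset (hours) for
# studies whose biological day is shifted from UTC.
.fix_day <- function(timestamp, tz_offset_h = 0) {
  as.Date(timestamp + tz_offset_h * 3600, tz = "UTC")
}

#' Detect the day of departure on autumn migration
#'
#' The departure day is the first calendar day (UTC, optionally offset) on
#' which the bird (i) travelled more than 100 km between the first and last
#' GPS fix of that day, in southward direction (the last fix lies at lower
#' latitude than the first), and (ii) ended up more than 50 km south of the
#' colony (north--south separation, with the last fix south of the colony).
#'
#' @param track A track (see [validate_track()]).
#' @param colony Numeric `c(lat, lon)` of the colony.
#' @param min_travel_km Displacement threshold, strict (default 100).
#' @param min_south_km End-of-day distance south of the colony, strict
#'   (default 50).
#' @param southward How to measure the day's displacement: `"geodesic"`
#'   (great-circle distance, required to point south by the latitude sign;
#'   the default) or `"latitudinal"` (pure north--south distance).
#' @param tz_offset_h Hours added to UTC before assigning calendar days.
#' @return The departure `Date`, or `NA` (class `Date`) if no day qualifies.
#' @export
detect_departure_day <- function(track, colony, min_travel_km = 100,
                                 min_south_km = 50,
                                 southward = c("geodesic", "latitudinal"),
                                 tz_offset_h = 0) {
  validate_track(track)
  southward <- match.arg(southward)
  stopifnot(is.numeric(colony), length(colony) == 2)
  if (nrow(track) == 0) return(as.Date(NA))
  day <- .fix_day(track$timestamp, tz_offset_h)
  first_i <- which(!duplicated(day))
  last_i <- which(!duplicated(day, fromLast = TRUE))
  lat1 <- track$lat[first_i]; lon1 <- track$lon[first_i]
  lat2 <- track$lat[last_i];  lon2 <- track$lon[last_i]
  disp <- if (southward == "geodesic") {
    geodesic_km(lat1, lon1, lat2, lon2)
  } else {
    (lat1 - lat2) * .km_per_deg_lat
  }
  south_of_colony <- (colony[1] - lat2) * .km_per_deg_lat
  ok <- disp > min_travel_km & lat2 < lat1 &
    south_of_colony > min_south_km & lat2 < colony[1]
  if (!any(ok)) return(as.Date(NA))
  day[first_i][which(ok)[1]]
}

#' Detect the moment of departure on autumn migration
#'
#' Among flight bouts with a net travel distance of at least
#' `min_net_km` (default 30 km) that start on the departure day or the
#' preceding calendar day, the earliest is the first migratory flight; the
#' departure moment is the timestamp of the GPS fix preceding that bout's
#' first fix (or the bout's first fix when the bout opens the track).
#' Including the preceding day captures birds that depart in the evening or
#' night before the day that satisfies the day-level rule.
#'
#' @param track A track (see [validate_track()]).
#' @param departure_day A `Date` from [detect_departure_day()].
#' @param min_net_km Net-displacement threshold, inclusive (default 30).
#' @param min_speed_kmh,max_gap_min Passed to [detect_flight_bouts()].
#' @param tz_offset_h Hours added to UTC before assigning calendar days.
#' @return A list of class `departure_event`: `bird_id`, `departure_day`,
#'   `departure_moment` (POSIXct) and `first_migratory_flight` (one-row bout
#'   tibble).
#' @export
detect_departure_moment <- function(track, departure_day, min_net_km = 30,
                                    min_speed_kmh = 5, max_gap_min = 30,
                                    tz_offset_h = 0) {
  validate_track(track)
  stopifnot(inherits(departure_day, "Date"), !is.na(departure_day))
  bouts <- detect_flight_bouts(track, min_speed_kmh, max_gap_min)
  if (nrow(bouts) > 0) {
    bday <- .fix_day(bouts$start_time, tz_offset_h)
    cand <- bouts[bouts$net_displacement_km >= min_net_km &
                    (bday == departure_day | bday == departure_day - 1), ,
                  drop = FALSE]
  } else {
    cand <- bouts
  }
  if (nrow(cand) == 0) {
    stop("no flight bout of >= ", min_net_km, " km net displacement starts ",
         "on the departure day or the preceding day: day-level and ",
         "moment-level departure rules are inconsistent for this track",
         call. = FALSE)
  }
  first <- cand[which.min(as.numeric(cand$start_time)), , drop = FALSE]
  moment_idx <- max(first$start_fix - 1L, 1L)
  structure(
    list(
      bird_id = track$bird_id[1],
      departure_day = departure_day,
      departure_moment = track$timestamp[moment_idx],
      first_migratory_flight = first
    ),
    class = "departure_event"
  )
}

#' @export
print.departure_event <- function(x, ...) {
  cat("<departure_event> bird", x$bird_id,
      "day", format(x$departure_day),
      "moment", format(x$departure_moment, tz = "UTC", usetz = TRUE),
      sprintf("(first flight: %.1f km net)",
              x$first_migratory_flight$net_displacement_km), "\n")
  invisible(x)
}

#' Detect departure for a whole track
#'
#' Convenience wrapper: [detect_departure_day()] then
#' [detect_departure_moment()].
#'
#' @inheritParams detect_departure_day
#' @inheritParams detect_departure_moment
#' @return A `departure_event`, or `NULL` when the bird never departed.
#' @export
detect_departure <- function(track, colony, min_travel_km = 100,
                             min_south_km = 50, min_net_km = 30,
                             min_speed_kmh = 5, max_gap_min = 30,
                             southward = c("geodesic", "latitudinal"),
                             tz_offset_h = 0) {
  day <- detect_departure_day(track, colony, min_travel_km, min_south_km,
                              match.arg(southward), tz_offset_h)
  if (is.na(day)) return(NULL)
  detect_departure_moment(track, day, min_net_km, min_speed_kmh, max_gap_min,
                          tz_offset_h)
}

#' Distance from a bird to its nest at a given time
#'
#' Great-circle distance from the fix nearest in time to the query timestamp
#' to the nest coordinate.
#'
#' @param track A non-empty track (see [validate_track()]).
#' @param at POSIXct timestamp(s).
#' @param nest Numeric `c(lat, lon)` of the nest.
#' @return Distance(s) in kilometres.
#' @export
distance_to_nest <- function(track, at, nest) {
  validate_track(track)
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  stopifnot(is.numeric(nest), length(nest) == 2)
  i <- .nearest_time_index(as.numeric(track$timestamp), as.numeric(at))
  geodesic_km(track$lat[i], track$lon[i], nest[1], nest[2])
}

# Index of the element of sorted vector `haystack` nearest to each value of
# `needle`; ties (exact midpoints) resolve to the earlier element.
.nearest_time_index <- function(haystack, needle) {
  j <- findInterval(needle, haystack, all.inside = FALSE)
  j0 <- pmax(j, 1L)
  j1 <- pmin(j + 1L, length(haystack))
  d0 <- abs(needle - haystack[j0])
  d1 <- abs(needle - haystack[j1])
  ifelse(j == 0, j1, ifelse(d1 < d0, j1, j0))
}
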