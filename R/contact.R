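# Dyadic linkage of chick and parent tracks, contact detection, day-level
# filtering and summaries, and post-departure proximity screening.

#' Link a chick track to its parent's track by nearest timestamp
#'
#' For every chick fix, finds the parent fix nearest in time (ties resolve
#' to the earlier fix; one parent fix may serve several chick fixes). A
#' linked pair is retained when the absolute time difference is below
#' `max_dt_min` (strictly), or — regardless of the time difference — when
#' the parent has already departed on migration while the chick has not: in
#' that case it is certain the two were not in contact, and the fix counts
#' as a no-contact observation.
#'
#' @param chick,parent Non-empty tracks (see [validate_track()]).
#' @param chick_departure,parent_departure Optional `departure_event`s (from
#'   [detect_departure()]); needed for the parent-departed retention rule.
#' @param nest Optional `c(lat, lon)`; when given, the chick's distance to
#'   the nest is attached to every linked fix.
#' @param max_dt_min Linkage window in minutes, strict (default 10).
#' @return A tibble of linked fixes: `chick_id`, `parent_id`, `pair_id`,
#'   `timestamp` (chick fix), `parent_timestamp`, `delta_t_min` (absolute),
#'   `distance_m`, `parent_departed`, `chick_lat/lon`, and `dist_nest_km`
#'   when `nest` is given. Contact is scored separately by
#'   [flag_contact()].
#' @export
link_tracks <- function(chick, parent, chick_departure = NULL,
                        parent_departure = NULL, nest = NULL,
                        max_dt_min = 10) {
  validate_track(chick); validate_track(parent)
  if (nrow(chick) == 0 || nrow(parent) == 0) {
    stop("both tracks must be non-empty", call. = FALSE)
  }
  ct <- as.numeric(chick$timestamp)
  pt <- as.numeric(parent$timestamp)
  j <- .nearest_time_index(pt, ct)
  dt_min <- abs(ct - pt[j]) / 60
  dist_m <- geodesic_km(chick$lat, chick$lon, parent$lat[j], parent$lon[j]) *
    1000
  parent_gone <- if (!is.null(parent_departure)) {
    ct > as.numeric(parent_departure$departure_moment)
  } else {
    rep(FALSE, length(ct))
  }
  chick_gone <- if (!is.null(chick_departure)) {
    ct > as.numeric(chick_departure$departure_moment)
  } else {
    rep(FALSE, length(ct))
  }
  keep <- dt_min < max_dt_min | (parent_gone & !chick_gone)
  out <- tibble::tibble(
    chick_id = chick$bird_id[1],
    parent_id = parent$bird_id[1],
    pair_id = paste(chick$bird_id[1], parent$bird_id[1], sep = "-"),
    timestamp = chick$timestamp,
    parent_timestamp = parent$timestamp[j],
    delta_t_min = dt_min,
    distance_m = dist_m,
    parent_departed = parent_gone & !chick_gone,
    chick_lat = chick$lat, chick_lon = chick$lon
  )
  if (!is.null(nest)) {
    out$dist_nest_km <- geodesic_km(chick$lat, chick$lon, nest[1], nest[2])
  }
  out[keep, , drop = FALSE]
}

#' Flag contact moments
#'
#' A linked fix is a contact moment when the chick--parent distance is
#' strictly less than the threshold: 10 m is the primary definition, 50 m
#' the sensitivity analysis; any positive threshold is accepted.
#'
#' @param linked Linked-fix tibble from [link_tracks()].
#' @param threshold_m Contact distance threshold in metres (default 10).
#' @return `linked` with an `in_contact` logical column (and the threshold
#'   recorded as attribute `contact_threshold_m`).
#' @export
flag_contact <- function(linked, threshold_m = 10) {
  stopifnot(is.data.frame(linked), "distance_m" %in% names(linked))
  if (!is.numeric(threshold_m) || length(threshold_m) != 1 ||
      threshold_m <= 0) {
    stop("threshold_m must be a single positive number", call. = FALSE)
  }
  linked$in_contact <- linked$distance_m < threshold_m
  attr(linked, "contact_threshold_m") <- threshold_m
  linked
}

# Pool raw behaviour labels for the behaviour-specific contact columns.
.pooled_label <- function(labels) {
  pool <- behaviour_pooling()
  ifelse(labels %in% names(pool), unname(pool[labels]), labels)
}

#' Daily contact summaries per chick--parent pair
#'
#' Aggregates contact-flagged linked fixes to one row per pair per day:
#' linked-fix counts, contact proportion, behaviour-specific contact
#' proportions (begging, foraging) over fixes with a complete acceleration
#' sample, and the chick's distance to the nest during contact. Day-level
#' completeness filters follow the study design: days with fewer than
#' `min_linked` linked fixes (of 144 possible at a 10-min cadence) carry no
#' overall-contact estimate, days with fewer than `min_linked_acc`
#' acceleration-complete linked fixes no behaviour-specific estimate; rows
#' failing both are dropped. Only chick ages inside `age_window` are kept
#' (the age window is applied first; both orderings are available via the
#' arguments).
#'
#' @param linked Contact-flagged linked fixes ([flag_contact()]), one or
#'   more pairs.
#' @param behaviours Optional tibble `bird_id`, `timestamp`, `behaviour`,
#'   `acc_complete` with the chick's (classified or true) behaviour per fix,
#'   matched on chick id and fix timestamp.
#' @param hatch_dates Named `Date` vector: hatch date per `chick_id`. Chick
#'   age on a day is the floored number of days since hatch at day start.
#' @param min_linked Minimum linked fixes for the overall estimate
#'   (default 130).
#' @param min_linked_acc Minimum acceleration-complete linked fixes for the
#'   behaviour-specific estimates (default 100).
#' @param age_window Chick-age window in days (default 35--136).
#' @param years Optional named vector (by chick_id) of study years; default
#'   the calendar year of each day.
#' @return A tibble with one row per pair-day: counts (`n_linked`,
#'   `n_contact`, `n_linked_with_acc`, `n_contact_beg`, `n_contact_forage`),
#'   proportions (`p_contact`, `p_contact_begging`, `p_contact_foraging`;
#'   `NA` where the relevant filter fails), nest-distance summaries during
#'   contact (`mean_dist_nest_km`, `median_dist_nest_km`), `chick_age`,
#'   `year`, and the filter flags `ok_overall`, `ok_behaviour`.
#' @export
summarise_daily <- function(linked, behaviours = NULL, hatch_dates,
                            min_linked = 130, min_linked_acc = 100,
                            age_window = c(35, 136), years = NULL) {
  stopifnot(is.data.frame(linked), "in_contact" %in% names(linked))
  if (nrow(linked) == 0) return(.empty_daily())
  stopifnot(!is.null(names(hatch_dates)), inherits(hatch_dates, "Date"))
  lk <- linked
  if (!is.null(behaviours)) {
    key <- paste(lk$chick_id, as.numeric(lk$timestamp))
    bkey <- paste(behaviours$bird_id, as.numeric(behaviours$timestamp))
    m <- match(key, bkey)
    lk$behaviour <- behaviours$behaviour[m]
    lk$acc_complete <- if ("acc_complete" %in% names(behaviours)) {
      behaviours$acc_complete[m] & !is.na(m)
    } else {
      !is.na(m)
    }
    lk$acc_complete[is.na(lk$acc_complete)] <- FALSE
  } else {
    lk$behaviour <- NA_character_
    lk$acc_complete <- FALSE
  }
  lk$date <- as.Date(lk$timestamp, tz = "UTC")
  hb <- hatch_dates[lk$chick_id]
  if (anyNA(hb)) stop("missing hatch date for some chick(s)", call. = FALSE)
  lk$chick_age <- as.integer(floor(as.numeric(lk$date - hb)))
  lk <- lk[lk$chick_age >= age_window[1] & lk$chick_age <= age_window[2], ,
           drop = FALSE]
  if (nrow(lk) == 0) return(.empty_daily())
  pooled <- .pooled_label(lk$behaviour)
  grp <- paste(lk$pair_id, lk$date)
  rows <- lapply(split(seq_len(nrow(lk)), grp), function(ii) {
    d <- lk[ii, , drop = FALSE]
    acc <- d$acc_complete & !is.na(d$behaviour)
    n_acc <- sum(acc)
    pd <- pooled[ii]
    n_beg <- sum(acc & pd == "beg" & d$in_contact, na.rm = TRUE)
    n_for <- sum(acc & pd == "forage" & d$in_contact, na.rm = TRUE)
    contact_nest <- if ("dist_nest_km" %in% names(d)) {
      d$dist_nest_km[d$in_contact]
    } else {
      numeric(0)
    }
    tibble::tibble(
      pair_id = d$pair_id[1], chick_id = d$chick_id[1],
      parent_id = d$parent_id[1], date = d$date[1],
      chick_age = d$chick_age[1],
      n_linked = nrow(d), n_contact = sum(d$in_contact),
      n_linked_with_acc = n_acc,
      n_contact_beg = n_beg, n_contact_forage = n_for,
      p_contact = sum(d$in_contact) / nrow(d),
      p_contact_begging = if (n_acc > 0) n_beg / n_acc else NA_real_,
      p_contact_foraging = if (n_acc > 0) n_for / n_acc else NA_real_,
      mean_dist_nest_km = if (length(contact_nest)) mean(contact_nest) else
        NA_real_,
      median_dist_nest_km = if (length(contact_nest))
        stats::median(contact_nest) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out$ok_overall <- out$n_linked >= min_linked
  out$ok_behaviour <- out$n_linked_with_acc >= min_linked_acc
  out$p_contact[!out$ok_overall] <- NA_real_
  out$p_contact_begging[!out$ok_behaviour] <- NA_real_
  out$p_contact_foraging[!out$ok_behaviour] <- NA_real_
  out <- out[out$ok_overall | out$ok_behaviour, , drop = FALSE]
  out$year <- if (is.null(years)) {
    as.integer(format(out$date, "%Y"))
  } else {
    as.integer(years[out$chick_id])
  }
  out <- out[order(out$pair_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_daily <- function() {
  tibble::tibble(
    pair_id = character(0), chick_id = character(0),
    parent_id = character(0), date = as.Date(character(0)),
    chick_age = integer(0), n_linked = integer(0), n_contact = integer(0),
    n_linked_with_acc = integer(0), n_contact_beg = integer(0),
    n_contact_forage = integer(0), p_contact = numeric(0),
    p_contact_begging = numeric(0), p_contact_foraging = numeric(0),
    mean_dist_nest_km = numeric(0), median_dist_nest_km = numeric(0),
    ok_overall = logical(0), ok_behaviour = logical(0), year = integer(0)
  )
}

#' Filter chick--parent pairs by data completeness
#'
#' Keeps only pairs with at least `min_days` qualifying days of nearly
#' complete joint data, and drops all rows on or after the chick's
#' departure day (post-departure chick data are far too sparse for daily
#' proportions).
#'
#' @param summaries Daily summaries from [summarise_daily()].
#' @param min_days Minimum qualifying days per pair (default 10).
#' @param chick_departures Optional named `Date` vector (by `chick_id`) of
#'   departure days.
#' @param qualifying Which day filter defines a qualifying day:
#'   `"overall"` (default) or `"behaviour"`.
#' @return The filtered summary tibble.
#' @export
pair_filter <- function(summaries, min_days = 10, chick_departures = NULL,
                        qualifying = c("overall", "behaviour")) {
  stopifnot(is.data.frame(summaries))
  qualifying <- match.arg(qualifying)
  out <- summaries
  if (!is.null(chick_departures)) {
    dep <- chick_departures[out$chick_id]
    out <- out[is.na(dep) | out$date < dep, , drop = FALSE]
  }
  flag <- if (qualifying == "overall") out$ok_overall else out$ok_behaviour
  n_days <- tapply(flag, out$pair_id, sum)
  keep_pairs <- names(n_days)[n_days >= min_days]
  out[out$pair_id %in% keep_pairs, , drop = FALSE]
}

#' Age at last contact
#'
#' Chick age at the latest contact moment of a linked, contact-flagged fix
#' set.
#'
#' @param linked Contact-flagged linked fixes ([flag_contact()]) for one
#'   chick (one or more parents).
#' @param hatch_date The chick's hatch `Date`.
#' @return Age in days at the last contact, or `NA_integer_` when the pair
#'   never had contact (a valid none-result, not an error).
#' @export
last_contact_age <- function(linked, hatch_date) {
  stopifnot(is.data.frame(linked), "in_contact" %in% names(linked),
            inherits(hatch_date, "Date"))
  hit <- linked$in_contact
  if (!any(hit)) return(NA_integer_)
  last <- max(as.numeric(linked$timestamp[hit]))
  as.integer(floor(as.numeric(
    as.Date(.POSIXct(last, tz = "UTC"), tz = "UTC") - hatch_date)))
}

#' Post-departure proximity screening
#'
#' After both birds have departed on migration only sparse fixes remain and
#' a 10 m criterion is meaningless, so possible meetings are screened
#' instead: every chick fix whose nearest-in-time parent fix lies within
#' `radius_km` becomes a candidate meeting for visual or tabular review.
#'
#' @param chick,parent Tracks (see [validate_track()]).
#' @param chick_departure,parent_departure `departure_event`s; only fixes
#'   after each bird's departure moment are screened.
#' @param radius_km Screening radius (default 25 km; pairs that never came
#'   within ~40 km of each other yield an empty table).
#' @return A time-ordered tibble of candidate meetings: `timestamp`,
#'   `parent_timestamp`, `delta_t_min`, `distance_km`.
#' @export
post_departure_proximity <- function(chick, parent, chick_departure,
                                     parent_departure, radius_km = 25) {
  validate_track(chick); validate_track(parent)
  stopifnot(radius_km >= 0)
  c2 <- chick[chick$timestamp > chick_departure$departure_moment, ,
              drop = FALSE]
  p2 <- parent[parent$timestamp > parent_departure$departure_moment, ,
               drop = FALSE]
  if (nrow(c2) == 0 || nrow(p2) == 0) {
    return(tibble::tibble(timestamp = c2$timestamp[0],
                          parent_timestamp = c2$timestamp[0],
                          delta_t_min = numeric(0), distance_km = numeric(0)))
  }
  j <- .nearest_time_index(as.numeric(p2$timestamp), as.numeric(c2$timestamp))
  d_km <- geodesic_km(c2$lat, c2$lon, p2$lat[j], p2$lon[j])
  keep <- d_km < radius_km
  out <- tibble::tibble(
    timestamp = c2$timestamp,
    parent_timestamp = p2$timestamp[j],
    delta_t_min = abs(as.numeric(c2$timestamp) - as.numeric(p2$timestamp[j]))
      / 60,
    distance_km = d_km
  )[keep, , drop = FALSE]
  out[order(out$timestamp), , drop = FALSE]
}
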