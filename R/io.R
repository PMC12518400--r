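# Readers/writers (CSV with ISO-8601 UTC timestamps, GeoJSON habitat, YAML
# config, JSON truth/manifest) and the pipeline driver.

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
.parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS",
                                      tz = "UTC")

#' Write / read GPS tracks as CSV
#'
#' Interchange dialect: columns `bird_id`, `timestamp` (ISO-8601 UTC, ms
#' precision), `lat`, `lon`, `gps_speed_kmh`. The reader tolerates extra
#' columns and returns them unchanged.
#'
#' @param tracks Track tibble (one or more birds).
#' @param path Output / input CSV path.
#' @return `write_tracks_csv()` the path invisibly; `read_tracks_csv()` a
#'   track tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- as.data.frame(tracks)
  out$timestamp <- .fmt_time(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- .parse_time(d$timestamp)
  tibble::as_tibble(d)
}

#' Write / read acceleration bursts as long CSV
#'
#' Long format: one row per reading with columns `bird_id`, `burst_start`,
#' `axis` (x/y/z), `index`, `value_g`, plus the per-burst columns
#' `gps_speed_kmh`, `behaviour` and `complete` repeated on every row.
#'
#' @param bursts Burst tibble (see [simulate_acc_bursts()]).
#' @param path CSV path.
#' @return The path invisibly / a burst tibble.
#' @export
write_bursts_csv <- function(bursts, path) {
  rows <- lapply(seq_len(nrow(bursts)), function(i) {
    n <- length(bursts$x[[i]])
    data.frame(
      bird_id = bursts$bird_id[i],
      burst_start = .fmt_time(bursts$burst_start[i]),
      axis = rep(c("x", "y", "z"), each = n),
      index = rep(seq_len(n), 3),
      value_g = c(bursts$x[[i]], bursts$y[[i]], bursts$z[[i]]),
      gps_speed_kmh = bursts$gps_speed_kmh[i],
      behaviour = if ("behaviour" %in% names(bursts)) bursts$behaviour[i]
        else NA_character_,
      complete = if ("complete" %in% names(bursts)) bursts$complete[i]
        else NA
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts_csv
#' @export
read_bursts_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(d$bird_id, d$burst_start)
  ord <- !duplicated(key)
  per <- d[ord, c("bird_id", "burst_start", "gps_speed_kmh", "behaviour",
                  "complete")]
  grab <- function(ax) {
    sub <- d[d$axis == ax, ]
    unname(split(sub$value_g[order(match(paste(sub$bird_id, sub$burst_start),
                                         key[ord]), sub$index)],
                 factor(paste(sub$bird_id, sub$burst_start),
                        levels = key[ord])))
  }
  tibble::tibble(
    bird_id = per$bird_id,
    burst_start = .parse_time(per$burst_start),
    behaviour = per$behaviour,
    gps_speed_kmh = per$gps_speed_kmh,
    complete = as.logical(per$complete),
    x = grab("x"), y = grab("y"), z = grab("z")
  )
}

#' Read / write a habitat map as GeoJSON
#'
#' The habitat map is a set of polygons of foraging water (freshwater,
#' brackish or marine); everything outside is land. Only `Polygon`
#' geometries (outer rings) are used.
#'
#' @param habitat List of rings (`data.frame(lon, lat)`).
#' @param path GeoJSON path.
#' @return The path invisibly / a habitat list.
#' @export
write_habitat_geojson <- function(habitat, path) {
  features <- lapply(habitat, function(ring) {
    coords <- cbind(ring$lon, ring$lat)
    if (!all(coords[1, ] == coords[nrow(coords), ])) {
      coords <- rbind(coords, coords[1, ])
    }
    list(type = "Feature",
         properties = list(habitat = "foraging_water"),
         geometry = list(type = "Polygon",
                         coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_habitat_geojson
#' @export
read_habitat_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  out <- list()
  for (f in g$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    out[[length(out) + 1]] <- data.frame(lon = m[, 1], lat = m[, 2])
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the simulation config with every analysis threshold: contact
#' distance (10 m primary / 50 m sensitivity), linkage window (10 min),
#' day-completeness filters (130 linked / 100 with acceleration), pair
#' filter (10 d), flight-speed (5 km/h), departure (100 km southward /
#' 50 km south of colony / 30 km net bout), post-departure screening
#' (25 km) and the chick-age window (35--136 d).
#'
#' @param sim A [sim_config()].
#' @param contact_threshold_m,linkage_max_dt_min,min_linked,min_linked_acc,
#'   min_pair_days,flight_min_speed_kmh,departure_min_travel_km,
#'   departure_min_south_km,departure_min_net_km,proximity_radius_km
#'   Analysis thresholds (see Description for defaults).
#' @param age_window Chick-age window in days.
#' @param southward Departure displacement measure (see
#'   [detect_departure_day()]).
#' @param tz_offset_h Calendar-day offset from UTC in hours.
#' @param n_train_bursts Labelled training bursts per class for the
#'   classifier stage.
#' @param use_true_behaviour If `TRUE`, skip classification and use the
#'   simulator's true labels (fast path for pipeline checks).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            contact_threshold_m = 10,
                            linkage_max_dt_min = 10,
                            min_linked = 130,
                            min_linked_acc = 100,
                            min_pair_days = 10,
                            flight_min_speed_kmh = 5,
                            departure_min_travel_km = 100,
                            departure_min_south_km = 50,
                            departure_min_net_km = 30,
                            proximity_radius_km = 25,
                            age_window = c(35, 136),
                            southward = "geodesic",
                            tz_offset_h = 0,
                            n_train_bursts = 120,
                            use_true_behaviour = FALSE) {
  thr <- c(contact_threshold_m, linkage_max_dt_min, min_linked,
           min_linked_acc, min_pair_days, flight_min_speed_kmh,
           departure_min_travel_km, departure_min_south_km,
           departure_min_net_km, proximity_radius_km)
  if (any(thr <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (age_window[1] >= age_window[2]) {
    stop("age_window must satisfy min < max", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$thr <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline config to YAML / read it back
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return The path invisibly / a `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # named vectors must go out as maps, not bare sequences
  x$sim$behaviour_freqs <- as.list(x$sim$behaviour_freqs)
  x$sim$year_effects <- as.list(x$sim$year_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  simargs <- x$sim
  simargs$behaviour_freqs <- unlist(simargs$behaviour_freqs)
  simargs$year_effects <- unlist(simargs$year_effects)
  sim <- do.call(sim_config, simargs)
  rest <- x[setdiff(names(x), "sim")]
  do.call(pipeline_config, c(list(sim = sim), rest))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> classify -> departure detection -> contact ->
#' models, writing every intermediate table as CSV, a model-selection
#' table, a JSON run manifest (config hash, seed, versions) and a
#' plain-text summary with per-stage record counts. A failing stage aborts
#' with a stage-named error; outputs written up to that point are kept.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `tracks`,
#'   `departures`, `linked`, `daily`, `filtered`, `selection`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  simres <- stage("simulate", simulate_family_tracks(config$sim))
  tracks <- simres$tracks
  truth <- simres$truth
  feeding <- stage("simulate", simulate_feeding_observations(config$sim))
  write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
  utils::write.csv(feeding$records, file.path(out_dir, "feeding.csv"),
                   row.names = FALSE)
  note("simulate: ", nrow(tracks), " fixes, ",
       nrow(truth$birds), " birds, ",
       nrow(feeding$records), " feeding records")

  # -- classify ------------------------------------------------------------
  chicks <- truth$birds[truth$birds$role == "chick", ]
  beh <- truth$behaviour
  if (config$use_true_behaviour) {
    chick_beh <- beh[beh$bird_id %in% chicks$bird_id, ]
    note("classify: skipped (true labels used), ", nrow(chick_beh),
         " labelled fixes")
  } else {
    train <- stage("classify",
                   simulate_training_bursts(config$n_train_bursts,
                                            config$sim))
    feats <- featurize_segments(segment_bursts(train, config$sim$burst_len,
                                               config$sim$acc_rate),
                                config$sim$acc_rate)
    model <- stage("classify", train_classifier(feats,
                                                seed = config$sim$seed))
    lab <- beh[beh$bird_id %in% chicks$bird_id & beh$acc_complete, ]
    chick_bursts <- stage("classify",
                          simulate_acc_bursts(lab, config$sim))
    segs <- segment_bursts(chick_bursts, config$sim$burst_len,
                           config$sim$acc_rate)
    sfeats <- featurize_segments(segs, config$sim$acc_rate)
    pred <- predict(model, sfeats)
    chick_beh <- tibble::tibble(bird_id = sfeats$bird_id,
                                timestamp = sfeats$burst_start,
                                behaviour = pred, acc_complete = TRUE)
    note("classify: ", nrow(chick_beh), " chick fixes classified (",
         config$n_train_bursts, " training bursts/class at ",
         config$sim$burst_len, " s)")
  }

  # -- departures ----------------------------------------------------------
  deps <- stage("departures", {
    out <- list()
    for (id in unique(tracks$bird_id)) {
      tr <- tracks[tracks$bird_id == id, ]
      out[[id]] <- detect_departure(
        tr, config$sim$colony_latlon,
        min_travel_km = config$departure_min_travel_km,
        min_south_km = config$departure_min_south_km,
        min_net_km = config$departure_min_net_km,
        min_speed_kmh = config$flight_min_speed_kmh,
        southward = config$southward, tz_offset_h = config$tz_offset_h)
    }
    out
  })
  dep_tab <- do.call(rbind, lapply(names(deps), function(id) {
    d <- deps[[id]]
    data.frame(bird_id = id,
               departure_day = if (is.null(d)) NA else
                 as.character(d$departure_day),
               departure_moment = if (is.null(d)) NA else
                 .fmt_time(d$departure_moment))
  }))
  utils::write.csv(dep_tab, file.path(out_dir, "departures.csv"),
                   row.names = FALSE)
  note("departures: ", sum(!is.na(dep_tab$departure_day)), " of ",
       nrow(dep_tab), " birds departed")

  # -- contact -------------------------------------------------------------
  hatch <- stats::setNames(truth$birds$hatch_date[
    truth$birds$role == "chick"], chicks$bird_id)
  years <- stats::setNames(truth$birds$year[truth$birds$role == "chick"],
                           chicks$bird_id)
  linked_all <- list(); daily_all <- list()
  parents <- truth$birds[truth$birds$role != "chick", ]
  for (i in seq_len(nrow(parents))) {
    pid <- parents$bird_id[i]
    cid <- parents$chick_id[i]
    lk <- stage("contact", link_tracks(
      tracks[tracks$bird_id == cid, ], tracks[tracks$bird_id == pid, ],
      chick_departure = deps[[cid]], parent_departure = deps[[pid]],
      nest = c(parents$nest_lat[i], parents$nest_lon[i]),
      max_dt_min = config$linkage_max_dt_min))
    lk <- flag_contact(lk, config$contact_threshold_m)
    linked_all[[i]] <- lk
    daily_all[[i]] <- summarise_daily(
      lk, chick_beh, hatch, min_linked = config$min_linked,
      min_linked_acc = config$min_linked_acc,
      age_window = config$age_window, years = years)
  }
  linked <- do.call(rbind, linked_all)
  daily <- do.call(rbind, daily_all)
  dep_days <- stats::setNames(
    as.Date(vapply(chicks$bird_id, function(id) {
      if (is.null(deps[[id]])) NA_character_ else
        as.character(deps[[id]]$departure_day)
    }, character(1))), chicks$bird_id)
  filtered <- pair_filter(daily, config$min_pair_days, dep_days)
  utils::write.csv(as.data.frame(daily[setdiff(names(daily),
                                               character(0))]),
                   file.path(out_dir, "daily_contact.csv"),
                   row.names = FALSE)
  note("contact: ", nrow(linked), " linked fixes -> ", nrow(daily),
       " pair-days -> ", nrow(filtered), " pair-days after pair filter (",
       length(unique(filtered$pair_id)), " pairs)")

  # -- models --------------------------------------------------------------
  sex_of <- stats::setNames(truth$birds$sex, truth$birds$bird_id)
  if (nrow(filtered) > 0) {
    filtered$chick_sex <- unname(sex_of[filtered$chick_id])
    filtered$parent_sex <- unname(sex_of[filtered$parent_id])
  }
  selection <- NULL
  if (nrow(filtered) > 0 && sum(filtered$n_contact, na.rm = TRUE) > 0 &&
      length(unique(filtered$chick_id)) >= 2) {
    fits <- stage("models",
                  fit_candidate_set(filtered, response = "p_contact"))
    selection <- selection_table(fits)
    utils::write.csv(selection, file.path(out_dir, "model_selection.csv"),
                     row.names = FALSE)
    best <- select_model(fits)
    note("models: most parsimonious p_contact model: ", best$label,
         sprintf(" (AICc %.2f, k %d)", best$AICc, best$k))
  } else {
    note("models: contact model selection skipped (needs retained contact ",
         "data from >= 2 chicks)")
  }
  feed_fit <- stage("models",
                    fit_feeding_age_model(feeding$records,
                                          seed = config$sim$seed))
  note("models: feeding count ~ age z = ", sprintf("%.2f", feed_fit$age_z))

  # -- manifest ------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config_yaml(config, cfg_path)
  manifest <- list(
    seed = config$sim$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("fledgelink")),
    created = "run manifest; timestamps in tables, not here, for replay"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "summary.txt"))
  invisible(list(tracks = tracks, truth = truth, departures = deps,
                 linked = linked, daily = daily, filtered = filtered,
                 selection = selection, manifest = manifest))
}
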