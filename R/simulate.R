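# Synthetic family-tracking data with known ground truth: GPS tracks of
# chicks and their tagged parent(s), contact episodes, migration departures,
# behaviour labels with class-specific acceleration signatures, and
# colour-ring feeding observations. Everything downstream is testable
# against the truth tables this module emits.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror
#' the study system: a Wadden Sea island colony, a GPS fix every 10 min with
#' a 1.6 s burst of 20 Hz tri-axial acceleration, fledging at 35 d, autumn
#' departures at 108--139 d, and contact probability declining log-linearly
#' with chick age with strong between-year differences.
#'
#' @param seed Integer RNG seed; the same config yields byte-identical data.
#' @param n_families Number of families (>= 1). Each chick has at least one
#'   tagged parent; both parents are tagged with probability
#'   `both_parents_prob`.
#' @param colony_latlon `c(lat, lon)` of the colony (degrees, WGS-84).
#' @param gps_interval_min GPS fix cadence in minutes (default 10).
#' @param years Candidate study years, assigned to families round-robin.
#' @param baseline_contact_odds Log-odds of per-fix chick--parent contact at
#'   age 35 d, before year effects.
#' @param contact_decay_rate Change in contact log-odds per day of chick age.
#' @param year_effects Named additive log-odds offsets, one per year level.
#' @param departure_age_range Chick departure age window in days (within
#'   35--200).
#' @param parent_departure_age_range Parent departure window, expressed on
#'   the chick-age scale.
#' @param acc_rate Accelerometer rate in Hz (default 20).
#' @param burst_len Burst length in seconds (default 1.6);
#'   `burst_len * acc_rate` must be an integer >= 8.
#' @param dropout Per-fix random dropout probability (default 0.03; the
#'   plausible range for this tracker system is roughly 0.02--0.10).
#' @param acc_missing Probability that a fix's acceleration burst is
#'   truncated or missing (default 0.05).
#' @param gps_error_m Positional error of a fix, expressed as the 2-D RMS
#'   error in metres (default 3; per-axis sd is `gps_error_m / sqrt(2)`).
#' @param acc_noise Multiplier on all stochastic components of the
#'   acceleration signatures (0 = noise-free, 1 = default overlap).
#' @param behaviour_freqs Named probabilities over the 9 behaviour classes.
#' @param both_parents_prob Probability that both parents carry a tracker.
#' @param joint_departure If `TRUE`, the first family's chick and parent
#'   depart in the same hour (exercises joint-departure detection).
#' @param post_departure_days Days of (sparse) tracking kept after each
#'   bird's departure.
#' @param jitter_s Uniform timestamp jitter, in seconds, applied
#'   independently per bird so chick and parent fixes never coincide
#'   exactly (default 30, i.e. +/- 30 s).
#' @param contact_offset_m Range (metres) of true chick--parent separation
#'   during a contact episode; must stay below 5 m.
#' @param noncontact_min_m Minimum true separation outside contact episodes
#'   (default 50 m).
#' @param n_feeding_chicks Number of colour-ringed chicks in the synthetic
#'   resighting dataset (default 127).
#' @param feeding_age_range Age support (days) of the feeding observations
#'   (default 35--136, the post-fledging analysis window).
#' @param feeding_age_slope Log-linear slope of feeding-observation
#'   intensity per day of chick age (default -0.035, a strong decline).
#' @param feeding_dist_slope Increase in feeding distance from the colony
#'   per day of age, km/d (default 0.12).
#' @param feeding_dist_sd Residual sd of feeding distance, km.
#' @param parent_ringed_prob Probability the feeding parent is
#'   colour-ringed.
#' @param sex_evidence_error Probability a visual sex-evidence record claims
#'   the wrong sex.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_families = 6L,
                       colony_latlon = c(53.487, 6.25),
                       gps_interval_min = 10,
                       years = 2016:2018,
                       baseline_contact_odds = -2.2,
                       contact_decay_rate = -0.03,
                       year_effects = c(`2016` = 0, `2017` = -1.5,
                                        `2018` = 0.5),
                       departure_age_range = c(108L, 139L),
                       parent_departure_age_range = c(80L, 130L),
                       acc_rate = 20,
                       burst_len = 1.6,
                       dropout = 0.03,
                       acc_missing = 0.05,
                       gps_error_m = 3,
                       acc_noise = 1,
                       behaviour_freqs = c(search = 0.17, handle = 0.04,
                                           ingest = 0.04, sit = 0.25,
                                           stand = 0.22, `fly-active` = 0.05,
                                           `fly-passive` = 0.03, walk = 0.13,
                                           beg = 0.07),
                       both_parents_prob = 0.2,
                       joint_departure = TRUE,
                       post_departure_days = 4L,
                       jitter_s = 30,
                       contact_offset_m = c(0.2, 2),
                       noncontact_min_m = 50,
                       n_feeding_chicks = 127L,
                       feeding_age_range = c(35L, 136L),
                       feeding_age_slope = -0.035,
                       feeding_dist_slope = 0.12,
                       feeding_dist_sd = 5,
                       parent_ringed_prob = 0.8,
                       sex_evidence_error = 0.05) {
  stopifnot(gps_interval_min > 0, acc_rate > 0, burst_len > 0)
  n_read <- burst_len * acc_rate
  if (abs(n_read - round(n_read)) > 1e-9 || round(n_read) < 8) {
    stop("burst_len * acc_rate must be an integer >= 8", call. = FALSE)
  }
  if (departure_age_range[1] <= 35 || departure_age_range[2] >= 200) {
    stop("departure_age_range must lie within (35, 200)", call. = FALSE)
  }
  stopifnot(length(behaviour_freqs) == 9,
            setequal(names(behaviour_freqs), behaviour_classes()),
            abs(sum(behaviour_freqs) - 1) < 1e-8,
            max(contact_offset_m) < 5, noncontact_min_m > 10)
  cfg <- as.list(environment())
  cfg$n_read <- NULL
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_families, "families, seed", x$seed,
      sprintf("| contact logit: %.2f %+.3f * (age - 35) + year\n",
              x$baseline_contact_odds, x$contact_decay_rate))
  invisible(x)
}

.km_per_deg_lon <- function(lat) .km_per_deg_lat * cos(lat * pi / 180)

# East/north offsets (km) from the colony -> lat/lon.
.en_to_latlon <- function(e_km, n_km, colony) {
  cbind(lat = colony[1] + n_km / .km_per_deg_lat,
        lon = colony[2] + e_km / .km_per_deg_lon(colony[1]))
}

# Waypoint schedule (time in seconds from epoch, E/N in km) for one bird's
# pre-departure life: roosting near the colony with up to two daily foraging
# trips of a few km, flown at 15-30 km/h so the 5 km/h bout threshold is
# exercised routinely.
.local_waypoints <- function(day_starts, roost_en) {
  wt <- c(); we <- c(); wn <- c()
  for (d0 in day_starts) {
    wt <- c(wt, d0); we <- c(we, roost_en[1]); wn <- c(wn, roost_en[2])
    trip_hours <- c(if (stats::runif(1) < 0.85) stats::runif(1, 6, 10),
                    if (stats::runif(1) < 0.85) stats::runif(1, 13, 17))
    for (h in trip_hours) {
      dist <- stats::runif(1, 2, 6)
      brg <- stats::runif(1, 0, 2 * pi)
      spd <- stats::runif(1, 15, 30)
      site <- roost_en + dist * c(sin(brg), cos(brg))
      t_go <- d0 + h * 3600
      t_arr <- t_go + dist / spd * 3600
      t_leave <- t_arr + stats::runif(1, 2, 3.5) * 3600
      t_back <- t_leave + dist / spd * 3600
      wt <- c(wt, t_go, t_arr, t_leave, t_back)
      we <- c(we, roost_en[1], site[1], site[1], roost_en[1])
      wn <- c(wn, roost_en[2], site[2], site[2], roost_en[2])
    }
  }
  list(t = wt, e = we, n = wn)
}

# Migration waypoints: hourly legs heading south (heading jitter sd 8 deg)
# at 40-60 km/h; ~10 h on the departure day, ~6 h on following days.
.migration_waypoints <- function(depart_time, start_en, n_days) {
  wt <- depart_time; we <- start_en[1]; wn <- start_en[2]
  e <- start_en[1]; n <- start_en[2]
  t <- depart_time
  for (d in seq_len(n_days)) {
    hours <- if (d == 1) stats::runif(1, 9, 11) else stats::runif(1, 5, 7)
    if (d > 1) {
      t <- (floor(t / 86400) + 1) * 86400 + stats::runif(1, 8, 10) * 3600
      wt <- c(wt, t); we <- c(we, e); wn <- c(wn, n)
    }
    for (h in seq_len(ceiling(hours))) {
      leg_h <- min(1, hours - (h - 1))
      spd <- stats::runif(1, 40, 60)
      hdg <- pi + stats::rnorm(1, 0, 8 * pi / 180)  # south, jittered
      e <- e + spd * leg_h * sin(hdg)
      n <- n + spd * leg_h * cos(hdg)
      t <- t + leg_h * 3600
      wt <- c(wt, t); we <- c(we, e); wn <- c(wn, n)
    }
  }
  list(t = wt, e = we, n = wn)
}

# One bird's true positions on its (jittered) fix grid.
.bird_path <- function(grid_t, day_starts, roost_en, depart_time,
                       migration_wp = NULL) {
  wp <- .local_waypoints(day_starts[day_starts < depart_time], roost_en)
  if (!is.null(depart_time) && is.finite(depart_time)) {
    mig <- if (is.null(migration_wp)) {
      .migration_waypoints(depart_time, roost_en, n_days = 4)
    } else {
      migration_wp
    }
    keep <- wp$t < depart_time
    wp <- list(t = c(wp$t[keep], mig$t), e = c(wp$e[keep], mig$e),
               n = c(wp$n[keep], mig$n))
  }
  o <- order(wp$t)
  e <- stats::approx(wp$t[o], wp$e[o], xout = grid_t, rule = 2)$y
  n <- stats::approx(wp$t[o], wp$n[o], xout = grid_t, rule = 2)$y
  # small within-site wander so positions are never literally constant
  e <- e + stats::rnorm(length(e), 0, 0.008)
  n <- n + stats::rnorm(length(n), 0, 0.008)
  list(e = e, n = n)
}

#' Simulate GPS tracks for spoonbill families
#'
#' Generates chick and parent tracks at the configured cadence with random
#' dropout, timestamp jitter, GPS positional noise, foraging trips, contact
#' episodes placed with probability
#' `plogis(baseline + decay * (age - 35) + year effect)` (true separation
#' drawn from `contact_offset_m` during an episode, at least
#' `noncontact_min_m` otherwise), autumn-migration departures inside the
#' configured age window (southward, 40--60 km/h), and sparse "GSM-mode"
#' fixes (one per 1--6 h) after the departure day.
#'
#' @param config A [sim_config()].
#' @return A list with `tracks` (one tibble of all birds' fixes: `bird_id`,
#'   `timestamp`, `lat`, `lon`, `gps_speed_kmh`) and `truth`, itself a list:
#'   `birds` (per-bird metadata: family, role, sex, year, hatch date, nest,
#'   true departure day and moment), `behaviour` (per fix: true behaviour
#'   class and whether a complete acceleration burst exists), `contacts`
#'   (true contact episodes: chick, parent, chick fix time, true separation)
#'   and `states` (per bird-day: at-colony vs migrating).
#' @export
simulate_family_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families < 1) stop("n_families must be >= 1", call. = FALSE)
  set.seed(config$seed)
  cfg <- config
  colony <- cfg$colony_latlon
  iv <- cfg$gps_interval_min * 60
  sd_axis <- cfg$gps_error_m / sqrt(2) / 1000  # km per axis

  birds <- list(); paths <- list(); grids <- list()
  fam_meta <- list()
  for (f in seq_len(cfg$n_families)) {
    year <- cfg$years[(f - 1) %% length(cfg$years) + 1]
    hatch <- as.Date(sprintf("%d-05-01", year)) + sample(0:14, 1)
    nest_en <- stats::runif(2, -0.05, 0.05)
    chick_sex <- sample(c("female", "male"), 1)
    roles <- if (stats::runif(1) < cfg$both_parents_prob) {
      c("mother", "father")
    } else {
      sample(c("mother", "father"), 1)
    }
    dep_age <- sample(seq(cfg$departure_age_range[1],
                          cfg$departure_age_range[2]), 1)
    t0 <- as.numeric(as.POSIXct(as.character(hatch + 35), tz = "UTC"))
    chick_dep <- as.numeric(as.POSIXct(as.character(hatch + dep_age),
                                       tz = "UTC")) +
      stats::runif(1, 8, 14) * 3600
    fam <- list(f = f, year = year, hatch = hatch, nest_en = nest_en,
                t0 = t0, chick_dep = chick_dep, chick_sex = chick_sex)
    ids <- c(sprintf("F%02d_chick", f), sprintf("F%02d_%s", f, roles))
    fam$chick_id <- ids[1]
    fam$parent_ids <- ids[-1]
    fam$parent_roles <- roles
    fam$parent_dep <- numeric(length(roles))
    for (k in seq_along(roles)) {
      if (f == 1 && cfg$joint_departure && k == 1) {
        fam$parent_dep[k] <- chick_dep
      } else {
        pa <- sample(seq(cfg$parent_departure_age_range[1],
                         cfg$parent_departure_age_range[2]), 1)
        fam$parent_dep[k] <-
          as.numeric(as.POSIXct(as.character(hatch + pa), tz = "UTC")) +
          stats::runif(1, 8, 14) * 3600
      }
    }
    fam_meta[[f]] <- fam
  }

  mk_grid <- function(t0, dep_time, cfg) {
    t_end <- (floor(dep_time / 86400) + cfg$post_departure_days) * 86400
    grid <- seq(t0, t_end, by = iv)
    # GSM mode: after the departure day ends, one fix per 1-6 h (within
    # antenna range -- i.e. until departure -- all 10-min fixes download).
    gsm_from <- (floor(dep_time / 86400) + 1) * 86400
    keep <- grid < gsm_from
    sparse <- c()
    t <- gsm_from
    while (t <= t_end) {
      sparse <- c(sparse, grid[which.min(abs(grid - t))])
      t <- t + stats::runif(1, 1, 6) * 3600
    }
    sort(unique(c(grid[keep], sparse)))
  }

  all_tracks <- list(); all_truth_birds <- list()
  all_contacts <- list(); all_beh <- list(); all_states <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- fam_meta[[f]]
    n_birds <- 1 + length(fam$parent_ids)
    ids <- c(fam$chick_id, fam$parent_ids)
    deps <- c(fam$chick_dep, fam$parent_dep)
    grids_f <- list(); paths_f <- list(); jit_f <- list()
    chick_mig <- NULL
    for (b in seq_len(n_birds)) {
      grid <- mk_grid(fam$t0, deps[b], cfg)
      day_starts <- seq(floor(fam$t0 / 86400) * 86400,
                        max(grid), by = 86400)
      roost <- fam$nest_en + stats::runif(2, -0.2, 0.2)
      mig_wp <- NULL
      if (f == 1 && cfg$joint_departure && b == 2) {
        # joint-flock departure: parent flies the chick's route, offset ~2 km
        mig_wp <- chick_mig
        mig_wp$e <- mig_wp$e + stats::rnorm(length(mig_wp$e), 1, 0.8)
        mig_wp$n <- mig_wp$n + stats::rnorm(length(mig_wp$n), 0, 0.8)
        mig_wp$t <- mig_wp$t
      }
      if (b == 1) {
        chick_mig <- .migration_waypoints(deps[b], roost, n_days = 4)
        path <- .bird_path(grid, day_starts, roost, deps[b], chick_mig)
      } else {
        path <- .bird_path(grid, day_starts, roost, deps[b], mig_wp)
      }
      grids_f[[b]] <- grid
      paths_f[[b]] <- path
      jit_f[[b]] <- stats::runif(length(grid), -cfg$jitter_s, cfg$jitter_s)
    }

    # contact episodes: chick-anchored, while both chick and parent are
    # pre-departure; parent true position is moved onto the chick (offset
    # < 5 m) with the age/year-dependent probability, else kept >= 50 m off.
    chick_grid <- grids_f[[1]]
    chick_path <- paths_f[[1]]
    age_days <- floor((chick_grid - as.numeric(
      as.POSIXct(as.character(fam$hatch), tz = "UTC"))) / 86400)
    yr_eff <- cfg$year_effects[as.character(fam$year)]
    if (is.na(yr_eff)) yr_eff <- 0
    p_contact <- stats::plogis(cfg$baseline_contact_odds +
                                 cfg$contact_decay_rate * (age_days - 35) +
                                 yr_eff)
    for (b in seq_along(fam$parent_ids) + 1) {
      pgrid <- grids_f[[b]]
      slot <- match(chick_grid, pgrid)  # same 10-min grid pre-departure
      eligible <- chick_grid < deps[1] & chick_grid < deps[b] & !is.na(slot)
      hit <- eligible & stats::runif(length(chick_grid)) < p_contact
      off_r <- stats::runif(sum(hit), cfg$contact_offset_m[1],
                            cfg$contact_offset_m[2]) / 1000
      off_b <- stats::runif(sum(hit), 0, 2 * pi)
      paths_f[[b]]$e[slot[hit]] <- chick_path$e[hit] + off_r * sin(off_b)
      paths_f[[b]]$n[slot[hit]] <- chick_path$n[hit] + off_r * cos(off_b)
      # enforce separation outside episodes
      non <- eligible & !hit
      de <- paths_f[[b]]$e[slot[non]] - chick_path$e[non]
      dn <- paths_f[[b]]$n[slot[non]] - chick_path$n[non]
      d <- sqrt(de^2 + dn^2)
      too_close <- d < cfg$noncontact_min_m / 1000
      if (any(too_close)) {
        tgt <- (cfg$noncontact_min_m + stats::rexp(sum(too_close), 1 / 100)) /
          1000
        scl <- ifelse(d[too_close] > 0, tgt / d[too_close], 1)
        i <- slot[non][too_close]
        brg <- stats::runif(sum(too_close), 0, 2 * pi)
        paths_f[[b]]$e[i] <- chick_path$e[non][too_close] +
          ifelse(d[too_close] > 0, de[too_close] * scl, tgt * sin(brg))
        paths_f[[b]]$n[i] <- chick_path$n[non][too_close] +
          ifelse(d[too_close] > 0, dn[too_close] * scl, tgt * cos(brg))
      }
      all_contacts[[length(all_contacts) + 1]] <- tibble::tibble(
        chick_id = fam$chick_id,
        parent_id = fam$parent_ids[b - 1],
        timestamp = .POSIXct(chick_grid[hit] + jit_f[[1]][hit], tz = "UTC"),
        grid_time = .POSIXct(chick_grid[hit], tz = "UTC"),
        true_offset_m = off_r * 1000,
        chick_age = age_days[hit]
      )
    }

    for (b in seq_len(n_birds)) {
      grid <- grids_f[[b]]
      path <- paths_f[[b]]
      keep <- stats::runif(length(grid)) >= cfg$dropout
      keep[1] <- TRUE
      ts <- grid[keep] + jit_f[[b]][keep]
      e_noisy <- path$e[keep] + stats::rnorm(sum(keep), 0, sd_axis)
      n_noisy <- path$n[keep] + stats::rnorm(sum(keep), 0, sd_axis)
      ll <- .en_to_latlon(e_noisy, n_noisy, colony)
      # logger speed: true displacement over elapsed time, light noise
      dt_h <- diff(ts) / 3600
      step <- sqrt(diff(path$e[keep])^2 + diff(path$n[keep])^2)
      spd <- pmax(0, c(0, step / dt_h) + stats::rnorm(sum(keep), 0, 0.3))
      beh <- sample(names(cfg$behaviour_freqs), sum(keep), replace = TRUE,
                    prob = cfg$behaviour_freqs)
      acc_ok <- stats::runif(sum(keep)) >= cfg$acc_missing
      all_tracks[[length(all_tracks) + 1]] <- tibble::tibble(
        bird_id = ids[b],
        timestamp = .POSIXct(ts, tz = "UTC"),
        lat = ll[, "lat"], lon = ll[, "lon"],
        gps_speed_kmh = spd
      )
      all_beh[[length(all_beh) + 1]] <- tibble::tibble(
        bird_id = ids[b],
        timestamp = .POSIXct(ts, tz = "UTC"),
        behaviour = beh,
        acc_complete = acc_ok
      )
      dep_moment <- max(grid[grid <= deps[b]])
      role <- if (b == 1) "chick" else fam$parent_roles[b - 1]
      nest_ll <- .en_to_latlon(fam$nest_en[1], fam$nest_en[2], colony)
      all_truth_birds[[length(all_truth_birds) + 1]] <- tibble::tibble(
        bird_id = ids[b], family = f, role = role,
        sex = if (b == 1) fam$chick_sex else
          ifelse(role == "mother", "female", "male"),
        year = fam$year, hatch_date = fam$hatch,
        nest_lat = nest_ll[, "lat"], nest_lon = nest_ll[, "lon"],
        departure_day = as.Date(.POSIXct(deps[b], tz = "UTC"), tz = "UTC"),
        departure_moment = .POSIXct(dep_moment, tz = "UTC"),
        chick_id = fam$chick_id
      )
      days <- as.Date(.POSIXct(grid, tz = "UTC"), tz = "UTC")
      udays <- unique(days)
      all_states[[length(all_states) + 1]] <- tibble::tibble(
        bird_id = ids[b], date = udays,
        state = ifelse(udays >= as.Date(.POSIXct(deps[b], tz = "UTC"),
                                        tz = "UTC"),
                       "migrating", "at-colony")
      )
    }
  }
  list(
    tracks = do.call(rbind, all_tracks),
    truth = list(
      birds = do.call(rbind, all_truth_birds),
      behaviour = do.call(rbind, all_beh),
      contacts = if (length(all_contacts)) do.call(rbind, all_contacts) else
        tibble::tibble(chick_id = character(0), parent_id = character(0),
                       timestamp = .POSIXct(numeric(0), tz = "UTC"),
                       grid_time = .POSIXct(numeric(0), tz = "UTC"),
                       true_offset_m = numeric(0), chick_age = integer(0)),
      states = do.call(rbind, all_states)
    )
  )
}

# Acceleration signature constants per behaviour class. Frequencies in Hz,
# amplitudes and noise in g, speeds in km/h. Classes share overlapping
# amplitude ranges but occupy distinct frequency bands / axis mixes:
# begging is a slow large heave-and-surge pump, flapping flight a fast
# heave oscillation, walking and searching intermediate.
.acc_signatures <- list(
  search = list(static = c(0.20, 0, 0.94), freq = c(1.2, 2.4),
                amp = c(0.12, 0.30, 0.18), noise = 0.15, speed = c(0, 3)),
  handle = list(static = c(0.22, 0, 0.93), freq = c(2.2, 3.4),
                amp = c(0.28, 0.25, 0.20), noise = 0.18, speed = c(0, 2)),
  ingest = list(static = c(0.20, 0, 0.95), freq = NA,
                amp = c(0.80, 0.20, 0.40), noise = 0.15, speed = c(0, 2)),
  sit = list(static = c(0.25, 0, 0.92), freq = NA,
             amp = c(0, 0, 0), noise = 0.05, speed = c(0, 0.8)),
  stand = list(static = c(0.05, 0, 1.00), freq = NA,
               amp = c(0, 0, 0), noise = 0.05, speed = c(0, 0.8)),
  `fly-active` = list(static = c(0.60, 0, 0.75), freq = c(3.8, 5.2),
                      amp = c(0.30, 0.10, 0.80), noise = 0.15,
                      speed = c(20, 60)),
  `fly-passive` = list(static = c(0.60, 0, 0.78), freq = NA,
                       amp = c(0, 0, 0), noise = 0.10, speed = c(20, 60)),
  walk = list(static = c(0.10, 0, 0.98), freq = c(1.4, 2.6),
              amp = c(0.22, 0.08, 0.28), noise = 0.15, speed = c(0, 4)),
  beg = list(static = c(0.10, 0, 0.97), freq = c(0.7, 1.6),
             amp = c(0.35, 0.10, 0.35), noise = 0.15, speed = c(0, 2))
)

#' Acceleration signature constants
#'
#' The per-class generative constants of the burst simulator, one row per
#' behaviour: static posture means, oscillation frequency band, per-axis
#' oscillation amplitudes, additive noise sd (all in g) and the GPS-speed
#' range in km/h. `NA` frequency marks aperiodic classes (for `ingest` the
#' signature is a short spike train rather than an oscillation).
#'
#' @return A tibble, one row per class.
#' @export
acc_signature_table <- function() {
  rows <- lapply(names(.acc_signatures), function(cl) {
    s <- .acc_signatures[[cl]]
    tibble::tibble(behaviour = cl,
                   static_x = s$static[1], static_y = s$static[2],
                   static_z = s$static[3],
                   freq_lo = s$freq[1], freq_hi = s$freq[length(s$freq)],
                   amp_x = s$amp[1], amp_y = s$amp[2], amp_z = s$amp[3],
                   noise_sd = s$noise,
                   speed_lo = s$speed[1], speed_hi = s$speed[2])
  })
  do.call(rbind, rows)
}

.one_burst <- function(class, n, rate, noise) {
  s <- .acc_signatures[[class]]
  tt <- seq_len(n) / rate
  amp_jit <- if (noise > 0) stats::runif(3, 1 - 0.6 * noise, 1 + 0.6 * noise)
             else rep(1, 3)
  amp <- s$amp * amp_jit
  base <- matrix(rep(s$static, each = n), ncol = 3)
  if (class == "ingest") {
    # one or two sharp swallowing spikes over a quiet baseline
    n_spike <- if (noise > 0) sample(1:2, 1) else 2L
    pos <- if (noise > 0) sample(seq_len(max(n - 3, 1)), n_spike) else
      unique(pmax(1, round(c(0.3, 0.7) * n)))[seq_len(n_spike)]
    for (p in pos) {
      w <- p:min(p + 2, n)
      base[w, 1] <- base[w, 1] + amp[1] * c(1, 0.6, 0.3)[seq_along(w)]
      base[w, 3] <- base[w, 3] + amp[3] * c(1, 0.6, 0.3)[seq_along(w)]
    }
  } else if (!anyNA(s$freq)) {
    f <- if (noise > 0) stats::runif(1, s$freq[1], s$freq[2]) else
      mean(s$freq)
    ph <- if (noise > 0) stats::runif(1, 0, 2 * pi) else 0
    osc <- sin(2 * pi * f * tt + ph)
    # sway leads the vertical by a quarter cycle (body roll)
    osc_y <- sin(2 * pi * f * tt + ph + pi / 2)
    base <- base + cbind(amp[1] * osc, amp[2] * osc_y, amp[3] * osc)
  }
  eps <- matrix(stats::rnorm(3 * n, 0, s$noise * noise), ncol = 3)
  base + eps
}

#' Simulate labelled acceleration bursts
#'
#' Draws one tri-axial burst per labelled fix from the class-specific
#' generative signatures in [acc_signature_table()]. Classes are separable
#' but overlap in amplitude and (for the slow rhythmic classes) in
#' frequency, so classification performance degrades at short segment
#' lengths the way it does on field data. A fraction of bursts
#' (`config$acc_missing`, or the `acc_complete` column of `labels` when
#' present) is randomly truncated to emulate incomplete downloads.
#'
#' @param labels A tibble with columns `bird_id`, `timestamp` and
#'   `behaviour` (one of the 9 classes); optional `acc_complete` (logical).
#'   Typically `truth$behaviour` from [simulate_family_tracks()], or a
#'   designed training table.
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to `config$seed + 1` so bursts are
#'   reproducible independently of the track draw.
#' @return A burst tibble (see [segment_bursts()]) with columns `bird_id`,
#'   `burst_start`, `behaviour`, `gps_speed_kmh`, `complete` and list
#'   columns `x`, `y`, `z`.
#' @export
simulate_acc_bursts <- function(labels, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(labels))
  stopifnot(all(c("bird_id", "timestamp", "behaviour") %in% names(labels)))
  if (!all(labels$behaviour %in% behaviour_classes())) {
    stop("unknown behaviour label(s)", call. = FALSE)
  }
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  n_full <- as.integer(round(config$burst_len * config$acc_rate))
  m <- nrow(labels)
  complete <- if ("acc_complete" %in% names(labels)) {
    labels$acc_complete
  } else {
    stats::runif(m) >= config$acc_missing
  }
  lens <- ifelse(complete, n_full, pmax(4L, n_full - 1L -
                                          sample.int(n_full - 4L, m,
                                                     replace = TRUE)))
  xs <- vector("list", m); ys <- vector("list", m); zs <- vector("list", m)
  spd <- numeric(m)
  for (i in seq_len(m)) {
    cl <- labels$behaviour[i]
    b <- .one_burst(cl, lens[i], config$acc_rate, config$acc_noise)
    xs[[i]] <- b[, 1]; ys[[i]] <- b[, 2]; zs[[i]] <- b[, 3]
    sp <- .acc_signatures[[cl]]$speed
    spd[i] <- if (config$acc_noise > 0) stats::runif(1, sp[1], sp[2]) else
      mean(sp)
  }
  tibble::tibble(
    bird_id = labels$bird_id,
    burst_start = labels$timestamp,
    behaviour = labels$behaviour,
    gps_speed_kmh = spd,
    complete = complete,
    x = xs, y = ys, z = zs
  )
}

#' Balanced labelled bursts for classifier training
#'
#' Convenience wrapper around [simulate_acc_bursts()]: `n_per_class`
#' complete bursts of every behaviour class, for training and evaluating
#' the classifier without running the track simulator.
#'
#' @param n_per_class Bursts per class.
#' @param config A [sim_config()].
#' @param seed Optional seed (default `config$seed + 1`).
#' @return A burst tibble.
#' @export
simulate_training_bursts <- function(n_per_class, config, seed = NULL) {
  classes <- behaviour_classes()
  labels <- tibble::tibble(
    bird_id = "trainer",
    timestamp = as.POSIXct("2017-07-01", tz = "UTC") +
      seq_len(n_per_class * length(classes)) * 2,
    behaviour = rep(classes, each = n_per_class),
    acc_complete = TRUE
  )
  simulate_acc_bursts(labels, config, seed)
}

#' Simulate colour-ring feeding observations
#'
#' Per-chick feeding resightings with a log-linear decline of observation
#' intensity in chick age, feeding distance from the colony increasing with
#' age, a fraction of unringed feeding parents, and visual sex-evidence
#' records (situation codes 1--7) for ringed adults with a configurable
#' error rate.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (default `config$seed + 2`).
#' @return A list: `records` (one row per feeding observation: chick, year,
#'   date, true age and 10-d age class, distance from colony, parent id/sex
#'   when ringed, chick sex where known) and `sex_evidence` (visual
#'   situation-code records per ringed adult, with the adult's true sex for
#'   validation).
#' @export
simulate_feeding_observations <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  n_chicks <- config$n_feeding_chicks
  if (n_chicks == 0) {
    return(list(records = tibble::tibble(
      chick_id = character(0), year = integer(0), date = as.Date(character(0)),
      age_days = numeric(0), age_class = integer(0), distance_km = numeric(0),
      parent_ringed = logical(0), parent_id = character(0),
      parent_sex = character(0), chick_sex = character(0)),
      sex_evidence = tibble::tibble(bird_id = character(0),
                                    situation_code = integer(0),
                                    claimed_sex = character(0),
                                    true_sex = character(0))))
  }
  ages_support <- seq(config$feeding_age_range[1],
                      config$feeding_age_range[2])
  w <- exp(config$feeding_age_slope * (ages_support - ages_support[1]))
  recs <- list()
  parents <- tibble::tibble(parent_id = sprintf("A%03d", 1:60),
                            sex = sample(c("female", "male"), 60,
                                         replace = TRUE))
  for (i in seq_len(n_chicks)) {
    year <- sample(config$years, 1)
    hatch <- as.Date(sprintf("%d-05-01", year)) + sample(0:20, 1)
    n_obs <- 1L + stats::rpois(1, 0.45)
    age <- sample(ages_support, n_obs, replace = TRUE, prob = w)
    dist <- pmax(0.1, 1 + config$feeding_dist_slope * (age - 35) +
                   stats::rnorm(n_obs, 0, config$feeding_dist_sd))
    ringed <- stats::runif(n_obs) < config$parent_ringed_prob
    pidx <- sample.int(nrow(parents), n_obs, replace = TRUE)
    recs[[i]] <- tibble::tibble(
      chick_id = sprintf("C%03d", i), year = year, date = hatch + age,
      age_days = as.numeric(age), age_class = bin_age(age),
      distance_km = dist,
      parent_ringed = ringed,
      parent_id = ifelse(ringed, parents$parent_id[pidx], NA_character_),
      parent_sex = ifelse(ringed, parents$sex[pidx], NA_character_),
      chick_sex = sample(c("female", "male", NA_character_), n_obs,
                         replace = TRUE, prob = c(0.34, 0.34, 0.32))
    )
  }
  records <- do.call(rbind, recs)
  seen <- unique(stats::na.omit(records$parent_id))
  ev <- lapply(seen, function(pid) {
    true_sex <- parents$sex[parents$parent_id == pid]
    n_ev <- 1L + stats::rpois(1, 1.2)
    code <- sample(1:7, n_ev, replace = TRUE)
    wrong <- stats::runif(n_ev) < config$sex_evidence_error
    claimed <- ifelse(wrong, setdiff(c("female", "male"), true_sex), true_sex)
    tibble::tibble(bird_id = pid, situation_code = code,
                   claimed_sex = claimed, true_sex = true_sex)
  })
  list(records = records, sex_evidence = do.call(rbind, ev))
}

#' Simulate day-level contact summaries from the mixed-model process
#'
#' Draws daily (contact, linked) counts directly from the binomial GLMM
#' data-generating process: per-chick correlated random intercept and age
#' slope, year fixed effects, and ~144 linked fixes per day. This is the
#' calibration companion of the full track simulator: it makes 100-replicate
#' parameter-recovery studies at the study's scale (16 pairs x ~70 days)
#' affordable, at the cost of abstracting away the GPS layer entirely.
#'
#' @param n_pairs Number of chick--parent pairs.
#' @param n_days Tracking days per pair (ages 35, 36, ...).
#' @param beta0 Intercept on the logit scale (at standardized age 0).
#' @param beta_age Fixed age slope per standardized-age unit.
#' @param year_effects Named logit offsets per year; pairs are assigned
#'   years round-robin. The first level is the reference (its effect should
#'   be 0 for direct comparison with fitted contrasts).
#' @param sd_intercept,sd_slope,re_corr Random-effect standard deviations
#'   and their correlation.
#' @param trials_per_day Mean linked fixes per day (Poisson-ish around 144
#'   minus dropout; default 135).
#' @param seed RNG seed.
#' @return A daily summary tibble compatible with [fit_contact_model()]:
#'   `pair_id`, `chick_id`, `parent_id`, `year`, `chick_age`, `age_std`,
#'   `n_linked`, `n_contact`, `p_contact`, `chick_sex`, `parent_sex`, plus
#'   the true parameters as attributes (`truth`).
#' @export
simulate_daily_contact <- function(n_pairs = 16, n_days = 70,
                                   beta0 = -3, beta_age = -0.9,
                                   year_effects = c(`2016` = 0,
                                                    `2017` = -1.2,
                                                    `2018` = 0.6),
                                   sd_intercept = 0.8, sd_slope = 0.5,
                                   re_corr = 0.3, trials_per_day = 135,
                                   seed = 1L) {
  set.seed(seed)
  sig <- matrix(c(sd_intercept^2,
                  re_corr * sd_intercept * sd_slope,
                  re_corr * sd_intercept * sd_slope,
                  sd_slope^2), 2)
  ch <- chol(sig)
  re <- matrix(stats::rnorm(2 * n_pairs), ncol = 2) %*% ch
  yrs <- names(year_effects)[(seq_len(n_pairs) - 1) %% length(year_effects) +
                               1]
  age <- 35:(35 + n_days - 1)
  z_age <- (age - mean(age)) / stats::sd(age)
  rows <- lapply(seq_len(n_pairs), function(i) {
    eta <- beta0 + re[i, 1] + (beta_age + re[i, 2]) * z_age +
      year_effects[yrs[i]]
    n_linked <- pmax(100L, stats::rpois(n_days, trials_per_day))
    n_contact <- stats::rbinom(n_days, n_linked, stats::plogis(eta))
    tibble::tibble(
      pair_id = sprintf("P%02d", i),
      chick_id = sprintf("P%02d_chick", i),
      parent_id = sprintf("P%02d_parent", i),
      year = yrs[i], chick_age = age, age_std = z_age,
      n_linked = n_linked, n_contact = n_contact,
      p_contact = n_contact / n_linked,
      chick_sex = sample(c("female", "male"), 1),
      parent_sex = sample(c("female", "male"), 1)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(beta0 = beta0, beta_age = beta_age,
                             year_effects = year_effects,
                             sd_intercept = sd_intercept,
                             sd_slope = sd_slope, re_corr = re_corr)
  out
}
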