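# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation.

# --- fixture builders -------------------------------------------------------

colony_test <- c(53.487, 6.25)

# A track from east/north offsets (km) relative to a reference point, with
# fixes every `step_s` seconds. Plain planar placement, adequate at test
# scales.
make_track_en <- function(e_km, n_km, start = "2017-07-01 00:00:00",
                          step_s = 600, ref = colony_test,
                          bird_id = "bird1", speed = NA_real_) {
  km_lat <- pi / 180 * 6371.0088
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(
    bird_id = bird_id,
    timestamp = t0 + (seq_along(e_km) - 1) * step_s,
    lat = ref[1] + n_km / km_lat,
    lon = ref[2] + e_km / (km_lat * cos(ref[1] * pi / 180)),
    gps_speed_kmh = rep_len(speed, length(e_km))
  )
}

# A track that moves due south by the given per-interval distances (km).
make_south_track <- function(leg_km, start = "2017-09-10 08:00:00",
                             step_s = 600, ref = colony_test,
                             bird_id = "mig1") {
  n_km <- -cumsum(c(0, leg_km))
  make_track_en(rep(0, length(n_km)), n_km, start, step_s, ref, bird_id)
}

# --- oracles ----------------------------------------------------------------

# O(n^2) run finder: for every candidate [i, j] interval run, check that all
# interval speeds pass and that it cannot be extended either way.
brute_flight_bouts <- function(speeds, dt_h, max_gap_h = 0.5,
                               min_speed = 5) {
  n <- length(speeds)
  ok <- speeds >= min_speed & dt_h <= max_gap_h
  bouts <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(ok[i:j]) &&
          (i == 1 || !ok[i - 1]) &&
          (j == n || !ok[j + 1])) {
        bouts[[length(bouts) + 1]] <- c(start = i, end = j)
      }
    }
  }
  bouts
}

brute_f <- function(pred, truth) {
  classes <- sort(unique(truth))
  out <- numeric(length(classes))
  names(out) <- classes
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    out[cl] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  out
}

brute_aicc <- function(ll, k, n) -2 * ll + 2 * k + (2 * k * k + 2 * k) /
  (n - k - 1)

# Exhaustive parsimony rule: enumerate all candidates within 2 of the best.
brute_select <- function(aicc_vals, k_vals) {
  best <- min(aicc_vals)
  cand <- which(aicc_vals - best <= 2)
  kk <- k_vals[cand]
  inner <- cand[kk == min(kk)]
  inner[which.min(aicc_vals[inner])]
}

# Exactly n linked fixes on one day.
linked_day <- function(n, date = "2017-06-01", seed = 1) {
  set.seed(seed)
  t0 <- as.POSIXct(date, tz = "UTC")
  tibble::tibble(
    chick_id = "c1", parent_id = "p1", pair_id = "c1-p1",
    timestamp = t0 + sort(sample(0:86399, n)),
    parent_timestamp = t0, delta_t_min = stats::runif(n, 0, 9),
    distance_m = stats::rexp(n, 1 / 80),
    parent_departed = FALSE,
    chick_lat = 53.5, chick_lon = 6.25,
    dist_nest_km = stats::runif(n, 0, 5)
  )
}

# A random linked-fix table for daily-summary recounts.
random_linked <- function(n_days, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_days), function(d) {
    n <- sample(120:150, 1)
    t0 <- as.POSIXct("2017-06-01", tz = "UTC") + (d - 1) * 86400
    tibble::tibble(
      chick_id = "c1", parent_id = "p1", pair_id = "c1-p1",
      timestamp = t0 + sort(sample(0:86399, n)),
      parent_timestamp = t0, delta_t_min = stats::runif(n, 0, 9),
      distance_m = stats::rexp(n, 1 / 80),
      parent_departed = FALSE,
      chick_lat = 53.5, chick_lon = 6.25,
      dist_nest_km = stats::runif(n, 0, 5)
    )
  })
  do.call(rbind, rows)
}
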