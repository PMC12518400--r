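small_cfg <- function(...) sim_config(seed = 31, n_families = 2, ...)

test_that("config invariants are enforced", {
  expect_error(sim_config(burst_len = 0.3), ">= 8")
  expect_error(sim_config(departure_age_range = c(30, 120)), "35, 200")
  expect_error(sim_config(gps_interval_min = 0))
  expect_error(simulate_family_tracks(sim_config(n_families = 0)),
               "n_families")
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_family_tracks(small_cfg())
  b <- simulate_family_tracks(small_cfg())
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth$contacts, b$truth$contacts)
  expect_identical(a$truth$birds, b$truth$birds)
  c_bursts <- simulate_acc_bursts(a$truth$behaviour[1:50, ], small_cfg())
  d_bursts <- simulate_acc_bursts(a$truth$behaviour[1:50, ], small_cfg())
  expect_identical(c_bursts, d_bursts)
  f1 <- simulate_feeding_observations(small_cfg())
  f2 <- simulate_feeding_observations(small_cfg())
  expect_identical(f1$records, f2$records)
})

test_that("tracks have the designed structure", {
  sim <- simulate_family_tracks(small_cfg())
  birds <- sim$truth$birds
  # every chick has at least one tagged parent, in the same family
  for (f in unique(birds$family)) {
    fam <- birds[birds$family == f, ]
    expect_identical(sum(fam$role == "chick"), 1L)
    expect_gte(sum(fam$role != "chick"), 1L)
  }
  for (id in birds$bird_id) {
    tr <- sim$tracks[sim$tracks$bird_id == id, ]
    expect_true(all(diff(as.numeric(tr$timestamp)) > 0))
    # pre-departure cadence ~10 min with dropout; gaps are multiples of it
    dep <- birds$departure_moment[birds$bird_id == id]
    pre_dt <- diff(as.numeric(tr$timestamp[tr$timestamp < dep]))
    expect_true(all(pre_dt < 3600 * 2))
    # post-departure GSM mode: sparse fixes, 1-6 h apart
    post <- tr$timestamp[as.Date(tr$timestamp, tz = "UTC") >
                           birds$departure_day[birds$bird_id == id]]
    if (length(post) > 3) {
      expect_gte(stats::median(diff(as.numeric(post))), 3600)
    }
  }
})

test_that("contact construction separates episodes from background", {
  sim <- simulate_family_tracks(small_cfg())
  tc <- sim$truth$contacts
  expect_gt(nrow(tc), 50)
  expect_true(all(tc$true_offset_m < 5))
  # contact episodes only between birds of the same family
  birds <- sim$truth$birds
  fam_of <- stats::setNames(birds$family, birds$bird_id)
  expect_true(all(fam_of[tc$chick_id] == fam_of[tc$parent_id]))
  # departures fall inside the configured age window
  chicks <- birds[birds$role == "chick", ]
  dep_age <- as.numeric(chicks$departure_day - chicks$hatch_date)
  expect_true(all(dep_age >= 108 & dep_age <= 139))
})

test_that("a null age slope produces flat contact in age", {
  cfg <- sim_config(seed = 77, n_families = 3, contact_decay_rate = 0,
                    years = 2017, year_effects = c(`2017` = 0),
                    joint_departure = FALSE)
  sim <- simulate_family_tracks(cfg)
  tc <- sim$truth$contacts
  # restrict to ages where every parent is still present (parents depart
  # from chick age 80), so eligibility per age is constant
  tc <- tc[tc$chick_age <= 74, ]
  # per-age counts of contact vs eligible fixes, logistic slope ~ 0
  agg <- as.data.frame(table(age = tc$chick_age))
  agg$age <- as.numeric(as.character(agg$age))
  # eligible fix count per age ~ 144/day per pair; regress episode count
  fit <- stats::glm(Freq ~ age, family = stats::poisson(), data = agg)
  ci <- suppressMessages(stats::confint(fit))["age", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("a strongly negative slope ranks young above old contact", {
  cfg <- sim_config(seed = 78, n_families = 3, contact_decay_rate = -0.08,
                    years = 2017, year_effects = c(`2017` = 0),
                    joint_departure = FALSE)
  sim <- simulate_family_tracks(cfg)
  tc <- sim$truth$contacts
  young <- sum(tc$chick_age %in% 35:45)
  old <- sum(tc$chick_age %in% 85:95)
  expect_gt(young, old * 3)
})

test_that("behaviour frequencies match the configuration", {
  sim <- simulate_family_tracks(small_cfg())
  beh <- sim$truth$behaviour
  freq <- table(beh$behaviour) / nrow(beh)
  target <- small_cfg()$behaviour_freqs
  # multinomial sampling error at this n is well under 1 percentage point
  expect_true(all(abs(freq[names(target)] - target) < 0.02))
})

test_that("bursts carry class signatures and truncation", {
  cfg <- small_cfg()
  labels <- tibble::tibble(
    bird_id = "b", timestamp = as.POSIXct("2017-07-01", tz = "UTC") + 1:400,
    behaviour = rep(behaviour_classes(), length.out = 400)
  )
  bursts <- simulate_acc_bursts(labels, cfg)
  n_full <- 32L
  lens <- vapply(bursts$x, length, integer(1))
  expect_true(all(lens[bursts$complete] == n_full))
  expect_true(all(lens[!bursts$complete] < n_full))
  expect_gt(sum(!bursts$complete), 0)      # ~5% truncated
  expect_lt(mean(!bursts$complete), 0.15)
  # begging is slow and large, flapping fast: check dominant frequencies
  feats <- featurize_segments(
    segment_bursts(bursts[bursts$complete, ], 1.6), 20)
  beg_f <- feats$z_domfreq[feats$behaviour == "beg"]
  fly_f <- feats$z_domfreq[feats$behaviour == "fly-active"]
  expect_lt(stats::median(beg_f), 2)
  expect_gt(stats::median(fly_f), 3.5)
  expect_error(simulate_acc_bursts(
    tibble::tibble(bird_id = "b",
                   timestamp = as.POSIXct("2017-07-01", tz = "UTC"),
                   behaviour = "hover"), cfg), "unknown behaviour")
})

test_that("feeding observations decline in age as configured", {
  cfg <- small_cfg()
  feeds <- simulate_feeding_observations(cfg)
  rec <- feeds$records
  expect_gt(nrow(rec), cfg$n_feeding_chicks - 1)
  expect_true(all(rec$age_days >= 35 & rec$age_days <= 136))
  # strong decline: monotone decreasing counts over the first age bins
  cnt <- table(rec$age_class)
  expect_gt(cnt[["40"]], cnt[["70"]])
  expect_gt(cnt[["70"]], cnt[["110"]])
  # unringed parents exist and carry no id
  expect_true(any(!rec$parent_ringed))
  expect_true(all(is.na(rec$parent_id[!rec$parent_ringed])))
  # empty request yields an empty, well-formed table
  empty <- simulate_feeding_observations(
    sim_config(n_feeding_chicks = 0))
  expect_identical(nrow(empty$records), 0L)
  expect_identical(nrow(empty$sex_evidence), 0L)
})

test_that("a flat feeding-age slope is recovered as a null effect", {
  hits <- 0
  for (s in 1:60) {
    # complete 10-day bins (35-134) so a flat slope is genuinely flat at
    # the bin level
    cfg <- sim_config(seed = s, n_feeding_chicks = 80,
                      feeding_age_range = c(35L, 134L),
                      feeding_age_slope = 0)
    rec <- simulate_feeding_observations(cfg)$records
    fit <- fit_feeding_age_model(rec, seed = s)
    ci <- fit$coefficients["age_class", ]
    lo <- ci[[1]] - 1.96 * ci[[2]]
    hi <- ci[[1]] + 1.96 * ci[[2]]
    hits <- hits + (lo < 0 && hi > 0)
  }
  expect_gte(hits / 60, 0.9)
})

test_that("day-level contact generator reproduces its own parameters", {
  d <- simulate_daily_contact(n_pairs = 16, n_days = 70, seed = 4)
  expect_identical(nrow(d), 16L * 70L)
  expect_true(all(d$n_contact <= d$n_linked))
  tr <- attr(d, "truth")
  # strong decline visible in raw proportions
  young <- mean(d$p_contact[d$chick_age <= 45])
  old <- mean(d$p_contact[d$chick_age >= 90])
  expect_gt(young, old)
  expect_identical(d, simulate_daily_contact(n_pairs = 16, n_days = 70,
                                             seed = 4))
})
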