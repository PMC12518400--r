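test_that("linkage keeps close-in-time pairs and drops the rest", {
  t0 <- as.POSIXct("2017-07-01 12:00:00", tz = "UTC")
  chick <- make_track_en(c(0, 0, 0), c(0, 0, 0), bird_id = "c",
                         step_s = 3600)
  # parent fixes 2 min, 11 min and 2 min from the three chick fixes
  parent <- chick
  parent$bird_id <- "p"
  parent$timestamp <- chick$timestamp + c(120, 660, -120)
  parent$lat <- parent$lat + c(0, 0, 5 / 111194.9)  # third fix ~5 m north
  lk <- link_tracks(chick, parent)
  expect_identical(nrow(lk), 2L)            # 11-min fix dropped
  expect_equal(lk$delta_t_min, c(2, 2))
  expect_lt(abs(lk$distance_m[2] - 5), 0.05)
})

test_that("fixes after parent departure are kept as certain no-contact", {
  chick <- make_track_en(rep(0, 6), rep(0, 6), step_s = 3 * 3600,
                         bird_id = "c")
  parent <- make_track_en(rep(0, 6), seq(0, -400, length.out = 6),
                          step_s = 3 * 3600, bird_id = "p")
  parent$timestamp <- parent$timestamp + 5400   # always 1.5 h off
  dep <- structure(list(bird_id = "p",
                        departure_day = as.Date("2017-07-01"),
                        departure_moment = chick$timestamp[2]),
                   class = "departure_event")
  none <- link_tracks(chick, parent)
  expect_identical(nrow(none), 0L)          # dt never < 10 min
  lk <- link_tracks(chick, parent, parent_departure = dep)
  expect_true(all(lk$parent_departed))
  expect_identical(nrow(lk), 4L)            # fixes after the moment
  lk <- flag_contact(lk)
  expect_false(any(lk$in_contact))          # hundreds of km apart
})

test_that("contact uses a strict distance threshold and is monotone", {
  lk <- tibble::tibble(distance_m = c(9.99, 10, 49.9, 50, 120))
  expect_identical(flag_contact(lk, 10)$in_contact,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(flag_contact(lk, 50)$in_contact,
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_gte(sum(flag_contact(lk, 50)$in_contact),
             sum(flag_contact(lk, 10)$in_contact))
  expect_error(flag_contact(lk, 0), "positive")
  expect_error(flag_contact(lk, -5), "positive")
})

test_that("daily summaries apply the completeness filters and arithmetic", {
  hatch <- c(c1 = as.Date("2017-04-25"))
  # day 1: 144 linked, 72 in contact; day 2: 129 linked (below 130)
  lk <- rbind(linked_day(144, "2017-06-01", seed = 3),
              linked_day(129, "2017-06-02", seed = 4))
  lk$distance_m <- 1000
  lk$distance_m[1:72] <- 5           # 72 contacts on day 1
  lk <- flag_contact(lk, 10)
  ds <- summarise_daily(lk, behaviours = NULL, hatch_dates = hatch,
                        min_linked_acc = 1)
  # day 2 fails both filters (no acc data at all, n_linked < 130) -> gone
  expect_identical(nrow(ds), 1L)
  expect_identical(ds$n_linked, 144L)
  expect_equal(ds$p_contact, 0.5)
  expect_identical(ds$chick_age, 37L)   # hatched 25 Apr, day 1 June
})

test_that("behaviour-specific proportions count begging in contact", {
  hatch <- c(c1 = as.Date("2017-04-20"))
  lk <- linked_day(144, "2017-06-01", seed = 5)
  lk$distance_m <- 1000
  beh <- tibble::tibble(bird_id = "c1", timestamp = lk$timestamp,
                        behaviour = "stand", acc_complete = FALSE)
  # 100 acc-complete fixes; 10 begging fixes that are also in contact
  beh$acc_complete[1:100] <- TRUE
  beh$behaviour[1:10] <- "beg"
  beh$behaviour[11:25] <- "search"
  lk$distance_m[1:18] <- 4           # contacts: all 10 beg + 8 search
  lk <- flag_contact(lk, 10)
  ds <- summarise_daily(lk, beh, hatch)
  expect_identical(ds$n_linked_with_acc, 100L)
  expect_equal(ds$p_contact_begging, 0.10)
  expect_equal(ds$p_contact_foraging, 0.08)  # search pools into forage
  # nest-distance summaries are over contact fixes only
  expect_equal(ds$mean_dist_nest_km, mean(lk$dist_nest_km[1:18]))
})

test_that("daily proportions equal a brute-force recount", {
  hatch <- c(c1 = as.Date("2017-04-01"))
  lk <- flag_contact(random_linked(30, seed = 9), 50)
  ds <- summarise_daily(lk, behaviours = NULL, hatch_dates = hatch,
                        min_linked = 100, min_linked_acc = 1)
  for (i in seq_len(nrow(ds))) {
    rows <- lk[as.Date(lk$timestamp) == ds$date[i], ]
    expect_identical(ds$n_linked[i], nrow(rows))
    expect_equal(ds$p_contact[i], mean(rows$distance_m < 50))
  }
})

test_that("age window restricts summaries", {
  hatch <- c(c1 = as.Date("2017-05-20"))   # age 12 on 1 June
  lk <- flag_contact(random_linked(3, seed = 2), 10)
  ds <- summarise_daily(lk, NULL, hatch, min_linked = 100,
                        min_linked_acc = 1)
  expect_identical(nrow(ds), 0L)           # all days below 35 d
})

test_that("pair filter enforces minimum days and pre-departure data", {
  hatch <- c(c1 = as.Date("2017-04-01"))
  lk <- flag_contact(random_linked(12, seed = 4), 50)
  ds <- summarise_daily(lk, NULL, hatch, min_linked = 100,
                        min_linked_acc = 1)
  expect_identical(nrow(pair_filter(ds, min_days = 10)), nrow(ds))
  expect_identical(nrow(pair_filter(ds, min_days = nrow(ds) + 1)), 0L)
  # rows on/after the chick's departure day are removed first
  dep <- c(c1 = ds$date[9])
  kept <- pair_filter(ds, min_days = 5, chick_departures = dep)
  expect_identical(nrow(kept), 8L)
  expect_true(all(kept$date < dep))
  # and the pair-day count is applied after that removal
  expect_identical(nrow(pair_filter(ds, min_days = 9,
                                    chick_departures = dep)), 0L)
})

test_that("last contact age picks the latest contact moment", {
  hatch <- as.Date("2017-05-01")
  t0 <- as.POSIXct("2017-06-20 10:00:00", tz = "UTC")  # age 50
  lk <- tibble::tibble(
    timestamp = t0 + c(0, 38, 70) * 86400,             # ages 50, 88, 120
    in_contact = c(TRUE, TRUE, TRUE)
  )
  expect_identical(last_contact_age(lk, hatch), 120L)
  lk1 <- lk[1, ]
  expect_identical(last_contact_age(lk1, hatch), 50L)
  lk$in_contact <- FALSE
  expect_identical(last_contact_age(lk, hatch), NA_integer_)
})

test_that("post-departure screening finds joint flights, not far pairs", {
  dep_c <- structure(list(departure_moment =
                            as.POSIXct("2017-09-10 08:00:00", tz = "UTC")),
                     class = "departure_event")
  dep_p <- dep_c
  # parallel southward tracks 60 km apart: never a candidate
  chick <- make_south_track(rep(25, 20), start = "2017-09-10 09:00:00",
                            step_s = 3600, bird_id = "c")
  parent <- make_track_en(rep(60, 21), -cumsum(c(0, rep(25, 20))),
                          start = "2017-09-10 09:00:00", step_s = 3600,
                          bird_id = "p")
  expect_identical(nrow(post_departure_proximity(chick, parent, dep_c,
                                                 dep_p)), 0L)
  # same flock: same path, 4 min time shift -> contiguous candidate run
  parent2 <- chick
  parent2$bird_id <- "p"
  parent2$timestamp <- parent2$timestamp + 240
  cand <- post_departure_proximity(chick, parent2, dep_c, dep_p)
  expect_identical(nrow(cand), nrow(chick))
  expect_true(all(cand$distance_km < 25))
  expect_true(all(diff(as.numeric(cand$timestamp)) == 3600))
  # zero radius yields nothing
  expect_identical(nrow(post_departure_proximity(chick, parent2, dep_c,
                                                 dep_p, radius_km = 0)), 0L)
})
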