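make_bursts <- function(xs, speeds = 0, behaviour = "stand") {
  tibble::tibble(
    bird_id = "b1",
    burst_start = as.POSIXct("2017-07-01", tz = "UTC") + seq_along(xs) * 2,
    behaviour = rep_len(behaviour, length(xs)),
    gps_speed_kmh = rep_len(speeds, length(xs)),
    complete = vapply(xs, length, integer(1)) == 32L,
    x = xs, y = xs, z = xs
  )
}

test_that("segmentation yields only full non-overlapping segments", {
  full <- make_bursts(list(rnorm(32)))
  expect_identical(nrow(segment_bursts(full, 0.4)), 4L)
  expect_identical(nrow(segment_bursts(full, 0.8)), 2L)
  expect_identical(nrow(segment_bursts(full, 1.6)), 1L)
  # a 1.2 s truncated burst at 0.8 s: one segment, 0.4 s discarded
  trunc <- make_bursts(list(rnorm(24)))
  s <- segment_bursts(trunc, 0.8)
  expect_identical(nrow(s), 1L)
  expect_identical(length(s$x[[1]]), 16L)
  expect_identical(s$x[[1]], trunc$x[[1]][1:16])
  # a 0.3 s remnant contributes nothing
  expect_identical(nrow(segment_bursts(make_bursts(list(rnorm(6))), 0.4)), 0L)
  expect_error(segment_bursts(full, 0.5), "segment_length")
})

test_that("features: degenerate, spectral and determinism cases", {
  zero <- featurize(rep(0, 32), rep(0, 32), rep(0, 32), gps_speed = 0)
  expect_equal(zero[["x_sd"]], 0)
  expect_equal(zero[["odba"]], 0)
  expect_equal(zero[["x_skew"]], 0)     # defined 0 for constant axes
  expect_equal(zero[["cor_xy"]], 0)
  # pure 2 Hz sinusoid on the heave axis
  tt <- seq_len(32) / 20
  s2 <- featurize(rep(0, 32), rep(0, 32), sin(2 * pi * 2 * tt),
                  gps_speed = 0)
  expect_lt(abs(s2[["z_domfreq"]] - 2), 0.1)
  # peak-bin share of the padded spectrum: well above the flat baseline
  # (1/256) even though window leakage spreads the main lobe
  expect_gt(s2[["z_dompow"]], 10 / 256)
  # identical segments, identical vectors
  set.seed(1)
  x <- rnorm(32); y <- rnorm(32); z <- rnorm(32)
  expect_identical(featurize(x, y, z, 3), featurize(x, y, z, 3))
  expect_error(featurize(c(NA, rnorm(31)), y, z, 3), "non-finite")
})

test_that("features shift with a constant offset only where documented", {
  set.seed(2)
  x <- rnorm(32); y <- rnorm(32); z <- rnorm(32)
  f0 <- featurize(x, y, z, 3)
  f1 <- featurize(x + 0.7, y + 0.7, z + 0.7, 3)
  shifting <- c("x_mean", "y_mean", "z_mean", "x_min", "y_min", "z_min",
                "x_max", "y_max", "z_max")
  expect_equal(f1[shifting], f0[shifting] + 0.7)
  invariant <- setdiff(names(f0), shifting)
  expect_equal(f1[invariant], f0[invariant], tolerance = 1e-10)
})

test_that("F-measure matches hand counts and pooling absorbs confusion", {
  # TP = 8, FP = 2, FN = 2 for class a
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), "b", "b", rep("b", 8), "a", "a")
  f <- f_measure(pred, truth)
  expect_equal(unname(f["a"]), 0.8)
  expect_equal(f_measure(truth, truth), c(a = 1, b = 1))
  # search mislabelled as ingest vanishes under the forage pool
  tr <- c("search", "search", "sit")
  pr <- c("ingest", "search", "sit")
  pooled <- f_measure(pr, tr, behaviour_pooling())
  expect_equal(unname(pooled["forage"]), 1)
  expect_lt(f_measure(pr, tr)["search"], 1)
  expect_error(f_measure("a", c("a", "b")), "equal length")
})

test_that("F-measure equals the brute-force confusion matrix", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    classes <- letters[1:sample(2:5, 1)]
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    expect_equal(f_measure(pred, truth), brute_f(pred, truth))
  }
})

test_that("habitat correction rewrites foraging over land to walking", {
  water <- list(data.frame(lon = c(6.0, 6.2, 6.2, 6.0),
                           lat = c(53.0, 53.0, 53.2, 53.2)))
  lat <- c(53.1, 53.5, 53.5)   # in water, on land, on land
  lon <- c(6.1, 6.1, 6.1)
  labs <- c("search", "ingest", "beg")
  out <- habitat_correct(labs, lat, lon, water)
  expect_identical(out, c("search", "walk", "beg"))
  expect_identical(in_foraging_habitat(lat, lon, water),
                   c(TRUE, FALSE, FALSE))
  # multi-polygon maps and points outside all coverage (treated as land)
  two <- c(water, list(data.frame(lon = c(6.4, 6.5, 6.5, 6.4),
                                  lat = c(53.4, 53.4, 53.5, 53.5))))
  expect_true(in_foraging_habitat(53.45, 6.45, two))
  expect_identical(habitat_correct("forage", 10, 10, two), "walk")
})

test_that("noise-free classes are separable by a nearest-centroid rule", {
  cfg <- sim_config(seed = 21, acc_noise = 0)
  bursts <- simulate_training_bursts(12, cfg)
  feats <- featurize_segments(segment_bursts(bursts, 1.6), 20)
  cols <- setdiff(names(feats), c("bird_id", "burst_start", "segment",
                                  "behaviour"))
  m <- as.matrix(feats[cols])
  m <- scale(m, center = TRUE, scale = apply(m, 2, function(v)
    max(stats::sd(v), 1e-9)))
  cent <- apply(m, 2, function(col) tapply(col, feats$behaviour, mean))
  pred <- rownames(cent)[apply(m, 1, function(r)
    which.min(colSums((t(cent) - r)^2)))]
  expect_equal(unname(f_measure(pred, feats$behaviour)),
               rep(1, 9))
})

test_that("classifier is reproducible and fails on degenerate labels", {
  cfg <- sim_config(seed = 8)
  bursts <- simulate_training_bursts(20, cfg)
  feats <- featurize_segments(segment_bursts(bursts, 1.6), 20)
  m1 <- train_classifier(feats, num_trees = 100, seed = 5)
  m2 <- train_classifier(feats, num_trees = 100, seed = 5)
  expect_identical(predict(m1, feats), predict(m2, feats))
  p <- predict(m1, feats, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(length(feature_importance(m1)) > 0)
  one <- feats
  one$behaviour <- "sit"
  expect_error(train_classifier(one), "2 classes")
  few <- feats[c(1:2, 21:40), ]
  expect_error(train_classifier(few), ">= 5")
})

test_that("shuffled labels collapse held-out F to chance", {
  cfg <- sim_config(seed = 13)
  bursts <- simulate_training_bursts(40, cfg)
  set.seed(99)
  bursts$behaviour <- sample(bursts$behaviour)
  ev <- evaluate_segment_lengths(bursts, segment_lengths = 1.6, seed = 13,
                                 pooling = NULL)
  # 9 balanced classes: chance F ~ 1/9; allow generous slack
  expect_lt(mean(ev$scores$F), 0.25)
})

test_that("stratified split keeps every class on both sides", {
  labels <- rep(c("a", "b", "c"), c(50, 20, 7))
  sp <- stratified_split(labels, 0.7, seed = 2)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  for (cl in c("a", "b", "c")) {
    expect_gt(sum(labels[sp$train] == cl), 0)
    expect_gt(sum(labels[sp$test] == cl), 0)
  }
})
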