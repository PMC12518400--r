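test_that("AICc follows the closed form and its limits", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_equal(aicc(-10, 0, 10), 20)               # k = 0: just deviance
  # large-n limit approaches plain AIC
  expect_equal(aicc(-50, 4, 1e8), -2 * -50 + 8, tolerance = 1e-5)
  expect_error(aicc(-10, 5, 6), "n <= k")
  set.seed(6)
  for (i in 1:300) {
    ll <- rnorm(1, -100, 30)
    k <- sample(1:10, 1)
    n <- k + 1 + sample(1:200, 1)
    expect_equal(aicc(ll, k, n), brute_aicc(ll, k, n))
  }
})

fake_fit <- function(a, k) {
  structure(list(label = paste0("m", k), AICc = a, k = k, logLik = NA,
                 n = 100, converged = TRUE), class = "model_fit")
}

test_that("model selection takes the fewest parameters within 2 AICc", {
  res <- list(fake_fit(100.0, 5), fake_fit(101.5, 3), fake_fit(103.0, 2))
  expect_identical(select_model(res)$k, 3)
  expect_identical(select_model(res[1])$k, 5)       # single model: itself
  # boundary: exactly 2 apart is inside the candidate set
  res2 <- list(fake_fit(100.0, 5), fake_fit(102.0, 2))
  expect_identical(select_model(res2)$k, 2)
  # non-converged fits are never selected
  bad <- fake_fit(90, 1); bad$converged <- FALSE
  expect_identical(select_model(c(res, list(bad)))$k, 3)
  expect_error(select_model(list(bad)), "no converged")
})

test_that("model selection equals exhaustive enumeration", {
  set.seed(8)
  for (i in 1:300) {
    m <- sample(2:8, 1)
    a <- round(runif(m, 100, 108), 2)
    k <- sample(1:9, m, replace = TRUE)
    res <- mapply(fake_fit, a, k, SIMPLIFY = FALSE)
    expect_identical(select_model(res)$label,
                     res[[brute_select(a, k)]]$label)
  }
})

test_that("selection table orders by AICc with weights summing to one", {
  res <- list(fake_fit(100, 5), fake_fit(101.5, 3), fake_fit(103, 2))
  tab <- selection_table(res)
  expect_equal(tab$dAICc[1], 0)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(sum(tab$weight), 1)
})

test_that("survival arithmetic matches the binomial formulas", {
  s <- survival_comparison(15, 7, 0.56, 0.04)
  expect_equal(round(s$rate, 2), 0.53)
  expect_equal(round(s$se, 2), 0.13)
  expect_equal(round(s$z, 2), -0.20)
  s0 <- survival_comparison(20, 0, 0.5, 0.1)
  expect_equal(s0$rate, 1)
  expect_equal(s0$se, 0)
  expect_error(survival_comparison(10, 11, 0.5, 0.1), "n_died")
  expect_error(survival_comparison(0, 0, 0.5, 0.1))
})

test_that("one-per-chick subsampling is seeded and restrictable", {
  rec <- simulate_feeding_observations(sim_config(seed = 3))$records
  a <- subsample_one_per_chick(rec, seed = 7)
  b <- subsample_one_per_chick(rec, seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a), length(unique(rec$chick_id)))
  expect_false(any(duplicated(a$chick_id)))
  sexed <- subsample_one_per_chick(rec, seed = 7, require = "chick_sex")
  expect_false(anyNA(sexed$chick_sex))
})

test_that("feeding-age Poisson model recovers a strong decline", {
  rec <- simulate_feeding_observations(sim_config(seed = 5))$records
  fit <- fit_feeding_age_model(rec, seed = 5)
  expect_lt(fit$age_slope, 0)
  expect_lt(fit$age_z, -3)
  expect_true(is.finite(fit$AICc))
  # the sign of the age effect is stable across subsampling seeds
  signs <- vapply(1:25, function(s)
    sign(fit_feeding_age_model(rec, seed = s)$age_slope), numeric(1))
  expect_true(all(signs == -1))
})

test_that("feeding-distance linear model behaves at its edges", {
  rec <- tibble::tibble(chick_id = sprintf("c%d", 1:40),
                        age_days = seq(40, 120, length.out = 40),
                        distance_km = 2 + 0.1 * seq(40, 120,
                                                    length.out = 40))
  # exact linear data: lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(fit_feeding_distance_model(rec))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$age_slope, 0.1, tolerance = 1e-10)
  # permuted ages destroy the relationship
  set.seed(2)
  noisy <- simulate_feeding_observations(sim_config(seed = 2))$records
  noisy$age_days <- sample(noisy$age_days)
  perm <- fit_feeding_distance_model(noisy)
  expect_lt(perm$r_squared, 0.05)
  expect_error(fit_feeding_distance_model(rec[1:2, ]), "n >= 3")
  rec$distance_km[1] <- -1
  expect_error(fit_feeding_distance_model(rec), ">= 0")
})

test_that("contact GLMM recovers a negative age slope", {
  d <- simulate_daily_contact(seed = 2)
  fit <- fit_contact_model(d, "p_contact", fixed = "age")
  expect_true(fit$converged)
  expect_lt(fit$coefficients["age_std", 1], 0)
  # k: 4 fixed (intercept, age, 2 year contrasts) + 2 sd + 1 corr
  expect_identical(fit$k, 7)
  expect_identical(fit$n, nrow(d))
  expect_equal(fit$AICc, aicc(fit$logLik, 7, nrow(d)))
})

test_that("random-effect heterogeneity can dominate the fixed effects", {
  d <- simulate_daily_contact(seed = 11, beta_age = -0.3,
                              sd_intercept = 1.2, sd_slope = 0.8)
  fit <- fit_contact_model(d, "p_contact", fixed = "age")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sds <- vc$sdcor[vc$grp == "chick_id" & is.na(vc$var2)]
  expect_gt(max(sds), abs(fit$coefficients["age_std", 1]))
})

test_that("degenerate contact data raise a clear error", {
  d <- simulate_daily_contact(seed = 3)
  d$n_contact <- 0L
  expect_error(fit_contact_model(d, "p_contact", fixed = "age"),
               "degenerate")
})

test_that("the candidate set holds all eight fixed-effect subsets", {
  d <- simulate_daily_contact(n_pairs = 8, n_days = 40, seed = 9)
  fits <- fit_candidate_set(d, response = "p_contact", random = "none")
  expect_identical(length(fits), 8L)
  labels <- vapply(fits, `[[`, character(1), "label")
  expect_identical(length(unique(labels)), 8L)
  expect_true(all(grepl("year", labels)))      # year always included
  best <- select_model(fits)
  expect_s3_class(best, "model_fit")
})

test_that("gamma distance model runs on positive distances", {
  d <- simulate_daily_contact(n_pairs = 8, n_days = 40, seed = 12)
  set.seed(1)
  d$mean_dist_nest_km <- exp(0.5 + 0.3 * d$age_std + rnorm(nrow(d), 0, 0.4))
  fit <- fit_contact_model(d, "nest_distance", fixed = "age")
  expect_gt(fit$coefficients["age_std", 1], 0)
  # k gains the Gamma shape parameter
  expect_identical(fit$k, 8)
})

test_that("pair-level random effects are an available alternative", {
  d <- simulate_daily_contact(n_pairs = 10, n_days = 40, seed = 13)
  fit <- fit_contact_model(d, "p_contact", fixed = "age", random = "pair")
  expect_true(grepl("RE:pair", fit$label))
  expect_true(is.finite(fit$AICc))
})
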