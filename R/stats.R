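# The statistical layer: feeding-count and feeding-distance models, contact
# and distance-to-nest mixed models with correlated random intercept and age
# slope, AICc model selection, and the first-year survival comparison.

#' Small-sample-corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1).
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed effects plus dispersion
#'   plus random-effect variance/correlation parameters).
#' @param n Sample size; must exceed k + 1.
#' @return The AICc value.
#' @examples
#' aicc(-10, 2, 10) # 24 + 12/7
#' @export
aicc <- function(logLik, k, n) {
  stopifnot(is.numeric(logLik), is.numeric(k), is.numeric(n))
  if (any(n <= k + 1)) {
    stop("AICc undefined for n <= k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Minimal fit-result container shared by all model-fitting operations.
.model_fit <- function(label, model, k, n, converged = TRUE,
                       extra = list()) {
  ll <- as.numeric(stats::logLik(model))
  structure(c(list(
    label = label,
    coefficients = tryCatch(
      as.data.frame(stats::coef(summary(model))), error = function(e) NULL),
    logLik = ll, k = k, n = n,
    AICc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
    converged = converged, model = model
  ), extra), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s | logLik %.2f, k %d, n %d, AICc %.2f%s\n",
              x$label, x$logLik, x$k, x$n, x$AICc,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Select the most parsimonious model by AICc
#'
#' Among converged fits whose AICc lies within 2 of the best (smallest)
#' AICc — the boundary inclusive — returns the one with the fewest
#' parameters; ties on the parameter count break towards lower AICc.
#'
#' @param results A list of `model_fit` objects.
#' @return The selected `model_fit`.
#' @export
select_model <- function(results) {
  stopifnot(is.list(results), length(results) > 0)
  ok <- vapply(results, function(r) isTRUE(r$converged) && is.finite(r$AICc),
               logical(1))
  if (!any(ok)) stop("no converged model with finite AICc", call. = FALSE)
  res <- results[ok]
  a <- vapply(res, `[[`, numeric(1), "AICc")
  k <- vapply(res, `[[`, numeric(1), "k")
  cand <- which(a <= min(a) + 2)
  pick <- cand[order(k[cand], a[cand])][1]
  res[[pick]]
}

#' Model-selection table
#'
#' @param results A list of `model_fit` objects.
#' @return A tibble sorted by AICc: label, k, logLik, AICc, dAICc and
#'   Akaike weights (converged models only).
#' @export
selection_table <- function(results) {
  if (length(results) == 0) stop("no fitted models", call. = FALSE)
  rows <- lapply(results, function(r) tibble::tibble(
    label = r$label, k = r$k, n = r$n, logLik = r$logLik, AICc = r$AICc,
    converged = r$converged
  ))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - min(tab$AICc[tab$converged], na.rm = TRUE)
  w <- exp(-tab$dAICc / 2)
  w[!tab$converged] <- NA
  tab$weight <- w / sum(w, na.rm = TRUE)
  tab
}

#' One random feeding observation per chick
#'
#' The feeding dataset holds repeat observations of the same chicks;
#' age/sex models use one randomly selected observation per chick, drawn
#' reproducibly.
#'
#' @param records Feeding-record tibble (see
#'   [simulate_feeding_observations()]).
#' @param seed RNG seed.
#' @param require Optional column that must be non-missing (e.g.
#'   `"chick_sex"` to restrict to sexed chicks) before sampling.
#' @return One row per chick.
#' @export
subsample_one_per_chick <- function(records, seed = 1L, require = NULL) {
  stopifnot(is.data.frame(records), "chick_id" %in% names(records))
  if (!is.null(require)) {
    records <- records[!is.na(records[[require]]), , drop = FALSE]
  }
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(records)), records$chick_id),
                       function(ii) if (length(ii) == 1) ii else
                         sample(ii, 1)),
                use.names = FALSE)
  records[sort(idx), , drop = FALSE]
}

#' Poisson model of feeding observations against chick age
#'
#' Tests whether the number of observed feedings declines with chick age:
#' one observation is sampled per known-age chick, ages are binned into
#' 10-day classes, and the per-class observation count is regressed on the
#' class midpoint with a Poisson GLM.
#'
#' @param records Feeding records with `chick_id` and `age_days`.
#' @param seed Seed for the one-per-chick subsample.
#' @return A `model_fit`; `$age_z` holds the Wald z of the age slope.
#' @export
fit_feeding_age_model <- function(records, seed = 1L) {
  one <- subsample_one_per_chick(records, seed)
  cls <- bin_age(one$age_days)
  counts <- as.data.frame(table(age_class = cls), stringsAsFactors = FALSE)
  counts$age_class <- as.numeric(counts$age_class)
  if (nrow(counts) < 2) {
    stop("need at least 2 age classes with observations", call. = FALSE)
  }
  fit <- stats::glm(Freq ~ age_class, family = stats::poisson(),
                    data = counts)
  z <- stats::coef(summary(fit))["age_class", "z value"]
  .model_fit("feeding_count ~ age_class (Poisson)", fit, k = 2,
             n = nrow(counts),
             extra = list(age_z = z,
                          age_slope = stats::coef(fit)[["age_class"]],
                          n_chicks = nrow(one)))
}

#' Linear model of feeding distance against chick age
#'
#' Distance from the colony at which a feeding took place, regressed on
#' chick age treated as an unbinned continuous variable.
#'
#' @param records Feeding records with `age_days` and `distance_km` (pass a
#'   one-per-chick subsample for the study design).
#' @return A `model_fit`; `$r_squared`, `$f_statistic` and `$age_slope` are
#'   attached.
#' @export
fit_feeding_distance_model <- function(records) {
  stopifnot(all(c("age_days", "distance_km") %in% names(records)))
  if (nrow(records) < 3) stop("need n >= 3", call. = FALSE)
  if (any(records$distance_km < 0)) {
    stop("distances must be >= 0", call. = FALSE)
  }
  fit <- stats::lm(distance_km ~ age_days, data = records)
  s <- summary(fit)
  .model_fit("feeding_distance ~ age (linear)", fit, k = 3,
             n = nrow(records),
             extra = list(r_squared = s$r.squared,
                          f_statistic = unname(s$fstatistic[1]),
                          age_slope = stats::coef(fit)[["age_days"]]))
}

# Build the model formula for one candidate contact/distance model.
.contact_formula <- function(response_lhs, fixed, random, with_year) {
  terms <- c(if ("age" %in% fixed) "age_std",
             if ("chick_sex" %in% fixed) "chick_sex",
             if ("parent_sex" %in% fixed) "parent_sex",
             if (with_year) "year")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  re <- switch(random,
               chick = "(1 + age_std | chick_id)",
               pair = "(1 + age_std | pair_id)",
               none = NULL)
  stats::as.formula(paste(response_lhs, "~", rhs,
                          if (!is.null(re)) paste("+", re)))
}

#' Fit a contact or distance-to-nest mixed model
#'
#' Fits one candidate model of the daily contact analysis: a binomial GLMM
#' on daily (contact, linked) counts, or a Gamma GLMM with log link on the
#' distance to the nest during contact, with correlated random variation in
#' intercept and (standardized) chick-age slope among chicks. Year is
#' always included as a fixed effect when more than one year is present;
#' interactions are never considered. Chick age is z-standardized
#' internally to ease convergence.
#'
#' @param summaries Daily summaries (from [summarise_daily()] /
#'   [pair_filter()], or [simulate_daily_contact()]). Must carry
#'   `chick_age`, `year`, and the response counts/values; `chick_sex` /
#'   `parent_sex` columns are required only when those terms are in
#'   `fixed`.
#' @param response One of `"p_contact"`, `"p_contact_beg"`,
#'   `"p_contact_forage"` (binomial on the matching counts) or
#'   `"nest_distance"` (Gamma, log link, on `mean_dist_nest_km` floored at
#'   1 m).
#' @param fixed Character subset of `c("age", "chick_sex", "parent_sex")`.
#' @param random `"chick"` (default: correlated intercept + age slope by
#'   chick), `"pair"` (the pair-level alternative), or `"none"` (a plain
#'   GLM).
#' @param with_year Include the year fixed effect (default `TRUE`; forced
#'   off when only one year level is present).
#' @return A `model_fit`. `k` counts fixed effects, random-effect standard
#'   deviations and their correlation, and (for Gamma) the shape parameter;
#'   `n` is the number of day-level rows. Non-convergence is flagged in
#'   `$converged`, not raised.
#' @export
fit_contact_model <- function(summaries,
                              response = c("p_contact", "p_contact_beg",
                                           "p_contact_forage",
                                           "nest_distance"),
                              fixed = c("age", "chick_sex", "parent_sex"),
                              random = c("chick", "pair", "none"),
                              with_year = TRUE) {
  response <- match.arg(response)
  random <- match.arg(random)
  stopifnot(all(fixed %in% c("age", "chick_sex", "parent_sex")))
  d <- as.data.frame(summaries)
  d$age_std <- (d$chick_age - mean(d$chick_age)) / stats::sd(d$chick_age)
  d$year <- factor(d$year)
  if (nlevels(d$year) < 2) with_year <- FALSE
  if (response == "p_contact") {
    d$.succ <- d$n_contact
    d$.fail <- d$n_linked - d$n_contact
  } else if (response == "p_contact_beg") {
    d$.succ <- d$n_contact_beg
    d$.fail <- d$n_linked_with_acc - d$n_contact_beg
  } else if (response == "p_contact_forage") {
    d$.succ <- d$n_contact_forage
    d$.fail <- d$n_linked_with_acc - d$n_contact_forage
  }
  gamma_resp <- response == "nest_distance"
  if (gamma_resp) {
    # Gamma support is the positive reals; floor at 1 m
    d$.dist <- pmax(d$mean_dist_nest_km, 0.001)
    d <- d[!is.na(d$.dist), , drop = FALSE]
    lhs <- ".dist"
    fam <- stats::Gamma(link = "log")
  } else {
    d <- d[!is.na(d$.succ) & !is.na(d$.fail), , drop = FALSE]
    if (sum(d$.succ) == 0) {
      stop("degenerate response: no successes on any day", call. = FALSE)
    }
    lhs <- "cbind(.succ, .fail)"
    fam <- stats::binomial()
  }
  form <- .contact_formula(lhs, fixed, random, with_year)
  label <- paste0(response, " ~ ",
                  paste(c(intersect(c("age", "chick_sex", "parent_sex"),
                                    fixed),
                          if (with_year) "year"), collapse = " + "))
  if (length(fixed) == 0 && !with_year) label <- paste0(response, " ~ 1")
  label <- paste0(label, " | RE:", random)
  converged <- TRUE
  if (random == "none") {
    fit <- stats::glm(form, family = fam, data = d)
    n_fix <- length(stats::coef(fit))
    k <- n_fix + if (gamma_resp) 1 else 0
  } else {
    fit <- withCallingHandlers(
      lme4::glmer(form, family = fam, data = d,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    n_fix <- length(lme4::fixef(fit))
    # 2 random-effect sds + 1 correlation (+ Gamma shape)
    k <- n_fix + 3 + if (gamma_resp) 1 else 0
  }
  .model_fit(label, fit, k = k, n = nrow(d), converged = converged,
             extra = list(response = response, fixed = fixed,
                          random = random, with_year = with_year))
}

#' Fit the candidate model set for one response
#'
#' All subsets of the fixed effects age, chick sex and parent sex (no
#' interactions), with year always included, giving eight candidate
#' models.
#'
#' @inheritParams fit_contact_model
#' @return A list of `model_fit`s (length 8), in decreasing order of
#'   complexity. Models that fail outright are skipped with a message;
#'   non-converged fits are kept but flagged.
#' @export
fit_candidate_set <- function(summaries, response = "p_contact",
                              random = "chick", with_year = TRUE) {
  terms <- c("age", "chick_sex", "parent_sex")
  subsets <- lapply(0:7, function(m) {
    terms[bitwAnd(m, c(1L, 2L, 4L)) > 0]
  })
  fits <- list()
  for (s in subsets) {
    f <- tryCatch(
      fit_contact_model(summaries, response, fixed = s, random = random,
                        with_year = with_year),
      error = function(e) {
        message("candidate {", paste(s, collapse = ","), "} failed: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  fits
}

#' Confidence intervals for the fixed effects of a fitted model
#'
#' Wald intervals on the fixed effects. For mixed models the normal
#' quantile badly understates uncertainty when the number of clusters is
#' small (here: 16--18 chicks), because it ignores the imprecision of the
#' estimated variance components; a t quantile with containment degrees of
#' freedom (number of random-effect groups minus number of fixed effects)
#' is used instead. Plain GLMs/LMs use their residual degrees of freedom.
#'
#' @param fit A `model_fit` (from [fit_contact_model()] and friends).
#' @param level Confidence level (default 0.95).
#' @return A data frame with `estimate`, `se`, `lower`, `upper`, `df`.
#' @export
fixed_effect_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "model_fit"))
  co <- fit$coefficients
  est <- co[[1]]; se <- co[[2]]
  df <- if (inherits(fit$model, "merMod")) {
    n_groups <- min(vapply(lme4::ngrps(fit$model), as.numeric, numeric(1)))
    max(1, n_groups - length(est))
  } else {
    stats::df.residual(fit$model)
  }
  q <- stats::qt(1 - (1 - level) / 2, df)
  out <- data.frame(term = rownames(co), estimate = est, se = se,
                    lower = est - q * se, upper = est + q * se, df = df)
  rownames(out) <- NULL
  out
}

#' First-year survival rate and comparison with a reference estimate
#'
#' Binomial survival rate of the tagged juveniles with its standard error,
#' and a two-sample z comparison against an external (mark-recapture)
#' estimate: `z = (rate - ref_rate) / sqrt(se^2 + ref_se^2)`.
#'
#' @param n_tagged Number of tagged juveniles (> 0).
#' @param n_died Number that died within the first year (0..n_tagged).
#' @param ref_rate,ref_se Reference survival rate and its standard error.
#' @return A list: `rate`, `se`, `z`, `p` (two-sided normal).
#' @examples
#' survival_comparison(15, 7, 0.56, 0.04) # rate 0.53, se 0.13, z -0.20
#' @export
survival_comparison <- function(n_tagged, n_died, ref_rate, ref_se) {
  if (!(n_tagged > 0) || n_died < 0 || n_died > n_tagged) {
    stop("need 0 <= n_died <= n_tagged and n_tagged > 0", call. = FALSE)
  }
  rate <- (n_tagged - n_died) / n_tagged
  se <- sqrt(rate * (1 - rate) / n_tagged)
  z <- (rate - ref_rate) / sqrt(se^2 + ref_se^2)
  list(rate = rate, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
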