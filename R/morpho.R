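# Morphometric and observational utilities: chick age from eighth-primary
# length, the visual sex-assignment decision rule, and 10-day age binning.

# Gompertz growth constants for the eighth primary (P8): asymptote (mm),
# growth-rate constant (1/day), inflection age (day).
.p8_asymptote <- 247
.p8_rate <- 0.095
.p8_inflection <- 19.3

#' Chick age from eighth-primary length
#'
#' Inverts the Gompertz growth curve of the eighth primary feather (P8),
#' \eqn{P8(t) = 247 \exp(-\exp(-0.095 (t - 19.3)))} (length in mm, age in
#' days), to estimate chick age at ringing:
#' \eqn{t = 19.3 - \log(-\log(P8/247)) / 0.095}.
#'
#' @param p8 Numeric vector of eighth-primary lengths in millimetres.
#'   Must lie strictly between 0 and the asymptote, 247 mm.
#' @return Numeric vector of ages in days. Real-valued; floor or bin only
#'   when an integer age class is needed (see [bin_age()]).
#' @examples
#' age_from_p8(247 / exp(1)) # inflection point: exactly 19.3 d
#' age_from_p8(c(50, 150, 214.8))
#' @seealso [p8_from_age()] for the forward curve, [bin_age()]
#' @export
age_from_p8 <- function(p8) {
  if (!is.numeric(p8) || anyNA(p8)) {
    stop("`p8` must be numeric and non-missing", call. = FALSE)
  }
  if (any(p8 <= 0) || any(p8 >= .p8_asymptote)) {
    stop("`p8` must lie strictly between 0 and the asymptote ",
         .p8_asymptote, " mm", call. = FALSE)
  }
  .p8_inflection - log(-log(p8 / .p8_asymptote)) / .p8_rate
}

#' Forward Gompertz growth curve for the eighth primary
#'
#' @param age Numeric vector of chick ages in days.
#' @return Expected eighth-primary length in millimetres.
#' @export
p8_from_age <- function(age) {
  stopifnot(is.numeric(age))
  .p8_asymptote * exp(-exp(-.p8_rate * (age - .p8_inflection)))
}

#' Bin chick age into 10-day classes
#'
#' Ages are grouped into 10-day classes labelled by the decade midpoint:
#' class 40 covers 35--44 days, class 50 covers 45--54 days, and so on.
#'
#' @param age Numeric vector of ages in days; all must be >= 35 (the
#'   post-fledging window starts at fledging, c. 35 d).
#' @return Integer vector of age-class labels (40, 50, 60, ...).
#' @examples
#' bin_age(c(35, 44, 45, 136)) # 40 40 50 140
#' @export
bin_age <- function(age) {
  if (!is.numeric(age) || anyNA(age)) {
    stop("`age` must be numeric and non-missing", call. = FALSE)
  }
  if (any(age < 35)) {
    stop("`age` below the post-fledging window (< 35 d)", call. = FALSE)
  }
  as.integer(40L + 10L * (floor((age - 35) / 10)))
}

# Situation codes carrying certain sex evidence: seen copulating (1), seen
# with partner with clear difference (2), partner molecularly sexed (5),
# incubated at night (7). Codes 3, 4 and 6 are uncertain.
.certain_codes <- c(1L, 2L, 5L, 7L)
.uncertain_codes <- c(3L, 4L, 6L)

#' Assign sex from visual resighting evidence
#'
#' Applies the field decision rule for visually sexing colour-ringed birds.
#' Each piece of evidence is a situation code 1--7 together with the sex the
#' observer claimed. Codes 1, 2, 5 and 7 count as certain identifications,
#' codes 3, 4 and 6 as uncertain. If a bird has certain identifications of a
#' single sex only, that is its sex. Otherwise, if the total number of female
#' identifications (certain and uncertain combined) differs from the total
#' number of male identifications by more than two, the majority sex is
#' assigned. In all remaining cases the sex is unknown.
#'
#' @param evidence A data frame with columns `situation_code` (integer 1--7)
#'   and `claimed_sex` (`"female"` or `"male"`). May have zero rows.
#' @return A one-row tibble: `sex` (`"female"`, `"male"` or `"unknown"`),
#'   the four evidence tallies (`n_certain_f`, `n_certain_m`,
#'   `n_uncertain_f`, `n_uncertain_m`) and `rule_fired`
#'   (`"only-certain-single-sex"`, `"majority-gt-2"` or `"unresolved"`).
#' @examples
#' assign_sex(data.frame(situation_code = 1, claimed_sex = "female"))
#' assign_sex(data.frame(situation_code = c(3, 4, 6),
#'                       claimed_sex = rep("female", 3)))
#' @export
assign_sex <- function(evidence) {
  stopifnot(is.data.frame(evidence))
  if (nrow(evidence) > 0) {
    code <- as.integer(evidence$situation_code)
    sex <- as.character(evidence$claimed_sex)
    if (anyNA(code) || !all(code %in% 1:7)) {
      stop("situation codes must be integers in 1..7", call. = FALSE)
    }
    if (!all(sex %in% c("female", "male"))) {
      stop("claimed_sex must be 'female' or 'male'", call. = FALSE)
    }
  } else {
    code <- integer(0)
    sex <- character(0)
  }
  certain <- code %in% .certain_codes
  n_cf <- sum(certain & sex == "female")
  n_cm <- sum(certain & sex == "male")
  n_uf <- sum(!certain & sex == "female")
  n_um <- sum(!certain & sex == "male")

  tot_f <- n_cf + n_uf
  tot_m <- n_cm + n_um
  if ((n_cf + n_cm) > 0 && (n_cf == 0 || n_cm == 0)) {
    out_sex <- if (n_cf > 0) "female" else "male"
    rule <- "only-certain-single-sex"
  } else if (abs(tot_f - tot_m) > 2) {
    out_sex <- if (tot_f > tot_m) "female" else "male"
    rule <- "majority-gt-2"
  } else {
    out_sex <- "unknown"
    rule <- "unresolved"
  }
  tibble::tibble(
    sex = out_sex,
    n_certain_f = n_cf, n_certain_m = n_cm,
    n_uncertain_f = n_uf, n_uncertain_m = n_um,
    rule_fired = rule
  )
}

#' Agreement between visual and molecular sexing
#'
#' Proportion of birds whose visually assigned sex (via [assign_sex()])
#' matches their molecular sex, among birds resolved by both methods.
#'
#' @param visual Character vector of visually assigned sexes
#'   (`"female"`, `"male"` or `"unknown"`).
#' @param molecular Character vector of molecular sexes, same length.
#' @return A list: `n_compared`, `n_agree`, `percent_agree` (0--100).
#' @export
sex_validation_agreement <- function(visual, molecular) {
  stopifnot(length(visual) == length(molecular))
  keep <- visual %in% c("female", "male") & molecular %in% c("female", "male")
  n <- sum(keep)
  if (n == 0) stop("no birds sexed by both methods", call. = FALSE)
  agree <- sum(visual[keep] == molecular[keep])
  list(n_compared = n, n_agree = agree, percent_agree = 100 * agree / n)
}
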