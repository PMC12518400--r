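---
title: "Methods: models, detectors and the synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, detectors and the synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fledgelink` quantifies post-fledging parental care in colony-breeding
waterbirds from dyadic GPS tracking, acceleration-based behaviour
classification and colour-ring feeding resightings. This vignette records
the modelling choices, the numerical details, and — because every stage is
validated against simulated data — exactly what the synthetic-data
generator does and does not emulate.

## Ageing chicks from feather growth

Chick age is needed both to window the analysis (35–136 d) and as the
central covariate. The eighth primary (P8) grows along a Gompertz curve

$$P8(t) = 247\,\exp(-\exp(-0.095\,(t - 19.3)))$$

with length in mm, age $t$ in days, asymptote 247 mm, growth constant
0.095 d$^{-1}$ and inflection at 19.3 d. `age_from_p8()` inverts it:

$$t = 19.3 - \ln(-\ln(P8/247))/0.095 .$$

Ages are kept real-valued; they are floored only when a day-level integer
age is needed, and binned only for the feeding-count model (10-day classes
labelled by the decade midpoint: 40 = 35–44 d, 50 = 45–54 d, …). The
inversion is exact: the round trip through the forward curve is accurate
to $10^{-9}$ days across the whole growth period, and lengths at or beyond
the asymptote are rejected rather than truncated.

## Visual sex assignment

Resighting evidence carries a situation code 1–7. Codes 1 (copulating),
2 (partner with clear size difference), 5 (partner molecularly sexed) and
7 (incubating at night) are *certain*; 3, 4 and 6 are *uncertain*. The
decision rule in `assign_sex()`:

1. certain identifications of a single sex only → that sex;
2. otherwise, if total female and male identifications (certain and
   uncertain pooled, equally weighted) differ by more than two → the
   majority sex;
3. otherwise unknown.

When certain identifications of *both* sexes exist the rule falls through
to step 2 — the literal reading of "in all other cases". The rule is
permutation-invariant in the evidence list.

## Trajectory segmentation

All distances are great-circle on the mean-radius sphere
(R = 6371.0088 km); at the 10-m scale of contact detection the spherical
error is far below GPS error, so no projection is used anywhere.

* **Flight bout** — a maximal run of consecutive GPS intervals whose
  average speed (displacement / elapsed time) is **at least** 5 km/h.
  Speeds are computed from positions, not from the logger's instantaneous
  speed field, which is kept only as a classification feature (robust to
  speed-field dropout). Intervals longer than 30 min (configurable) break
  bouts so sparse post-departure data cannot be stitched into one.
* **Departure day** — the first calendar day (UTC; a fixed offset is
  available, though the study system spans a single timezone) on which the
  bird moved **more than** 100 km between the day's first and last fix, in
  southward direction, and ended **more than** 50 km south of the colony.
  "Southward" is tested on the latitude sign; the 100-km displacement is
  geodesic by default, with a pure-latitudinal variant behind a switch
  since the original phrasing mixes both readings. Strict inequalities for
  "more than", inclusive for "at least", throughout.
* **Departure moment** — among flight bouts with net displacement
  ≥ 30 km starting on the departure day *or the preceding day* (birds
  sometimes leave in the evening), the earliest; the moment is the
  timestamp of the fix immediately preceding that bout's first fix. If no
  bout qualifies, the day- and moment-level rules are inconsistent for
  that track and an error names the situation rather than dropping it.

## Linking chick and parent

Linkage is chick-anchored: every chick fix is paired with the parent fix
nearest in time (ties go to the earlier fix, for determinism; one parent
fix may serve several chick fixes, since post-departure parent data are
coarse). A linked fix is retained when |Δt| < 10 min, or — regardless of
Δt — when the parent has departed while the chick has not: then it is
certain the two were not together, and the fix contributes a no-contact
observation. Contact is distance **strictly below** the threshold: 10 m
primary, 50 m sensitivity; p(contact at 50 m) ≥ p(contact at 10 m) holds
day by day, by construction.

Daily summaries keep days with ≥ 130 linked fixes (of 144 possible at the
10-min cadence) for overall contact and ≥ 100 acceleration-complete linked
fixes for behaviour-specific contact; pairs need ≥ 10 qualifying days and
only pre-departure chick data are used. The 35–136 d age window is applied
*before* the day-completeness filters; the order is exposed as arguments
because the original description does not fix it (with near-complete days
the two orders differ only for days straddling the window edges).
Behaviour-specific proportions divide begging-in-contact (or
foraging-in-contact, after pooling search/handle/ingest) by the day's
acceleration-complete linked fixes. Distance-to-nest summaries use contact
fixes only.

After both birds have migrated, 10 m is meaningless at 1–6 h fix
intervals, so `post_departure_proximity()` screens nearest-fix pairs
within 25 km for review instead.

## Behaviour classification

Bursts (1.6 s at 20 Hz) are cut into non-overlapping segments of 0.4, 0.8
or 1.6 s; truncated bursts contribute only full segments. The feature set
is frozen and documented in `featurize()`: per-axis mean, sd, min, max,
skewness, kurtosis; per-axis dominant spectral frequency and its
normalized peak power (Hann window, zero-padding to 512 samples for
sub-bin resolution, bins below 0.3 Hz excluded so slow trends cannot pose
as behavioural rhythms); pairwise axis correlations (defined 0 for
constant axes); overall dynamic body acceleration; and GPS speed. Means,
minima and maxima shift under a constant offset of all axes; every other
feature is invariant.

The classifier is a random forest (500 trees, seeded, single-threaded for
reproducibility) with inverse-frequency class weights — begging is by far
the rarest class in any field training set, and without weighting the
forest happily ignores it. Evaluation uses the per-class F-measure
(harmonic mean of precision and recall, 0 when both are 0) after pooling
forage = {search, handle, ingest}, rest = {sit, stand},
fly = {fly-active, fly-passive}; walk and beg stay unpooled. Train/test
splits are stratified by class at the *burst* level so segments of one
burst never sit on both sides. Finally, because walking is persistently
confused with foraging, foraging classifications at fixes outside foraging
habitat (freshwater, brackish or marine polygons; point-in-polygon by ray
casting on raw coordinates) are rewritten to walking; fixes outside map
coverage count as land by default and are reported.

## Statistical models

* **Feeding counts** — one randomly selected observation per known-age
  chick (seeded subsample), counts per 10-d age class, Poisson GLM of
  count on class midpoint.
* **Feeding distance** — ordinary linear model of distance from the colony
  on exact (unbinned) age; slope, $R^2$ and F reported.
* **Contact and distance to nest** — generalized linear mixed models on
  day-level aggregates: binomial (successes = contact fixes,
  trials = linked fixes) for the three contact responses, Gamma with log
  link for distance to the nest during contact (floored at 1 m, since
  Gamma support is the positive reals; the floor is logged in the docs,
  applied in code). All models carry correlated random variation in
  intercept and age slope among chicks (a pair-level alternative is
  available), a year fixed effect always, and never interactions. Chick
  age is z-standardized internally to ease convergence. Day-level
  aggregation, rather than fix-level Bernoulli, matches the
  "proportion of time per day" unit of the analysis and its filters.

Model support uses AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1). k counts every
estimated parameter: fixed effects, the two random-effect standard
deviations, their correlation, and the Gamma shape where applicable —
necessary for comparability across random structures. n is the number of
day-level rows; whether the effective sample size of such a mixed model is
days or chicks is genuinely ambiguous, and the day-level choice is flagged
here. The most parsimonious model is the fewest-parameter model within
2 ΔAICc of the best, boundary inclusive, ties broken by lower AICc;
non-converged fits are flagged and excluded from selection.

Fixed-effect confidence intervals (`fixed_effect_ci()`) use a t quantile
with containment degrees of freedom (number of random-effect groups minus
number of fixed effects) instead of the normal quantile: with 16–18 chicks
the normal-based Wald interval ignores the imprecision of the variance
components and undercovers noticeably. This was verified by simulation
(coverage of the age slope and year contrasts rises from ~0.83–0.87 to
~0.92–0.95 at 16 pairs × 70 days).

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which the pipeline is validated.

**Movement.** Birds roost near the colony (roost drawn within a few
hundred metres of the nest) and make up to two daily foraging trips of
2–6 km, flown at 15–30 km/h — routinely exercising the 5 km/h bout
threshold. Migration starts at a departure age drawn uniformly from
108–139 d (parents: 80–130 d on the chick-age scale), between 08:00 and
14:00 UTC, and proceeds in hourly legs at 40–60 km/h heading south with
8° heading jitter, ~10 h on the first day — so the 100 km/50 km day rule
is satisfiable on the true departure day. One family optionally departs
jointly (chick and parent in the same hour, parent flying the chick's
route offset by ~2 km) to exercise joint-departure screening.

**Sampling.** Fixes every 10 min with ±30 s independent timestamp jitter
per bird (chick and parent timestamps never coincide, exercising
nearest-timestamp linkage), 3% random dropout (the plausible range for
this tracker family is 2–10%; at 3%, typical days clear the 130-fix filter
the way real near-complete days did), and GSM-mode thinning to one fix per
1–6 h from the end of the departure day — within antenna range (i.e. until
departure) all 10-min fixes are assumed downloaded. Positional error is
parameterized as the 2-D RMS error of a fix, default 3 m (per-axis sd
3/√2); no authoritative value exists for this tracker, so it is a config
parameter, not an assertion.

**Contact.** At each chick fix while both birds are pre-departure, a
contact episode occurs with probability
logistic(baseline + decay·(age − 35) + year effect); defaults
(baseline −2.2, decay −0.03 d⁻¹, year offsets 0 / −1.5 / +0.5) put
per-fix contact near 10% at fledging falling to ~2% at 90 d, with strong
between-year differences. During an episode the parent's true position is
the chick's plus a 0.2–2 m offset — birds standing next to each other at
body-length scale; with 3 m RMS GPS error on both positions this leaves
the 10 m detector a <1% miss rate, consistent with episode-recovery
checks. Outside episodes the parent is kept at least 50 m away.

**Behaviour and acceleration.** Behaviour labels are drawn iid from
configured class frequencies, *independent of contact state* — a
deliberate simplification that keeps the frequency-recovery property exact
but means simulated begging is not concentrated at contact moments.
Acceleration signatures are generative constants per class
(`acc_signature_table()`): begging is a slow (0.7–1.6 Hz) large surge-and-
heave oscillation, walking 1.4–2.6 Hz and smaller, searching
sway-dominated at 1.2–2.4 Hz, active flight 3.8–5.2 Hz heave-dominated;
postures separate sitting/standing; ingestion is a short spike train; GPS
speed separates flight from everything else. Frequency bands deliberately
overlap (beg/walk share 1.4–1.6 Hz) and amplitudes jitter ±60% at the
default noise multiplier, so classes are separable but overlapping: on
held-out data begging F rises from ~0.75–0.86 (0.4 s segments) through
~0.83–0.94 (0.8 s) to ~0.93–0.97 (1.6 s) — short windows cannot resolve
the slow begging rhythm — while pooled rest/fly and searching stay above
0.93. At noise multiplier 0 every stochastic component collapses and a
nearest-centroid rule is already perfect, a degenerate-separability check.
About 5% of bursts are truncated, mimicking incomplete downloads.

**Feeding observations.** Per-chick resightings with observation ages
drawn from an exponentially tilted distribution over 35–136 d (default
slope −0.035 d⁻¹, a strong decline), feeding distance increasing with age
(0.12 km/d over a 5 km residual sd), 20% unringed parents, and visual
sex-evidence codes with a 5% error rate.

**The day-level shortcut.** Recovery studies for the binomial GLMM need
hundreds of fits at the study's scale (16 pairs × ~70 days). For these,
`simulate_daily_contact()` draws daily (contact, linked) counts directly
from the mixed model's data-generating process — correlated random
intercept and slope, year effects, ~135 trials per day — rather than
running the full track simulator hundreds of times. The full simulator
backs the detector-recovery and end-to-end checks at smaller replication.

**What the generator does not emulate.** Tidal and weather drivers of
movement, energetics, multi-colony structure, contact-dependent begging
(above), northward spring migration, stopover behaviour, and habitat
selection. Passing tests therefore demonstrate correctness of the
*pipeline* under a movement and sampling model with the study's
statistical structure, not field realism of spoonbill behaviour.

## Numerical choices and degenerate inputs

* Nearest-timestamp ties resolve to the earlier fix (determinism).
* A chick with no contact ever yields `NA` from `last_contact_age()` — a
  valid none-result, distinct from an error.
* F-measure is 0 when precision + recall = 0; skewness/kurtosis of a
  constant axis are 0; axis correlations with a constant axis are 0.
* AICc is undefined (error) for n ≤ k + 1; model selection refuses empty
  or all-non-converged candidate sets.
* Zero-contact datasets raise a degenerate-response error before any GLMM
  is attempted.
* Distance floors: Gamma responses at 1 m; simulated feeding distances at
  100 m.

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to keep the full suite fast
while preserving the study's structure: 2–5 families for track-level
checks, two replicate simulations (10 families total) for
detector-recovery rates, 100 replicates of 16 pairs × 70 days for GLMM
recovery, 1000 random instances per brute-force oracle comparison, and
125–1000 labelled bursts per class for classifier evaluation (the larger
size in the acceptance script, the smaller in the routine suite).

## Known limitations

* The parent-sex effect in real data of this kind hinges on the few
  families where both parents carry trackers; the pair-level random-effect
  option exists precisely because chick- vs pair-level clustering changes
  that inference.
* Begging annotation in the field came from very little reference
  material; the synthetic begging signature is a modelling choice, not a
  measured waveform, and classifier scores on synthetic data bound what
  the pipeline can do, not what field data deliver.
* Drinking and prey-handling are known to classify poorly in this system;
  nothing here improves that, and per-event detection of actual
  feed-the-chick moments (seconds-long, a few times a day) is out of
  scope.
* The habitat correction is only as good as the habitat polygons; points
  outside coverage default to land.
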