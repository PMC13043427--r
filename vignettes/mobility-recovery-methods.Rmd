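---
title: "Methods: smartphone mobility phenotyping of post-operative recovery"
author: "mobiphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone mobility phenotyping of post-operative recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After surgical decompression for cervical myelopathy, recovery is usually
assessed at sparse follow-up visits with questionnaires (VAS for pain, mJOA,
ODI, NDI). Passive smartphone sensing offers a continuous, objective
complement: duty-cycled GPS (1 minute on per 5) and tri-axial accelerometry
(10 s on per 10 s) collected by the patient's own phone can be reduced to
five daily mobility variables — distance traveled, significant location
count, significant location entropy, home duration, and steps — and those
variables can be analyzed for week-over-week improvement, arm-specific
recovery trajectories, and concordance with the questionnaires.

`mobiphen` implements that full chain: raw trace ingestion, trajectory
segmentation, daily summarization, a cleaning ladder, and the three
analyses, together with a calibrated synthetic-cohort generator that
provides raw sensor streams with known ground truth.

## Daily mobility variables

**Pauses and flights.** A *pause* is a maximal run of (epoch-averaged)
positions that stay within a radius (default 50 m) of the run's running
centroid for at least a minimum duration (default 300 s). The segments
between pauses are split wherever the heading changes by more than a
threshold (default 30°); each resulting straight sub-segment is a *flight*,
and daily distance is the sum of flight lengths (haversine geometry on the
WGS84 mean radius, never a projected CRS). Positions are averaged over 10-s
epochs before segmentation; this suppresses per-fix GPS noise by roughly
the square root of the burst rate and keeps per-fix jitter from
masquerading as directional changes (a 5-m minimum vertex displacement
guards the heading computation for the same reason). Pauses are split at
observation gaps longer than 15 minutes, so sensor outages are never
counted as dwell; ordinary duty-cycle gaps (4 minutes) are bridged.

**Significant locations.** Pauses of at least 15 minutes from a patient's
entire follow-up are clustered by duration-weighted k-means (seeded
k-means++, 10 restarts) over their centroids, growing k until every pause
lies within half the separation threshold (default 50 m) of its center —
so that pause groups more than 50 m apart resolve into distinct locations
while closer groups merge. This k-selection rule is a design choice: the
concept ("distinct pauses at least 15 min long and 50 m apart, clustered by
k-means") does not determine an algorithm, and the radius-of-half-separation
criterion is the one that makes cluster centers provably at least the
separation apart on well-separated data. *Home* is the significant location
with the most pause time inside the 20:00–08:00 local-time windows over the
whole follow-up (ties: larger all-day dwell, then smaller id).

**Occupancy and entropy.** For each day, pause seconds are attributed to
the nearest significant location within the separation radius, giving
occupancies $p_i$ normalized over the day's observed significant-location
dwell, and the entropy $-\sum_{p_i>0} p_i \ln p_i$ (natural log; nats). The
normalization is deliberate: with home duration around 14.6 h the
*unnormalized* day-fraction share of home alone would contribute
$-0.61\ln 0.61 \approx 0.30$ nats on every day, which is incompatible with
week-level entropy means near 0.10; normalized occupancy makes a
stay-at-home day have entropy exactly 0 and matches the scale of the
reference values. The day's location count is the number of locations with
any dwell that day — any observed pause time at a known significant
location counts as a visit, whether or not that particular pause reached 15
minutes.

**Steps.** The accelerometer magnitude $\sqrt{x^2+y^2+z^2}$ (orientation
invariant) is band-passed (Butterworth order 2, 0.5–3 Hz) per 10-s burst
and peaks above 0.1 g separated by at least 0.3 s are counted as steps.
Daily steps are the raw sum over bursts; because the duty cycle observes
half the time, the raw sum captures about half the steps actually taken. An
`extrapolate` switch rescales by period/on-time; it is off by default
because the reference step magnitudes are raw duty-cycled counts, and the
validation suite compares extrapolated counts against ground truth instead.

## Cleaning ladder

In order: (1) censor observations beyond post-operative day 70; (2) exclude,
per patient, any variable with *strictly more than* 50% missing days —
excluded cells are never imputed; (3) multiple imputation by chained
equations with random-forest conditional models (each variable regressed on
the other four, post-operative day, and surgical approach; a random tree's
prediction is drawn per missing cell to preserve between-imputation
variability; 5 datasets × 50 iterations, fixed seed); (4) consolidation by
cell-wise mean (rounded for integer variables) — pooling data rather than
estimates, so Rubin's rules do not apply; (5) automated univariate outlier
removal by Tukey fences with $k = 3$ (a reproducible surrogate for
graphical inspection; a zero-IQR variable never flags anything); (6)
$\log(x+1)$ companion columns for the right-skewed variables (distance,
steps, entropy) — the offset admits zero days. Observed cells pass through
the ladder bit-identical; provenance records every exclusion, imputed cell
and removed outlier, and a second pass over the ladder's own output is the
identity as long as the outlier step is stable.

## Analyses

*Week comparison.* Weeks are calendar weeks from surgery (week 1 = days
1–7, week 5 = days 29–35). Raw-scale means with t-based 95% CIs; the
two-sided Wilcoxon rank-sum test on the pooled patient-day values (the rank
test is invariant to the log transform, so raw values are used).

*Recovery trajectories.* GLMs of each variable on
`PostopDay * SurgeryApproach`: gamma with log link for distance, home
duration and entropy (log link kept for a uniform linear-predictor
interpretation; zeros receive a configurable offset of 0.01, logged);
Poisson with log link for count and steps; homoscedastic gaussian available
as the unifying baseline. Days are treated as independent within patients —
faithful to the analysis being reproduced, not a general recommendation; a
mixed model would be the better default elsewhere.

*PROM concordance.* Daily VAS pairs with the same patient-day; weekly
instruments pair with the trailing 7-day mean of the mobility variable
(the pairing window is a design choice — response dates summarize the week
just lived). Pearson r with two-sided t-tests on all 20 pairs,
Benjamini–Hochberg adjustment across the 20 tests (BH chosen where only
"FDR" is specified), α = 0.05. Pairs with fewer than 3 observations are
not estimable.

## The synthetic cohort

The generator works schedule-first. Each patient-day draws: a number of
away-place visits (stratified binomial with logit-linear propensity), a
common dwell time per visit (log-linear trajectory, lognormal day
multiplier, floored at 27 minutes so every visit survives the 15-minute
qualification), a distance budget (log-linear, lognormal noise), a short
walking bout (the only step source), and an observed-home-hours target
(linear trajectory). Distance beyond the visit round-trips is realized as a
vehicle errand loop with a 6-minute stop at the turnaround — long enough to
guarantee a GPS fix at the corner, short enough never to become a
significant location. Sensor outage blocks carved out of home intervals
make observed home duration equal its target: a phone that is stationary
and idle for hours a day is a documented property of real smartphone GPS
streams, and it is the only way a mostly-home patient can show ~14.6
observed home hours. Ground truth (exact haversine path length, observable
occupancies, steps = cadence × walking seconds) is computed from the
schedule, not from the rendered sensors, and the generator's entropy is
written out as its own formula so extractor and generator share no code on
that path.

Calibration inverts week-level targets into day-level curves exactly
(log-linear/linear curves solved against week means; the dwell curve solved
through the binomial-mixture entropy expectation with Gauss–Hermite
quadrature over the dwell noise). Arm-specific targets give the anterior
arm higher initial levels and steeper recovery for home duration, steps and
count, with shared distance trajectories and pooled means equal to the
overall targets. The home-duration arm split (anterior decreasing
15.13→13.29 h, posterior increasing 14.20→14.70 h) and the day-level
home-hours noise (SD 0.35 h) were chosen so that the pooled means, the
confidence-interval placement *and* a rank-sum p below 0.001 are
simultaneously achievable — the reference CIs imply a much larger spread
under which that p-value would be unreachable for a 0.6 h shift, an
inconsistency the generator resolves in favor of the printed means and
p-values.

PROMs are linear in the log of the linked true mobility value (daily
distance for VAS; trailing-week steps for mJOA; trailing-week distance for
ODI and NDI), anchored at week-1/week-5 scores (VAS 5→2.8, mJOA 13.2→13.7,
ODI 40→17, NDI 28.4→16.9), rounded and truncated to each instrument's
native scale. The noise SD is solved so the correlation between the
*recorded* (rounded, truncated) score and the raw-scale mobility value hits
the target (VAS–distance −0.358, mJOA–steps 0.403, ODI–distance −0.409,
NDI–distance −0.279); the noise is drawn orthogonal to the linked mobility
value so the realized sample correlation is pinned by the calibration
rather than floating with the draw. Correlation targets are interpreted
pre-truncation in spirit but solved post-truncation in practice, which is
what the analysis actually measures.

What the generator does *not* emulate: street networks (transits are
straight lines), travel-mode mixtures (walking bouts and vehicle errands
only), point-level missingness (day-level MCAR only, default 8%), device
heterogeneity, and realistic step totals — the reference step scale
(~109–250/day) is far below typical daily totals and is reproduced as
printed without asserting real-world plausibility. Stationary
accelerometer bursts are thinned to 2% in the output stream (they carry no
steps by construction, and full retention would be pure dead weight);
active bursts are always kept. Passing the validation suite therefore
shows the estimators recover the truth under these idealized conditions,
not that they are robust to urban canyons, mode confusion or informative
missingness.

## Numerical choices and degenerate inputs

Haversine on radius 6371.0088 km throughout; equirectangular projection to
local meters only inside the clustering step. Empty GPS days yield
all-missing rows (not zeros); a day with under 10% of expected on-windows
observed is treated as missing. Days with no accelerometer bursts yield
missing steps. k-means is seeded and restarted 10 times for determinism;
ties in home detection break by all-day dwell then id. The chained imputer
refuses a variable with no observed values anywhere. Gamma fits refuse
non-positive data unless the zero offset is enabled (it is, at 0.01, by
default). Wilcoxon p-values use the exact distribution where R's
implementation provides it (small samples without ties) and the normal
approximation otherwise.

## Problem sizes used in validation

The validation suite runs the full default cohort (13 patients × 70 days,
~12 million GPS fixes) once and reuses it across checks; GLM recovery uses
200 replicates at 900 patient-days; the null-calibration and
flat-trajectory checks use truth-level simulation only (no sensor
rendering), which is about two orders of magnitude faster and exercises the
same schedule draw. These sizes were chosen to keep the whole suite in the
tens of minutes while leaving every statistical tolerance comfortably
non-marginal.

## Known limitations

Independence across days within patients is assumed by all three analyses,
as in the analysis being reproduced. The flight algorithm is one concrete
realization of a concept description; equivalence with any particular
platform's segmentation is not claimed. Step counts from a pocket phone are
proxies; no spatial gait analysis is attempted. The entropy normalization
and the weekly-PROM pairing window are documented interpretations of
under-specified definitions.
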