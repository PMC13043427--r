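# mobiphen

Smartphone digital phenotyping of post-operative mobility recovery.

After surgery for cervical myelopathy, recovery is conventionally tracked
with sparse questionnaires (VAS pain, mJOA, ODI, NDI). A patient's own
smartphone, sampling GPS for 1 minute in every 5 and the accelerometer for
10 s in every 10, provides a continuous behavioral record instead.
`mobiphen` turns those raw duty-cycled streams into five daily mobility
variables and reproduces the three analyses of a post-surgical
digital-phenotyping study design on them:

1. **Feature extraction.** GPS fixes are epoch-averaged and segmented into
   *pauses* (runs within 50 m of a running centroid for ≥ 5 min) and
   *flights* (straight segments split at > 30° heading changes). Daily
   **distance traveled** is the sum of flight lengths. Pauses ≥ 15 min are
   clustered per patient (seeded, duration-weighted k-means) into
   **significant locations** ≥ 50 m apart; **home** is the location holding
   the most 20:00–08:00 dwell. Daily occupancies p_i over the observed
   significant-location dwell give the **location count** and the
   **entropy** −Σ p_i ln p_i (nats). **Steps** are threshold peaks of the
   band-passed (0.5–3 Hz) accelerometer magnitude, summed over bursts.
2. **Cleaning ladder.** Censoring at post-operative day 70; per-patient
   exclusion of any variable > 50% missing; chained random-forest multiple
   imputation (5 datasets × 50 iterations, fixed seed) consolidated by
   cell-wise mean; Tukey-fence outlier removal (k = 3); log(x+1) columns
   for the skewed variables.
3. **Analyses.** Week-1 vs week-5 means with Wilcoxon rank-sum tests;
   gamma/Poisson log-link GLMs of each variable on
   `PostopDay * SurgeryApproach`; Pearson correlation of the five variables
   with the four PROMs (daily VAS paired by day, weekly instruments paired
   with the trailing 7-day mean) under Benjamini–Hochberg FDR control.

Because the underlying patient data are not deposited anywhere, the package
ships a calibrated synthetic-cohort generator (`simulate_cohort()`): 13
patients (6 anterior / 7 posterior approach), 70-day follow-up, raw sensor
streams rendered from daily schedules whose ground truth is known exactly.
Its defaults are calibrated so that the extracted cohort reproduces the
reference week-1/week-5 means and PROM correlations through the full
pipeline. See the methods vignette
(`vignettes/mobility-recovery-methods.Rmd`) for the model, the calibration,
and the design decisions.

## Worked example

```r
library(mobiphen)

res <- run_study(seed = 1)   # simulate -> extract -> preprocess -> analyze
res$weeks[, .(variable, mean_a = round(mean_a, 2), mean_b = round(mean_b, 2),
              p = signif(p, 2))]
```

```
          variable  mean_a  mean_b       p
1:     distance_km    3.08   13.48 1.7e-30
2:      home_hours   14.34   13.70 4.7e-06
3:   sig_loc_count    1.38    2.44 2.8e-15
4: sig_loc_entropy    0.11    0.25 2.7e-08
5:           steps  111.39  258.31 1.7e-23
```

Reading: over the five weeks after surgery the simulated cohort's daily
distance rises from ~3 km to ~13.5 km and raw duty-cycled steps from ~111
to ~258 per day, locations visited and entropy increase, and home time
falls by ~0.6 h — all week-1 vs week-5 differences significant by rank-sum
test. Correlations with the questionnaires:

```r
res$correlations[instrument == "VAS" & variable == "distance_km"]
#>    variable instrument      r     p p_adj   n estimable
#> distance_km        VAS -0.370 2e-16 4e-15 460      TRUE
```

Higher daily pain scores go with shorter distances traveled (r ≈ −0.37
over ~460 paired patient-days).

The per-stage functions are exported too: `read_cohort()` /
`simulate_cohort()` → `extract_daily_summaries()` → `preprocess_daily()` →
`week_comparison()` / `fit_recovery_glm()` / `correlate_proms()`. A thin
command-line front end with `simulate`, `extract`, `preprocess`, `analyze`
and `run-all` subcommands lives in `inst/cli/mobiphen`.

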