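# End-to-end convenience driver: simulate (or load) a cohort, extract the
# daily mobility summaries, run the cleaning ladder, and compute the three
# study analyses.

#' Run the full recovery-analysis pipeline
#'
#' With the default arguments this simulates the calibrated 13-patient
#' cohort, extracts daily mobility summaries from the raw duty-cycled
#' sensor streams, applies the cleaning ladder, and produces the
#' week-1/week-5 comparison, the five recovery-trajectory GLMs and the
#' PROM correlation table.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param cohort an existing `mobiphen_cohort`; when `NULL`, one is
#'   simulated from `cohort_cfg`.
#' @param cohort_cfg a [cohort_config()] (used when `cohort` is `NULL`).
#' @param config a [run_config()]; its seed is tied to `seed` unless
#'   supplied explicitly.
#' @return list with `cohort`, `summaries`, `analytic`, `weeks`
#'   (week comparison), `glms` (named list), `correlations`.
#' @export
run_study <- function(seed = 1L, cohort = NULL,
                      cohort_cfg = cohort_config(),
                      config = run_config(seed = seed)) {
  if (is.null(cohort)) cohort <- simulate_cohort(cohort_cfg, seed = seed)
  summaries <- extract_daily_summaries(cohort, config)
  analytic <- preprocess_daily(summaries, cohort$patients, config)
  weeks <- week_comparison(analytic)
  glms <- lapply(setNames(nm = .MOBILITY_VARS), function(v)
    fit_recovery_glm(analytic, v, family = "auto",
                     gamma_offset = config$gamma_offset))
  correlations <- correlate_proms(analytic, cohort$proms, cohort$patients,
                                  fdr_method = config$fdr_method)
  list(cohort = cohort, summaries = summaries, analytic = analytic,
       weeks = weeks, glms = glms, correlations = correlations)
}
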