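# The three study objectives on the analytic dataset: week-1 vs week-5
# comparison (raw-scale means with t-based CIs; two-sided Wilcoxon rank-sum,
# which is invariant to the monotone log transform), generalized linear
# recovery trajectories with a Postop Day x Surgery Approach interaction
# (gamma log-link for distance/home/entropy, Poisson log-link for count and
# steps, gaussian as the unifying baseline), and Pearson correlation of
# mobility with patient-reported outcomes under Benjamini-Hochberg FDR
# control. Days are treated as independent within patients, matching the
# study's tests.

.FAMILY_MAP <- c(distance_km = "gamma", home_hours = "gamma",
                 sig_loc_entropy = "gamma",
                 sig_loc_count = "poisson", steps = "poisson")

.t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Compare mobility between two post-operative weeks
#'
#' Post-operative week `w` spans days `7(w-1)+1` to `7w`. For each
#' mobility variable the raw-scale means with t-based 95% CIs and the
#' two-sided Wilcoxon rank-sum p-value over the pooled patient-day values
#' are reported.
#'
#' @param dataset analytic table ([preprocess_daily()]).
#' @param week_a,week_b week indices (defaults 1 and 5).
#' @return a `data.table`, one row per variable: means, CI bounds, `p`.
#' @export
week_comparison <- function(dataset, week_a = 1, week_b = 5) {
  dataset <- as.data.table(dataset)
  days_a <- .WEEK_DAYS(week_a); days_b <- .WEEK_DAYS(week_b)
  rows <- lapply(.MOBILITY_VARS, function(v) {
    xa <- dataset[postop_day %in% days_a][[v]]
    xa <- xa[!is.na(xa)]
    xb <- dataset[postop_day %in% days_b][[v]]
    xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2)
      stop("week_comparison: week ", if (length(xa) < 2) week_a else week_b,
           " has fewer than 2 observations for ", v)
    cia <- .t_ci(xa); cib <- .t_ci(xb)
    p <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))$p.value
    data.table(variable = v,
               mean_a = cia[1], lower_a = cia[2], upper_a = cia[3], n_a = length(xa),
               mean_b = cib[1], lower_b = cib[2], upper_b = cib[3], n_b = length(xb),
               p = p)
  })
  rbindlist(rows)
}

#' Fit a recovery-trajectory GLM
#'
#' Maximum-likelihood fit of
#' `mean(variable) = g^-1(b0 + b1 PostopDay + b2 Approach + b3 PostopDay:Approach)`.
#' Families: `"gamma"` (log link; zeros receive a configurable positive
#' offset, logged in the result), `"poisson"` (log link) or `"gaussian"`;
#' `"auto"` uses the study's family map (distance/home/entropy gamma,
#' count/steps Poisson).
#'
#' @param dataset analytic table carrying `approach`.
#' @param variable mobility variable name.
#' @param family `"auto"`, `"gaussian"`, `"gamma"` or `"poisson"`.
#' @param gamma_offset offset added to non-positive values under the gamma
#'   family.
#' @return an object of class `mobiphen_glm`: the `stats::glm` fit plus a
#'   coefficient table (`estimate`, `se`, `p`) and a per-arm trajectory
#'   evaluator `predict_arm(arm, days)`.
#' @export
fit_recovery_glm <- function(dataset, variable, family = "auto",
                             gamma_offset = 0.01) {
  dataset <- as.data.table(dataset)
  if (!variable %in% names(dataset)) stop("unknown variable ", variable)
  if (identical(family, "auto")) family <- .FAMILY_MAP[[variable]]
  dd <- dataset[!is.na(get(variable)),
                .(y = as.numeric(get(variable)), postop_day,
                  approach = factor(approach,
                                    levels = c("anterior", "posterior")))]
  n_offset <- 0L
  fam <- switch(family,
    gaussian = gaussian(),
    poisson = poisson(link = "log"),
    gamma = {
      nz <- dd$y <= 0
      n_offset <- sum(nz)
      if (n_offset) {
        dd[nz, y := y + gamma_offset]
        .log_msg("fit_recovery_glm: offset %d zero value(s) of %s by %g",
                 n_offset, variable, gamma_offset)
      }
      Gamma(link = "log")
    },
    stop("unknown family ", family))
  fit <- glm(y ~ postop_day * approach, data = dd, family = fam)
  if (!fit$converged)
    stop("fit_recovery_glm: IRLS did not converge for ", variable,
         " (", fit$iter, " iterations)")
  sm <- summary(fit)$coefficients
  coefs <- data.table(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4])
  structure(list(
    variable = variable, family = family, fit = fit, coefficients = coefs,
    n_offset = n_offset,
    predict_arm = function(arm, days) {
      nd <- data.frame(postop_day = days,
                       approach = factor(arm, levels = c("anterior", "posterior")))
      as.numeric(predict(fit, nd, type = "response"))
    }), class = "mobiphen_glm")
}

#' @export
print.mobiphen_glm <- function(x, ...) {
  cat("<recovery GLM>", x$variable, "~ postop_day * approach, family",
      x$family, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Correlate mobility variables with patient-reported outcomes
#'
#' Daily VAS scores pair with the same patient-day mobility value; weekly
#' instruments (mJOA, ODI, NDI) pair with the patient's mean mobility over
#' the 7 days ending on the response date. Each of the 5 x 4 pairs gets a
#' Pearson r with a two-sided t-test p, adjusted across all tests by
#' Benjamini-Hochberg (or the configured method). Pairs with fewer than 3
#' complete observations are marked not estimable. All available
#' non-missing PROM observations are used.
#'
#' @param dataset analytic table.
#' @param proms PROM long table ([read_proms_csv()] schema).
#' @param patients patient metadata (for surgery dates).
#' @param fdr_method adjustment method tag for [stats::p.adjust()].
#' @return a `data.table`: `variable`, `instrument`, `r`, `p`, `p_adj`,
#'   `n`, `estimable`.
#' @export
correlate_proms <- function(dataset, proms, patients, fdr_method = "BH") {
  dataset <- as.data.table(dataset)
  proms <- as.data.table(proms)
  patients <- as.data.table(patients)
  proms <- merge(proms, patients[, .(patient_id, surgery_date)],
                 by = "patient_id")
  proms[, postop_day := as.integer(as.Date(date) - as.Date(surgery_date))]
  rows <- list()
  for (ins in c("VAS", "mJOA", "ODI", "NDI")) {
    pr <- proms[instrument == ins]
    for (v in .MOBILITY_VARS) {
      if (ins == "VAS") {
        mm <- merge(pr, dataset[, c("patient_id", "postop_day", v),
                                with = FALSE],
                    by = c("patient_id", "postop_day"))
        x <- mm[[v]]; y <- mm$score
      } else {
        x <- numeric(nrow(pr)); y <- pr$score
        for (k in seq_len(nrow(pr))) {
          win <- dataset[patient_id == pr$patient_id[k] &
                           postop_day >= pr$postop_day[k] - 6 &
                           postop_day <= pr$postop_day[k]][[v]]
          x[k] <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
        }
      }
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        rows[[paste(ins, v)]] <- data.table(
          variable = v, instrument = ins, r = NA_real_, p = NA_real_,
          n = n, estimable = FALSE)
      } else {
        ct <- cor.test(x[ok], y[ok], method = "pearson",
                       alternative = "two.sided")
        rows[[paste(ins, v)]] <- data.table(
          variable = v, instrument = ins, r = unname(ct$estimate),
          p = ct$p.value, n = n, estimable = TRUE)
      }
    }
  }
  out <- rbindlist(rows)
  out[, p_adj := NA_real_]
  out[estimable == TRUE, p_adj := p.adjust(p, method = fdr_method)]
  setcolorder(out, c("variable", "instrument", "r", "p", "p_adj", "n",
                     "estimable"))
  out[]
}

#' Fitted mobility-PROM relationship curves with pointwise bands
#'
#' For each (mobility variable, instrument) pair, a gaussian GLM of score
#' on the mobility value evaluated on an x-grid with a pointwise 95% Wald
#' band. Pairs with degenerate x (zero variance) are skipped.
#'
#' @param dataset analytic table.
#' @param proms PROM long table.
#' @param patients patient metadata.
#' @param n_grid grid size along the mobility axis.
#' @return a `data.table`: `variable`, `instrument`, `x`, `fit`, `lower`,
#'   `upper`.
#' @export
relationship_curves <- function(dataset, proms, patients, n_grid = 50) {
  dataset <- as.data.table(dataset)
  proms <- as.data.table(proms)
  patients <- as.data.table(patients)
  proms <- merge(proms, patients[, .(patient_id, surgery_date)],
                 by = "patient_id")
  proms[, postop_day := as.integer(as.Date(date) - as.Date(surgery_date))]
  out <- list()
  for (ins in unique(proms$instrument)) {
    pr <- proms[instrument == ins]
    for (v in .MOBILITY_VARS) {
      if (ins == "VAS") {
        mm <- merge(pr, dataset[, c("patient_id", "postop_day", v),
                                with = FALSE],
                    by = c("patient_id", "postop_day"))
        x <- mm[[v]]; y <- mm$score
      } else {
        x <- vapply(seq_len(nrow(pr)), function(k) {
          win <- dataset[patient_id == pr$patient_id[k] &
                           postop_day >= pr$postop_day[k] - 6 &
                           postop_day <= pr$postop_day[k]][[v]]
          if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
        }, numeric(1))
        y <- pr$score
      }
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0) next
      fit <- glm(y ~ x, data = data.frame(x = x[ok], y = y[ok]),
                 family = gaussian())
      grid <- seq(min(x[ok]), max(x[ok]), length.out = n_grid)
      pp <- predict(fit, data.frame(x = grid), se.fit = TRUE)
      out[[paste(ins, v)]] <- data.table(
        variable = v, instrument = ins, x = grid, fit = pp$fit,
        lower = pp$fit - qnorm(0.975) * pp$se.fit,
        upper = pp$fit + qnorm(0.975) * pp$se.fit)
    }
  }
  rbindlist(out)
}
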