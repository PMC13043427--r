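# Week comparison, recovery GLMs, PROM correlation and relationship curves.

mk_analytic <- function(vals_by_day, patients = "A", approach = "anterior") {
  dt <- data.table::CJ(patient_id = patients, postop_day = seq_along(vals_by_day))
  for (v in c("distance_km", "home_hours", "sig_loc_count",
              "sig_loc_entropy", "steps"))
    dt[, (v) := vals_by_day[postop_day]]
  dt[, approach := approach]
  dt
}

test_that("week comparison: identical weeks give p = 1 and equal means", {
  vals <- rep(NA_real_, 35)
  vals[1:7] <- c(3, 4, 5, 6, 5, 4, 3)
  vals[29:35] <- c(3, 4, 5, 6, 5, 4, 3)
  wc <- suppressWarnings(week_comparison(mk_analytic(vals)))
  expect_equal(wc$mean_a, wc$mean_b)
  expect_true(all(wc$p > 0.99))
  expect_true(all(wc$lower_a <= wc$mean_a & wc$mean_a <= wc$upper_a))
})

test_that("small-sample Wilcoxon p matches full enumeration", {
  vals <- rep(NA_real_, 35)
  vals[1:3] <- c(1, 2, 3)
  vals[29:31] <- c(10, 11, 12)
  wc <- week_comparison(mk_analytic(vals))
  # enumeration oracle: all 20 assignments of ranks to group A
  ranks <- combn(6, 3)
  w_obs <- sum(rank(c(1, 2, 3, 10, 11, 12))[1:3])
  w_all <- colSums(matrix(rank(1:6)[ranks], nrow = 3))
  p_exact <- mean(w_all <= w_obs | w_all >= sum(4:6) + sum(1:3) - w_obs)
  expect_equal(p_exact, 0.1)
  expect_equal(unique(wc$p), 0.1)
})

test_that("Wilcoxon p is invariant to monotone transforms of the data", {
  set.seed(6)
  vals <- rep(NA_real_, 35)
  vals[1:7] <- rlnorm(7, 1, 0.5)
  vals[29:35] <- rlnorm(7, 2, 0.5)
  p_raw <- week_comparison(mk_analytic(vals))$p[1]
  p_log <- week_comparison(mk_analytic(log1p(vals)))$p[1]
  p_sqrt <- week_comparison(mk_analytic(sqrt(vals)))$p[1]
  expect_equal(p_raw, p_log)
  expect_equal(p_raw, p_sqrt)
})

test_that("week comparison rejects near-empty weeks", {
  vals <- rep(NA_real_, 35)
  vals[1] <- 1
  vals[29:35] <- 2
  expect_error(week_comparison(mk_analytic(vals)), "fewer than 2")
})

test_that("poisson-log recovery GLM recovers known coefficients", {
  set.seed(41)
  n <- 900
  d <- sample(1:70, n, TRUE)
  arm <- sample(c("anterior", "posterior"), n, TRUE)
  a <- as.integer(arm == "posterior")
  eta <- 1 + 0.02 * d + 0.3 * a + 0.01 * d * a
  y <- rpois(n, exp(eta))
  dt <- data.table::data.table(patient_id = "x", postop_day = d,
                               approach = arm, sig_loc_count = y)
  fit <- fit_recovery_glm(dt, "sig_loc_count", family = "poisson")
  est <- fit$coefficients$estimate
  se <- fit$coefficients$se
  expect_true(all(abs(est - c(1, 0.02, 0.3, 0.01)) < 3 * se))
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
  # per-arm evaluator returns positive means under the log link
  expect_true(all(fit$predict_arm("anterior", 1:70) > 0))
})

test_that("gamma-log GLM offsets zeros and a constant response gives zero
          slopes", {
  dt <- data.table::data.table(
    patient_id = "x", postop_day = rep(1:50, 2),
    approach = rep(c("anterior", "posterior"), each = 50),
    sig_loc_entropy = c(0, rep(0.4, 99)))
  fit <- fit_recovery_glm(dt, "sig_loc_entropy", family = "gamma",
                          gamma_offset = 0.01)
  expect_equal(fit$n_offset, 1L)

  dt2 <- data.table::copy(dt)[, distance_km := 5]
  fit2 <- fit_recovery_glm(dt2, "distance_km", family = "gaussian")
  expect_lt(abs(fit2$coefficients$estimate[2]), 1e-6)
  expect_lt(abs(fit2$coefficients$estimate[4]), 1e-6)
})

test_that("interaction p-values are uniform under the null", {
  set.seed(17)
  n <- 300
  reps <- 150
  pvals <- replicate(reps, {
    d <- sample(1:70, n, TRUE)
    arm <- sample(c("anterior", "posterior"), n, TRUE)
    y <- rpois(n, exp(1 + 0.02 * d))  # no arm effect at all
    dt <- data.table::data.table(patient_id = "x", postop_day = d,
                                 approach = arm, steps = y)
    fit_recovery_glm(dt, "steps", family = "poisson")$coefficients[
      term == "postop_day:approachposterior", p]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("PROM correlation pairs daily and weekly instruments correctly", {
  dt <- mk_analytic(seq(1, 5, length.out = 35))
  patients <- data.table::data.table(patient_id = "A",
                                     surgery_date = as.Date("2025-03-02"))
  # daily VAS exactly linear in distance -> r = -1
  proms <- data.table::data.table(
    patient_id = "A", date = as.Date("2025-03-02") + 1:35,
    instrument = "VAS", score = 10 - 0.5 * seq(1, 5, length.out = 35))
  ct <- correlate_proms(dt, proms, patients)
  expect_equal(ct[instrument == "VAS" & variable == "distance_km", r], -1)
  expect_equal(ct[instrument == "VAS" & variable == "distance_km", n], 35L)

  # weekly instrument pairs with the trailing 7-day mean
  promw <- data.table::data.table(
    patient_id = "A", date = as.Date("2025-03-02") + c(7, 14, 21),
    instrument = "mJOA", score = c(10, 12, 14))
  ctw <- correlate_proms(dt, promw, patients)
  x_manual <- vapply(c(7, 14, 21), function(d)
    mean(dt[postop_day >= d - 6 & postop_day <= d, distance_km]), numeric(1))
  expect_equal(ctw[instrument == "mJOA" & variable == "distance_km", r],
               cor(x_manual, c(10, 12, 14)))
  # fewer than 3 pairs is not estimable
  ct2 <- correlate_proms(dt, promw[1:2], patients)
  expect_false(ct2[instrument == "mJOA" & variable == "distance_km", estimable])
  expect_true(is.na(ct2[instrument == "mJOA" & variable == "distance_km", r]))
})

test_that("BH adjustment matches the hand step-up procedure and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up by hand: p_(i) * m / i, cumulative minimum from the largest
  m <- length(p)
  hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(hand, rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), hand)
  # within correlate_proms the adjusted p is never below the raw p
  dt <- mk_analytic(seq(1, 5, length.out = 35))
  set.seed(3)
  for (v in c("home_hours", "steps"))
    dt[, (v) := runif(.N, 1, 2)]
  patients <- data.table::data.table(patient_id = "A",
                                     surgery_date = as.Date("2025-03-02"))
  proms <- data.table::data.table(
    patient_id = "A", date = as.Date("2025-03-02") + 1:35,
    instrument = "VAS", score = round(runif(35, 0, 10)))
  ct <- correlate_proms(dt, proms, patients)
  est <- ct[estimable == TRUE]
  expect_true(all(est$p_adj >= est$p - 1e-12))
  # adjusted order follows raw order
  expect_equal(order(est$p), order(est$p_adj, est$p))
})

test_that("relationship curves are flat for constant scores and collapse
          with vanishing noise", {
  dt <- mk_analytic(seq(1, 5, length.out = 35))
  patients <- data.table::data.table(patient_id = "A",
                                     surgery_date = as.Date("2025-03-02"))
  proms <- data.table::data.table(
    patient_id = "A", date = as.Date("2025-03-02") + 1:35,
    instrument = "VAS", score = 4)
  cv <- relationship_curves(dt, proms, patients)
  expect_true(all(abs(cv[variable == "distance_km", fit] - 4) < 1e-8))

  # perfectly linear: the band width shrinks to zero
  proms2 <- data.table::copy(proms)[, score := 2 + 0.5 * dt$distance_km]
  cv2 <- relationship_curves(dt, proms2, patients)
  expect_lt(max(cv2[variable == "distance_km", upper - lower]), 1e-6)
})
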