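# The cleaning ladder: follow-up censoring, per-patient sparse-variable
# exclusion, chained-equation multiple imputation with a random-forest
# conditional model, consolidation of the imputations, automated outlier
# fences, and log transforms. Observed cells are never altered; every
# modified cell is recorded in the provenance attribute.

.MOBILITY_VARS <- c("distance_km", "home_hours", "sig_loc_count",
                    "sig_loc_entropy", "steps")
.INTEGER_VARS <- c("sig_loc_count", "steps")

#' Censor observations beyond the follow-up window
#'
#' Removes rows with `postop_day` greater than `censor_day` (day
#' `censor_day` itself is retained).
#'
#' @param table a daily-summary table.
#' @param censor_day follow-up horizon in days.
#' @return the censored table.
#' @export
censor_followup <- function(table, censor_day = 70) {
  table <- as.data.table(table)
  n_drop <- sum(table$postop_day > censor_day)
  if (n_drop > 0) .log_msg("censor_followup: dropped %d row(s)", n_drop)
  table[postop_day <= censor_day]
}

#' Exclude per-patient sparse variables
#'
#' For each patient and mobility variable, if the fraction of missing
#' values within that patient's records is strictly greater than
#' `threshold`, the variable is excluded from analysis for that patient:
#' its values are set missing and it is never imputed.
#'
#' @param table a daily-summary table.
#' @param threshold missing-fraction cutoff (default 0.5).
#' @return the table, with an `"exclusions"` attribute listing
#'   (patient_id, variable) pairs.
#' @export
exclude_sparse_variables <- function(table, threshold = 0.5) {
  table <- copy(as.data.table(table))
  exc <- list()
  for (v in .MOBILITY_VARS) {
    frac <- table[, .(f = mean(is.na(.SD[[1]]))), by = patient_id, .SDcols = v]
    bad <- frac[f > threshold, patient_id]
    if (length(bad)) {
      table[patient_id %in% bad, (v) := NA]
      exc[[v]] <- data.table(patient_id = bad, variable = v)
    }
  }
  exc <- if (length(exc)) rbindlist(exc) else
    data.table(patient_id = character(), variable = character())
  data.table::setattr(table, "exclusions", exc)
  table[]
}

#' Chained-equation multiple imputation with random-forest models
#'
#' Fills missing mobility cells by iterated conditional random forests:
#' each variable with missing values is regressed on the other mobility
#' variables, `postop_day` and `approach`, and missing cells are replaced
#' by the prediction of one randomly drawn tree (a donor-style draw that
#' preserves between-imputation variability). `m` independent chains give
#' `m` completed tables. Observed cells are untouched; deterministic under
#' a fixed seed. Cells flagged in `non_imputable` (a logical matrix or
#' `NULL`) stay missing.
#'
#' @param table a daily-summary table with `patient_id`, `postop_day`,
#'   `approach` and the five mobility variables.
#' @param m number of completed datasets.
#' @param iterations chained iterations per dataset.
#' @param seed integer seed.
#' @param trees forest size per conditional model.
#' @param non_imputable optional logical matrix (rows x mobility variables)
#'   marking cells that must remain missing (excluded variables).
#' @return list of `m` completed `data.table`s with an `"imputed"`
#'   attribute (logical matrix of imputed cells).
#' @export
impute_chained <- function(table, m = 5, iterations = 50, seed = 1L,
                           trees = 100, non_imputable = NULL) {
  table <- as.data.table(table)
  if (!"approach" %in% names(table))
    stop("impute_chained: table must carry an 'approach' column")
  vars <- .MOBILITY_VARS
  miss <- sapply(vars, function(v) is.na(table[[v]]))
  if (!is.null(non_imputable)) miss <- miss & !non_imputable
  for (v in vars) {
    if (all(is.na(table[[v]])))
      stop("impute_chained: variable '", v, "' has no observed values")
  }
  if (!any(miss)) {
    out <- lapply(seq_len(m), function(j) copy(table))
    for (j in seq_len(m)) data.table::setattr(out[[j]], "imputed", miss)
    return(out)
  }
  .with_seed(seed, {
    out <- vector("list", m)
    for (j in seq_len(m)) {
      comp <- copy(table)
      # forests predict on the continuous scale; integer variables are
      # rounded back at pooling time
      for (v in vars)
        data.table::set(comp, j = v, value = as.numeric(comp[[v]]))
      # initialize missing cells with draws from the observed marginals
      for (v in vars) {
        mi <- which(miss[, v])
        if (length(mi)) {
          obs <- comp[[v]][!is.na(table[[v]])]
          data.table::set(comp, i = mi, j = v,
                          value = sample(obs, length(mi), replace = TRUE))
        }
      }
      comp[, approach := factor(approach)]
      for (it in seq_len(iterations)) {
        for (v in vars) {
          mi <- which(miss[, v])
          if (!length(mi)) next
          preds <- c(setdiff(vars, v), "postop_day", "approach")
          train <- comp[!is.na(table[[v]]),
                        c(v, preds), with = FALSE]
          fit <- ranger::ranger(
            dependent.variable.name = v, data = train,
            num.trees = trees, seed = sample.int(.Machine$integer.max, 1),
            num.threads = 1, verbose = FALSE)
          pa <- predict(fit, comp[mi, preds, with = FALSE],
                        predict.all = TRUE, num.threads = 1)$predictions
          pick <- sample.int(trees, length(mi), replace = TRUE)
          data.table::set(comp, i = mi, j = v,
                          value = pa[cbind(seq_along(mi), pick)])
        }
      }
      comp[, approach := as.character(approach)]
      data.table::setattr(comp, "imputed", miss)
      out[[j]] <- comp
    }
    out
  })
}

#' Consolidate multiple imputations into one analytic table
#'
#' Cell-wise mean across the `m` completed tables for continuous
#' variables; rounded mean for integer-valued variables (location count,
#' steps). Observed cells are identical across imputations and pass
#' through unchanged.
#'
#' @param tables list of completed tables from [impute_chained()].
#' @return a single pooled `data.table` with the `"imputed"` attribute
#'   carried over.
#' @export
pool_imputations <- function(tables) {
  if (!length(tables)) stop("pool_imputations: no tables")
  shapes <- vapply(tables, nrow, integer(1))
  if (length(unique(shapes)) != 1)
    stop("pool_imputations: shape mismatch across imputations")
  pooled <- copy(as.data.table(tables[[1]]))
  for (v in .MOBILITY_VARS) {
    mats <- sapply(tables, function(tb) as.numeric(tb[[v]]))
    mean_v <- rowMeans(mats)
    if (v %in% .INTEGER_VARS) mean_v <- round(mean_v)
    data.table::set(pooled, j = v, value = mean_v)
  }
  data.table::setattr(pooled, "imputed", attr(tables[[1]], "imputed"))
  pooled[]
}

#' Remove univariate outliers with Tukey fences
#'
#' Cells outside \[Q1 - k IQR, Q3 + k IQR\] per variable are set missing
#' for analysis (rows retained). A variable with zero IQR never flags
#' anything.
#'
#' @param dataset the pooled analytic table.
#' @param k fence multiplier (default 3, gross outliers only).
#' @return the table with an `"outliers"` attribute (row/variable pairs).
#' @export
remove_outliers <- function(dataset, k = 3) {
  dataset <- copy(as.data.table(dataset))
  rem <- list()
  for (v in .MOBILITY_VARS) {
    x <- as.numeric(dataset[[v]])
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    if (!is.finite(iqr) || iqr == 0) next
    bad <- which(!is.na(x) & (x < q[1] - k * iqr | x > q[2] + k * iqr))
    if (length(bad)) {
      rem[[v]] <- data.table(row = bad, variable = v, value = x[bad])
      data.table::set(dataset, i = bad, j = v, value = NA)
    }
  }
  rem <- if (length(rem)) rbindlist(rem) else
    data.table(row = integer(), variable = character(), value = numeric())
  data.table::setattr(dataset, "outliers", rem)
  dataset[]
}

#' Add log-transformed companion columns
#'
#' Adds `log(x + 1)` columns (suffix `_log`) for the requested variables;
#' originals are retained for raw-scale summaries.
#'
#' @param dataset analytic table.
#' @param variables variables to transform (must be non-negative).
#' @return the table with added columns.
#' @export
log_transform <- function(dataset,
                          variables = c("distance_km", "steps", "sig_loc_entropy")) {
  dataset <- copy(as.data.table(dataset))
  for (v in variables) {
    x <- as.numeric(dataset[[v]])
    if (any(x < 0, na.rm = TRUE))
      stop("log_transform: negative values in ", v)
    data.table::set(dataset, j = paste0(v, "_log"), value = log1p(x))
  }
  dataset[]
}

#' Run the full cleaning ladder
#'
#' Censoring, per-patient sparse-variable exclusion, chained random-forest
#' multiple imputation, pooling, outlier fences and log transforms, in
#' that order. The result carries a `"provenance"` attribute recording
#' exclusions, imputed cells and removed outliers; re-running the ladder
#' on its own output is the identity as long as the outlier step is
#' stable (previously removed or excluded cells are never re-imputed).
#'
#' @param summaries a daily-summary table ([extract_daily_summaries()]).
#' @param patients the patient-metadata table (for `approach`).
#' @param config a [run_config()].
#' @return the analytic `data.table` (grid-completed to
#'   `patient x 1..censor_day`) with `approach` attached and a
#'   `"provenance"` attribute.
#' @export
preprocess_daily <- function(summaries, patients, config = run_config()) {
  summaries <- as.data.table(summaries)
  patients <- as.data.table(patients)
  prev <- attr(summaries, "provenance")
  tb <- censor_followup(summaries, config$censor_day)
  grid <- data.table::CJ(patient_id = unique(patients$patient_id),
                         postop_day = seq_len(config$censor_day))
  keep <- intersect(c("patient_id", "postop_day", .MOBILITY_VARS,
                      paste0(.MOBILITY_VARS, "_log")), names(tb))
  tb <- merge(grid, tb[, keep, with = FALSE],
              by = c("patient_id", "postop_day"), all.x = TRUE)
  tb <- merge(tb, patients[, .(patient_id, approach)], by = "patient_id")
  setorder(tb, patient_id, postop_day)

  tb <- exclude_sparse_variables(tb, config$missing_fraction_threshold)
  exclusions <- attr(tb, "exclusions")
  non_imp <- sapply(.MOBILITY_VARS, function(v)
    tb$patient_id %in% exclusions[variable == v, patient_id])
  non_imp <- matrix(non_imp, nrow = nrow(tb),
                    dimnames = list(NULL, .MOBILITY_VARS))
  if (!is.null(prev) && nrow(prev$outliers)) {
    # cells removed as outliers by an earlier pass stay removed
    for (v in unique(prev$outliers$variable))
      non_imp[prev$outliers[variable == v, row], v] <- TRUE
  }
  imps <- impute_chained(tb, m = config$mice_m,
                         iterations = config$mice_iterations,
                         seed = config$seed, trees = config$mice_trees,
                         non_imputable = non_imp)
  pooled <- pool_imputations(imps)
  imputed <- attr(pooled, "imputed")
  pooled <- remove_outliers(pooled, config$outlier_k)
  outliers <- attr(pooled, "outliers")
  if (!is.null(prev) && nrow(prev$outliers))
    outliers <- unique(rbind(prev$outliers, outliers))
  stale_log <- intersect(paste0(.MOBILITY_VARS, "_log"), names(pooled))
  if (length(stale_log)) pooled[, (stale_log) := NULL]  # recomputed below
  analytic <- log_transform(pooled, config$log_variables)
  data.table::setattr(analytic, "provenance",
                      list(exclusions = exclusions, imputed = imputed,
                           outliers = outliers))
  analytic[]
}

#' Provenance of an analytic dataset
#'
#' @param dataset output of [preprocess_daily()].
#' @return list with `exclusions`, `imputed`, `outliers`.
#' @export
provenance <- function(dataset) attr(dataset, "provenance")
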