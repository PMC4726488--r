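#' Run-day median normalization
#'
#' Removes day-level instrument drift from semi-quantitative MS intensities:
#' each value is divided by the median of its metabolite on its run day and
#' multiplied by the metabolite's overall median, both taken over observed
#' values only. After normalization, every run day's median for a metabolite
#' equals that metabolite's pre-normalization overall median, so the
#' operation is idempotent and invariant to rescaling any single day.
#'
#' @param x A RAW-scale [metab_matrix()].
#' @return A NORMALIZED-scale `metab_matrix` carrying the day-by-metabolite
#'   median table in its `"day_medians"` attribute.
#' @examples
#' m <- metab_matrix(matrix(c(2, 4, 8, 16), 4, 1), paste0("s", 1:4), "m1",
#'                   run_day = c("d1", "d1", "d2", "d2"))
#' metab_values(run_day_normalize(m))  # 4, 8, 4, 8
#' @export
run_day_normalize <- function(x) {
  check_scale(x, "RAW", "run_day_normalize")
  vals <- metab_values(x)
  days <- x$run_day
  day_levels <- unique(days)
  overall <- apply(vals, 2, median, na.rm = TRUE)
  day_med <- matrix(NA_real_, length(day_levels), ncol(vals),
                    dimnames = list(day_levels, colnames(vals)))
  for (d in day_levels) {
    day_med[d, ] <- apply(vals[days == d, , drop = FALSE], 2, median, na.rm = TRUE)
  }
  if (any(day_med == 0, na.rm = TRUE)) {
    abort("zero run-day median encountered; raw intensities must be positive.")
  }
  no_obs <- which(is.na(day_med), arr.ind = TRUE)
  if (nrow(no_obs)) {
    warn(sprintf("%d (day, metabolite) cell(s) have no observed values; left missing.",
                 nrow(no_obs)))
  }
  norm <- vals / day_med[days, , drop = FALSE] *
    matrix(overall, nrow(vals), ncol(vals), byrow = TRUE)
  out <- set_metab_values(x, norm, scale = "NORMALIZED")
  attr(out, "day_medians") <- tibble::as_tibble(day_med, rownames = "run_day")
  attr(out, "overall_medians") <- overall
  out
}

#' Natural-log transform
#'
#' @param x A NORMALIZED-scale [metab_matrix()] with strictly positive
#'   observed values.
#' @return A LOG-scale `metab_matrix`; missing cells stay missing.
#' @export
log_transform <- function(x) {
  check_scale(x, "NORMALIZED", "log_transform")
  vals <- metab_values(x)
  bad <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-positive value at sample '%s', metabolite '%s'.",
                  rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  set_metab_values(x, log(vals), scale = "LOG")
}

#' Exclude metabolites and samples with excessive missingness
#'
#' Metabolites with a missing fraction strictly greater than
#' `metabolite_threshold` are dropped first; then samples whose missing
#' fraction over the retained metabolites is strictly greater than
#' `sample_threshold` are dropped. The strict inequality means a metabolite
#' missing in exactly 20% of samples is retained.
#'
#' @param x A [metab_matrix()] (any scale).
#' @param metabolite_threshold Maximum tolerated metabolite missing fraction
#'   (default 0.20).
#' @param sample_threshold Maximum tolerated sample missing fraction over
#'   retained metabolites (default 0.10).
#' @return A list with `matrix` (the filtered `metab_matrix`) and `report`
#'   (a list: `dropped_metabolites`, `dropped_samples`,
#'   `n_missing_remaining`).
#' @export
filter_missingness <- function(x, metabolite_threshold = 0.20,
                               sample_threshold = 0.10) {
  stopifnot(metabolite_threshold >= 0, metabolite_threshold <= 1,
            sample_threshold >= 0, sample_threshold <= 1)
  vals <- metab_values(x)
  met_frac <- colMeans(is.na(vals))
  drop_met <- colnames(vals)[met_frac > metabolite_threshold]
  keep <- setdiff(colnames(vals), drop_met)
  if (!length(keep)) abort("all metabolites exceed the missingness threshold.")
  vals2 <- vals[, keep, drop = FALSE]
  samp_frac <- rowMeans(is.na(vals2))
  drop_samp <- rownames(vals2)[samp_frac > sample_threshold]
  rows <- !(rownames(vals2) %in% drop_samp)
  out <- x[rows, c("sample_id", "run_day", keep)]
  out <- new_metab_matrix(tibble::as_tibble(out), metab_scale(x))
  list(matrix = out,
       report = list(dropped_metabolites = drop_met,
                     dropped_samples = drop_samp,
                     n_missing_remaining = sum(is.na(metab_values(out)))))
}

#' Chained-equations imputation of remaining missing values
#'
#' Each missing cell is filled by iterated linear regression of its
#' metabolite on all others (observed values plus current imputations),
#' starting from per-metabolite observed means, until the largest absolute
#' change falls below `tol` or `max_iter` sweeps are reached. The default is
#' deterministic conditional-mean imputation; `draws = TRUE` adds a residual
#' noise draw per cell (seeded) for stochastic imputation. Observed cells are
#' never altered. A numerically singular regression step falls back to a
#' small ridge penalty with a warning.
#'
#' @param x A LOG-scale [metab_matrix()], post-filtering; every metabolite
#'   needs at least two observed values.
#' @param max_iter Maximum sweeps over the metabolites (default 20).
#' @param tol Convergence tolerance on imputed values (default 1e-4).
#' @param seed Optional seed, used only when `draws = TRUE`.
#' @param draws Add residual-SD noise to each imputed value.
#' @return A complete LOG-scale `metab_matrix`; the number of imputed cells
#'   is recorded in the `"n_imputed"` attribute.
#' @export
impute_chained <- function(x, max_iter = 20L, tol = 1e-4, seed = NULL,
                           draws = FALSE) {
  check_scale(x, "LOG", "impute_chained")
  vals <- metab_values(x)
  miss <- is.na(vals)
  if (!any(miss)) {
    attr(x, "n_imputed") <- 0L
    return(x)
  }
  if (any(colSums(!miss) < 2)) {
    abort("every metabolite needs at least two observed values to impute.")
  }
  if (!is.null(seed)) set.seed(seed)
  filled <- vals
  mu <- colMeans(vals, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) filled[miss[, j], j] <- mu[j]
  target_cols <- which(colSums(miss) > 0)
  for (iter in seq_len(max_iter)) {
    max_change <- 0
    for (j in target_cols) {
      obs <- !miss[, j]
      xx <- cbind(1, filled[, -j, drop = FALSE])
      xo <- xx[obs, , drop = FALSE]
      xtx <- crossprod(xo)
      xty <- crossprod(xo, filled[obs, j])
      fit <- tryCatch(solve(xtx, xty), error = function(e) NULL)
      if (is.null(fit)) {
        warn(sprintf("singular design imputing '%s'; using ridge fallback.",
                     colnames(vals)[j]))
        fit <- solve(xtx + 1e-4 * diag(ncol(xx)), xty)
      }
      pred <- drop(xx[!obs, , drop = FALSE] %*% fit)
      if (draws) {
        res_sd <- sd(filled[obs, j] - drop(xx[obs, , drop = FALSE] %*% fit))
        pred <- pred + rnorm(length(pred), 0, res_sd)
      }
      max_change <- max(max_change, abs(pred - filled[!obs, j]))
      filled[!obs, j] <- pred
    }
    if (max_change < tol) break
  }
  out <- set_metab_values(x, filled, scale = "LOG")
  attr(out, "n_imputed") <- sum(miss)
  out
}

#' Standardize metabolites to mean zero, unit variance
#'
#' @param x A complete LOG-scale [metab_matrix()].
#' @return A STANDARDIZED-scale `metab_matrix` (per-metabolite sample mean 0,
#'   sample SD 1).
#' @export
standardize <- function(x) {
  check_scale(x, "LOG", "standardize")
  vals <- metab_values(x)
  if (anyNA(vals)) abort("standardize() requires a complete matrix; impute first.")
  s <- apply(vals, 2, sd)
  if (any(s == 0)) {
    abort(sprintf("zero-variance metabolite '%s'.", colnames(vals)[which(s == 0)[1]]))
  }
  set_metab_values(x, scale(vals), scale = "STANDARDIZED")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: run-day normalization, log transform, missingness
#' filtering, chained-equations imputation, then standardization.
#'
#' @inheritParams filter_missingness
#' @inheritParams impute_chained
#' @param x A RAW-scale [metab_matrix()].
#' @return A list with `log_matrix` (complete LOG scale, for association and
#'   ratio scans), `std_matrix` (STANDARDIZED, for network inference), and
#'   `report` (dropped ids, imputed cell count, day-median table).
#' @export
preprocess <- function(x, metabolite_threshold = 0.20, sample_threshold = 0.10,
                       max_iter = 20L, seed = NULL, draws = FALSE) {
  norm <- run_day_normalize(x)
  lg <- log_transform(norm)
  flt <- filter_missingness(lg, metabolite_threshold, sample_threshold)
  imp <- impute_chained(flt$matrix, max_iter = max_iter, seed = seed,
                        draws = draws)
  std <- standardize(imp)
  list(log_matrix = imp,
       std_matrix = std,
       report = list(dropped_metabolites = flt$report$dropped_metabolites,
                     dropped_samples = flt$report$dropped_samples,
                     imputed_cell_count = attr(imp, "n_imputed"),
                     day_median_table = attr(norm, "day_medians")))
}
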