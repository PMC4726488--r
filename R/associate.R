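#' Bonferroni family-wise threshold
#'
#' The per-test significance level controlling the family-wise error rate at
#' `alpha` over `n_tests` tests. With the study's 456 metabolites this is
#' 0.05/456 = 1.09e-4; over the 32 x 456 SNP-metabolite grid it is 3.43e-6.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' signif(bonferroni_threshold(0.05, 456), 3)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (length(n_tests) != 1 || n_tests < 1) abort("`n_tests` must be >= 1.")
  alpha / n_tests
}

#' Fit the per-metabolite case-control linear model
#'
#' Ordinary least squares of one metabolite's log concentration on a case
#' indicator plus the contrast's adjustment covariates (age and sex by
#' default), restricted to the contrast's two groups; the reported test is
#' the two-sided t-test on the case indicator. Samples missing the response
#' or any covariate are dropped listwise. This is the single-metabolite
#' reference path via [stats::lm()]; [run_scan()] applies the same model to
#' every metabolite at once.
#'
#' @param matrix A LOG-scale (or STANDARDIZED) [metab_matrix()].
#' @param annotation Sample annotation tibble.
#' @param ctr A [contrast()].
#' @param metabolite Metabolite column name.
#' @param threshold Optional per-test significance level used to set the
#'   `significant` flag.
#' @return A one-row tibble: `metabolite_id`, `contrast`, `beta`, `se`,
#'   `t_stat`, `p_value`, `n_used`, `direction`, `significant`.
#' @export
fit_metabolite_model <- function(matrix, annotation, ctr, metabolite,
                                 threshold = NULL) {
  stopifnot(inherits(ctr, "contrast"))
  if (!metabolite %in% metabolite_ids(matrix)) {
    abort(sprintf("metabolite '%s' not in matrix.", metabolite))
  }
  des <- contrast_design(align_annotation(matrix, annotation), ctr)
  idx <- match(des$sample_id, matrix$sample_id)
  y <- metab_values(matrix)[idx, metabolite]
  keep <- !is.na(y)
  if (sum(keep) <= ncol(des$X) + 1) abort("too few samples with observed values.")
  dat <- as.data.frame(des$X[keep, -1, drop = FALSE])
  dat$y <- y[keep]
  fit <- stats::lm(y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients["case", ]
  assoc_record(metabolite, ctr$name, beta = sm[1], se = sm[2], t_stat = sm[3],
               p_value = sm[4], n_used = sum(keep), threshold = threshold)
}

assoc_record <- function(metabolite, contrast_name, beta, se, t_stat, p_value,
                         n_used, threshold = NULL) {
  tibble::tibble(
    metabolite_id = metabolite,
    contrast = contrast_name,
    beta = unname(beta), se = unname(se), t_stat = unname(t_stat),
    p_value = unname(p_value), n_used = as.integer(n_used),
    direction = dplyr::if_else(beta >= 0, "UP", "DOWN"),
    significant = if (is.null(threshold)) NA else p_value < threshold)
}

#' Metabolome-wide association scan
#'
#' Runs the per-metabolite linear model of [fit_metabolite_model()] for every
#' metabolite and every contrast, and flags metabolome-wide significance at
#' the Bonferroni level `alpha / n_tests`. The default test count is the
#' number of metabolites in the matrix — the number profiled, not the
#' post-filter count — matching a 0.05/456 style correction.
#'
#' @param matrix A LOG-scale (or STANDARDIZED) [metab_matrix()].
#' @param annotation Sample annotation tibble.
#' @param contrasts List of [contrast()] objects (default: PD vs control,
#'   RLS vs control, PD vs RLS).
#' @param alpha Family-wise level (default 0.05).
#' @param n_tests Bonferroni denominator; defaults to the number of
#'   metabolite columns.
#' @return A tibble of class `assoc_table`, one row per (metabolite,
#'   contrast), sorted by contrast then p-value, with the threshold in the
#'   `"threshold"` attribute.
#' @export
run_scan <- function(matrix, annotation, contrasts = default_contrasts(),
                     alpha = 0.05, n_tests = NULL) {
  if (inherits(contrasts, "contrast")) contrasts <- list(contrasts)
  ids <- metabolite_ids(matrix)
  n_tests <- n_tests %||% length(ids)
  threshold <- bonferroni_threshold(alpha, n_tests)
  vals <- metab_values(matrix)
  out <- purrr::map_dfr(contrasts, function(ctr) {
    des <- contrast_design(align_annotation(matrix, annotation), ctr)
    idx <- match(des$sample_id, matrix$sample_id)
    fit <- ols_scan(des$X, vals[idx, , drop = FALSE], term = 2L)
    assoc_record(ids, ctr$name, fit$beta, fit$se, fit$t, fit$p, fit$n_used,
                 threshold)
  })
  out <- dplyr::arrange(out, factor(.data$contrast,
                                    unique(vapply(contrasts, `[[`, "", "name"))),
                        .data$p_value)
  structure(out, threshold = threshold, alpha = alpha, n_tests = n_tests,
            class = c("assoc_table", class(out)))
}

#' Classify metabolites into shared and disease-unique sets
#'
#' Given scan results for the three standard contrasts, each metabolite is
#' classified by where it reaches metabolome-wide significance:
#' `shared_unidirectional` (significant versus controls in both PD and RLS,
#' same direction — candidates for drug effects or systematic artifacts),
#' `pd_unique` / `rls_unique` (significant versus controls in exactly one
#' disease), `discordant` (significant in both but with opposite directions),
#' and `pd_vs_rls` (significant in the direct PD-RLS comparison, reported
#' alongside the other sets).
#'
#' @param table An `assoc_table` from [run_scan()] covering the contrasts
#'   `PD_vs_CONTROL`, `RLS_vs_CONTROL`, `PD_vs_RLS`.
#' @return A tibble of class `metab_classification`: one row per metabolite
#'   with logical columns `shared_unidirectional`, `pd_unique`, `rls_unique`,
#'   `discordant`, `pd_vs_rls`.
#' @export
classify_metabolites <- function(table) {
  needed <- c("PD_vs_CONTROL", "RLS_vs_CONTROL", "PD_vs_RLS")
  if (!all(needed %in% table$contrast)) {
    abort(paste0("classification needs the contrasts: ",
                 paste(needed, collapse = ", ")))
  }
  wide <- table |>
    dplyr::select("metabolite_id", "contrast", "significant", "direction") |>
    tidyr::pivot_wider(names_from = "contrast",
                       values_from = c("significant", "direction"))
  sig_pd <- wide$significant_PD_vs_CONTROL %in% TRUE
  sig_rls <- wide$significant_RLS_vs_CONTROL %in% TRUE
  same_dir <- wide$direction_PD_vs_CONTROL == wide$direction_RLS_vs_CONTROL
  out <- tibble::tibble(
    metabolite_id = wide$metabolite_id,
    shared_unidirectional = sig_pd & sig_rls & same_dir,
    discordant = sig_pd & sig_rls & !same_dir,
    pd_unique = sig_pd & !sig_rls,
    rls_unique = sig_rls & !sig_pd,
    pd_vs_rls = wide$significant_PD_vs_RLS %in% TRUE)
  structure(out, class = c("metab_classification", class(out)))
}
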