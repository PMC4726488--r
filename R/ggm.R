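#' Regress confounders out of every metabolite
#'
#' Replaces each (standardized) metabolite by its residual from OLS on an
#' intercept plus the requested covariates, then re-standardizes. The default
#' covariate set is age, sex, and the disease indicators (`"group"` expands to
#' PD and RLS 0/1 columns), so downstream partial correlations are corrected
#' for these confounders.
#'
#' @param x A STANDARDIZED-scale [metab_matrix()].
#' @param annotation Sample annotation tibble.
#' @param covariates Annotation fields to remove; an empty vector returns the
#'   input unchanged.
#' @return A STANDARDIZED-scale `metab_matrix` of residuals.
#' @export
residualize <- function(x, annotation, covariates = c("age", "sex", "group")) {
  check_scale(x, "STANDARDIZED", "residualize")
  if (!length(covariates)) return(x)
  ann <- validate_annotation(annotation)
  idx <- match(x$sample_id, ann$sample_id)
  if (anyNA(idx)) abort("samples missing from annotation.")
  covars <- covariate_design(ann[idx, , drop = FALSE], covariates)
  if (anyNA(covars)) abort("covariates must be complete for residualization.")
  X <- cbind(1, covars)
  if (qr(X)$rank < ncol(X)) abort("collinear covariates in residualization design.")
  vals <- metab_values(x)
  res <- stats::lm.fit(X, vals)$residuals
  s <- apply(res, 2, sd)
  if (any(s < 1e-12)) {
    abort(sprintf("metabolite '%s' is fully explained by the covariates (zero residual variance).",
                  colnames(vals)[which(s < 1e-12)[1]]))
  }
  set_metab_values(x, scale(res), scale = "STANDARDIZED")
}

#' Shrinkage estimate of correlation and partial correlation
#'
#' Computes the sample correlation matrix `R`, the analytic shrinkage
#' intensity
#' `lambda* = sum_(i<j) Var(r_ij) / sum_(i<j) r_ij^2` (clamped to `[0, 1]`,
#' with `Var(r_ij)` the unbiased empirical variance of the standardized
#' product terms), the shrunk correlation `(1 - lambda) R + lambda I`, and the
#' partial correlations `rho_ij = -O_ij / sqrt(O_ii O_jj)` from its inverse
#' `O`. Shrinking toward the identity keeps the estimate well conditioned
#' even when the number of metabolites approaches or exceeds the sample
#' count, which is what makes partial correlations usable in low-powered
#' settings.
#'
#' @param x A complete [metab_matrix()] (any scale; columns are standardized
#'   internally) or a plain numeric matrix, samples in rows.
#' @param lambda Optional fixed shrinkage intensity overriding the analytic
#'   value (e.g. `lambda = 1` forces the identity, all partials zero).
#' @return A list of class `shrinkage_estimate`: `lambda`, `correlation`,
#'   `shrunk_correlation`, `partial_correlation`, `n`, `p`, and the
#'   standardized `data` (kept for permutation tests).
#' @export
estimate_shrinkage <- function(x, lambda = NULL) {
  X <- if (inherits(x, "metab_matrix")) metab_values(x) else as.matrix(x)
  if (anyNA(X)) abort("shrinkage estimation requires a complete matrix.")
  n <- nrow(X); p <- ncol(X)
  if (n < 3) abort("need at least 3 samples.")
  Xs <- scale(X)
  if (any(!is.finite(Xs))) abort("zero-variance metabolite; cannot correlate.")
  R <- crossprod(Xs) / (n - 1)
  if (is.null(lambda)) {
    # unbiased variance of r_ij from the product terms w_kij = x_ki * x_kj:
    # Var(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean_k w_kij)^2
    sum_w2 <- crossprod(Xs^2)          # sum_k w_kij^2
    wbar <- R * (n - 1) / n            # mean_k w_kij
    var_r <- n / (n - 1)^3 * (sum_w2 - n * wbar^2)
    num <- sum(var_r[upper.tri(var_r)])
    den <- sum(R[upper.tri(R)]^2)
    lambda <- if (den <= 0) 1 else min(1, max(0, num / den))
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
  }
  shrunk <- (1 - lambda) * R
  diag(shrunk) <- 1
  omega <- tryCatch(chol2inv(chol(shrunk)), error = function(e) {
    abort("shrunk correlation matrix is numerically singular; set a lambda floor.")
  })
  structure(list(lambda = lambda, correlation = R, shrunk_correlation = shrunk,
                 partial_correlation = precision_to_partial(omega),
                 n = n, p = p, metabolite_ids = colnames(X), data = Xs),
            class = "shrinkage_estimate")
}

#' @export
print.shrinkage_estimate <- function(x, ...) {
  cat(sprintf("# shrinkage_estimate: p = %d, n = %d, lambda* = %.4f\n",
              x$p, x$n, x$lambda))
  invisible(x)
}

#' Per-pair significance of marginal and partial correlations
#'
#' For every metabolite pair, tests the Pearson correlation and the
#' shrinkage partial correlation against zero. The default is the Fisher
#' z-transform: `z = atanh(r) * sqrt(n - 3 - q)` with `q = 0` for the marginal
#' correlation and `q = p - 2` for the full-order partial correlation,
#' referred two-sided to the standard normal. The permutation alternative
#' permutes one member of each pair (its covariate-residual for the partial
#' test) `B` times and reports the add-one-corrected p-value
#' `(b + 1) / (B + 1)`; it is exact under exchangeability and used as the
#' fallback when the Fisher degrees of freedom `n - 3 - q` drop below 1.
#'
#' @param estimate A [estimate_shrinkage()] result.
#' @param n Sample count (taken from the estimate by default).
#' @param method `"FISHER_Z"` or `"PERMUTATION"`.
#' @param B Permutation count.
#' @param seed Seed for the permutation draws.
#' @return A tibble, one row per unordered pair: `metabolite_a`,
#'   `metabolite_b`, `pearson_r`, `pearson_p`, `partial_r`, `partial_p`.
#' @export
edge_pvalues <- function(estimate, n = estimate$n,
                         method = c("FISHER_Z", "PERMUTATION"),
                         B = 1000, seed = NULL) {
  stopifnot(inherits(estimate, "shrinkage_estimate"))
  method <- match.arg(method)
  p <- estimate$p
  q_partial <- p - 2
  if (method == "FISHER_Z" && n - 3 - q_partial < 1) {
    warn("Fisher-z degrees of freedom below 1; falling back to permutation test.")
    method <- "PERMUTATION"
  }
  ut <- which(upper.tri(estimate$correlation), arr.ind = TRUE)
  ids <- estimate$metabolite_ids %||% paste0("V", seq_len(p))
  r_marg <- estimate$correlation[ut]
  r_part <- estimate$partial_correlation[ut]
  if (method == "FISHER_Z") {
    pearson_p <- fisher_z_pvalue(r_marg, n, 0)
    partial_p <- fisher_z_pvalue(r_part, n, q_partial)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pp <- permutation_pvalues(estimate$data, ut, B)
    pearson_p <- pp$pearson
    partial_p <- pp$partial
    r_part <- pp$partial_r   # residual-based statistic matches its null
  }
  tibble::tibble(metabolite_a = ids[ut[, 1]], metabolite_b = ids[ut[, 2]],
                 pearson_r = r_marg, pearson_p = pearson_p,
                 partial_r = r_part, partial_p = partial_p)
}

#' Fisher z-transform p-value for a correlation
#'
#' @param r Correlation estimate(s).
#' @param n Sample count.
#' @param q Number of conditioning variables (0 for a marginal correlation).
#' @return Two-sided normal p-value(s); `r = 0` gives exactly 1.
#' @export
fisher_z_pvalue <- function(r, n, q = 0) {
  df <- n - 3 - q
  if (df < 1) abort("Fisher-z requires n - 3 - q >= 1.")
  z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(df)
  2 * pnorm(-abs(z))
}

# Permutation p-values per pair: the marginal statistic is the Pearson r, the
# partial statistic the correlation of the two residual vectors after
# regressing each member on all remaining metabolites. One member is permuted
# B times; add-one correction.
permutation_pvalues <- function(Xs, ut, B) {
  n <- nrow(Xs); p <- ncol(Xs)
  pearson <- partial <- partial_r <- numeric(nrow(ut))
  perms <- replicate(B, sample.int(n))
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    xi <- Xs[, i]; xj <- Xs[, j]
    r_obs <- stats::cor(xi, xj)
    r_null <- apply(perms, 2, function(pm) stats::cor(xi, xj[pm]))
    pearson[k] <- (sum(abs(r_null) >= abs(r_obs)) + 1) / (B + 1)
    others <- Xs[, -c(i, j), drop = FALSE]
    if (ncol(others)) {
      Z <- cbind(1, others)
      ei <- stats::lm.fit(Z, xi)$residuals
      ej <- stats::lm.fit(Z, xj)$residuals
    } else {
      ei <- xi - mean(xi); ej <- xj - mean(xj)
    }
    pr_obs <- stats::cor(ei, ej)
    pr_null <- apply(perms, 2, function(pm) stats::cor(ei, ej[pm]))
    partial[k] <- (sum(abs(pr_null) >= abs(pr_obs)) + 1) / (B + 1)
    partial_r[k] <- pr_obs
  }
  list(pearson = pearson, partial = partial, partial_r = partial_r)
}

#' Infer the Gaussian graphical model with the dual-significance edge rule
#'
#' Full network pipeline: residualize confounders out (age, sex, and disease
#' status by default), estimate the shrunk correlation and partial
#' correlations, compute per-pair p-values for both, and call an edge when
#' both the Pearson and the partial correlation pass the Bonferroni-corrected
#' level `alpha / n_pairs`. Pairs with a near-zero Pearson correlation
#' (`|r| < artifact_eps`) but a negative partial correlation are flagged as
#' statistical artifacts and excluded regardless of significance.
#'
#' @param x A STANDARDIZED-scale [metab_matrix()] (or the output of
#'   [residualize()]; set `covariates = character(0)` to skip the internal
#'   residualization).
#' @param annotation Sample annotation (needed unless `covariates` is empty).
#' @param alpha Family-wise level over all metabolite pairs (default 0.05).
#' @param covariates Confounders removed before correlation.
#' @param edge_test `"FISHER_Z"` (default) or `"PERMUTATION"`.
#' @param B,seed Permutation parameters.
#' @param artifact_eps Pearson magnitude below which a negative partial
#'   correlation is treated as an artifact (default 0.05).
#' @param lambda Optional fixed shrinkage intensity.
#' @return An object of class `ggm`: all pairs with correlations, p-values,
#'   `artifact_flag` and `passes_dual_rule`, plus `lambda`, `n`, `p` and the
#'   per-pair threshold. Use [tidy()] for the edge table and
#'   [annotate_network()] / [write_network()] for export.
#' @export
build_network <- function(x, annotation = NULL, alpha = 0.05,
                          covariates = c("age", "sex", "group"),
                          edge_test = c("FISHER_Z", "PERMUTATION"),
                          B = 1000, seed = NULL, artifact_eps = 0.05,
                          lambda = NULL) {
  edge_test <- match.arg(edge_test)
  if (length(covariates)) {
    if (is.null(annotation)) abort("annotation needed to residualize covariates.")
    x <- residualize(x, annotation, covariates)
  }
  est <- estimate_shrinkage(x, lambda = lambda)
  pv <- edge_pvalues(est, method = edge_test, B = B, seed = seed)
  n_pairs <- nrow(pv)
  threshold <- bonferroni_threshold(alpha, n_pairs)
  pv$artifact_flag <- abs(pv$pearson_r) < artifact_eps & pv$partial_r < 0
  pv$passes_dual_rule <- pv$pearson_p < threshold & pv$partial_p < threshold &
    !pv$artifact_flag
  structure(list(edges = pv, lambda = est$lambda, n = est$n, p = est$p,
                 alpha = alpha, threshold = threshold,
                 nodes = est$metabolite_ids, estimate = est),
            class = "ggm")
}

#' @export
print.ggm <- function(x, ...) {
  cat(sprintf("# ggm: %d metabolites, %d samples, lambda* = %.4f\n",
              x$p, x$n, x$lambda))
  cat(sprintf("#   %d / %d pairs pass the dual-significance rule (alpha = %g, per-pair %0.3g)\n",
              sum(x$edges$passes_dual_rule), nrow(x$edges), x$alpha, x$threshold))
  invisible(x)
}

#' Overlay association results on the network
#'
#' Maps each contrast's regression coefficient sign and -log10 p-value onto
#' the nodes of the dual-rule-filtered network, the export format meant for
#' pie-chart style rendering in external graph tools.
#'
#' @param ggm A [build_network()] result (or an edge tibble with a
#'   `passes_dual_rule` column).
#' @param association_table An [run_scan()] result, or `NULL` for a network
#'   without node annotation.
#' @return A list of class `metab_network` with tibbles `nodes` (one row per
#'   metabolite, per-contrast `<contrast>_direction` and `<contrast>_mlog10p`
#'   columns) and `edges` (pairs passing the dual rule).
#' @export
annotate_network <- function(ggm, association_table = NULL) {
  edges <- if (inherits(ggm, "ggm")) ggm$edges else ggm
  nodes_ids <- if (inherits(ggm, "ggm")) ggm$nodes else
    unique(c(edges$metabolite_a, edges$metabolite_b))
  kept <- dplyr::filter(edges, .data$passes_dual_rule) |>
    dplyr::select("metabolite_a", "metabolite_b", "pearson_r", "pearson_p",
                  "partial_r", "partial_p")
  nodes <- tibble::tibble(metabolite_id = nodes_ids)
  if (!is.null(association_table)) {
    absent <- setdiff(nodes_ids, association_table$metabolite_id)
    if (length(absent)) {
      warn(sprintf("%d node(s) absent from the association table; attributes set missing.",
                   length(absent)))
    }
    attrs <- association_table |>
      dplyr::mutate(mlog10p = -log10(.data$p_value)) |>
      dplyr::select("metabolite_id", "contrast", "direction", "mlog10p") |>
      tidyr::pivot_wider(names_from = "contrast",
                         values_from = c("direction", "mlog10p"),
                         names_glue = "{contrast}_{.value}")
    nodes <- dplyr::left_join(nodes, attrs, by = "metabolite_id")
  }
  structure(list(nodes = nodes, edges = kept), class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("# metab_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
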