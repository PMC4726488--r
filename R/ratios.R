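#' All-pairs metabolite-ratio association scan
#'
#' For every unordered metabolite pair the ratio of concentrations is tested
#' in the same case-control linear model as the single metabolites; on the
#' pipeline's log scale the ratio response is simply `log(a) - log(b)`.
#' Because OLS is linear in the response, the ratio coefficient is the
#' difference of the single-metabolite coefficients and its standard error
#' follows from the residual cross-products, so the full p(p-1)/2 scan costs
#' one model fit plus one residual cross-product — no per-pair regression.
#' Each pair carries the p-gain statistic `min(p_a, p_b) / p_ratio`: values
#' much above 1 mean the ratio is more strongly associated than either
#' metabolite alone, the signature of a shared enzymatic conversion.
#'
#' @param matrix A complete LOG-scale [metab_matrix()].
#' @param annotation Sample annotation tibble.
#' @param ctr A single [contrast()].
#' @param alpha Family-wise level; the per-pair threshold is
#'   `alpha / (p(p-1)/2)`.
#' @param max_pairs Guard against accidental huge scans; raise it explicitly
#'   for a full 456-metabolite run (103,740 pairs).
#' @return A tibble of `RatioRecord`s: `metabolite_a < metabolite_b` by id,
#'   `beta`, `se`, `t_stat`, `p_value`, `n_used`, single-metabolite `p_a`,
#'   `p_b`, `p_gain`, `significant`, and `degenerate` (constant ratio
#'   response, reported non-significant).
#' @export
ratio_scan <- function(matrix, annotation, ctr, alpha = 0.05,
                       max_pairs = 150000) {
  stopifnot(inherits(ctr, "contrast"))
  ids <- metabolite_ids(matrix)
  p <- length(ids)
  if (p < 2) abort("ratio scan needs at least two metabolites.")
  n_pairs <- p * (p - 1) / 2
  if (n_pairs > max_pairs) {
    abort(sprintf("%d pairs exceeds max_pairs = %d; raise `max_pairs`.",
                  n_pairs, max_pairs))
  }
  vals <- metab_values(matrix)
  if (anyNA(vals)) abort("ratio scan requires a complete matrix; impute first.")
  des <- contrast_design(align_annotation(matrix, annotation), ctr)
  idx <- match(des$sample_id, matrix$sample_id)
  fit <- ols_scan(des$X, vals[idx, , drop = FALSE], term = 2L)
  df <- fit$df
  rss <- unname(colSums(fit$residuals^2))
  rcp <- crossprod(fit$residuals)   # residual cross-products, all pairs at once

  ut <- which(upper.tri(rcp), arr.ind = TRUE)
  ia <- ut[, 1]; ib <- ut[, 2]
  beta <- fit$beta[ia] - fit$beta[ib]
  rss_ratio <- rss[ia] + rss[ib] - 2 * rcp[ut]
  rss_ratio[rss_ratio < 0] <- 0   # numerical guard
  sigma2 <- rss_ratio / df
  degenerate <- sigma2 < 1e-12
  se <- sqrt(sigma2 * fit$xtx_inv_jj)
  t_stat <- ifelse(degenerate, NA_real_, beta / se)
  p_value <- 2 * pt(-abs(t_stat), df)
  threshold <- bonferroni_threshold(alpha, n_pairs)
  p_ab <- pmin(fit$p[ia], fit$p[ib])
  out <- tibble::tibble(
    metabolite_a = ids[ia], metabolite_b = ids[ib],
    beta = beta, se = se, t_stat = t_stat, p_value = p_value,
    n_used = nrow(des$X),
    p_a = fit$p[ia], p_b = fit$p[ib],
    p_gain = p_ab / p_value,
    significant = !degenerate & !is.na(p_value) & p_value < threshold,
    degenerate = degenerate)
  # store each pair once, smaller id first
  flip <- out$metabolite_a > out$metabolite_b
  if (any(flip)) {
    tmp_a <- out$metabolite_a[flip]
    out$metabolite_a[flip] <- out$metabolite_b[flip]
    out$metabolite_b[flip] <- tmp_a
    out$beta[flip] <- -out$beta[flip]
    out$t_stat[flip] <- -out$t_stat[flip]
    tmp_p <- out$p_a[flip]
    out$p_a[flip] <- out$p_b[flip]
    out$p_b[flip] <- tmp_p
  }
  out <- dplyr::arrange(out, .data$metabolite_a, .data$metabolite_b)
  structure(out, threshold = threshold, contrast = ctr$name,
            class = c("ratio_table", class(out)))
}

#' Select the most informative ratios
#'
#' Sorts by p-gain (descending; ties broken by pair id for a stable order)
#' and keeps the top `k` rows and/or those with `p_gain >= p_gain_min`.
#'
#' @param table A [ratio_scan()] result.
#' @param k Keep at most this many rows.
#' @param p_gain_min Keep rows with at least this p-gain.
#' @return The filtered, sorted tibble.
#' @export
top_ratios <- function(table, k = NULL, p_gain_min = NULL) {
  out <- dplyr::arrange(table, dplyr::desc(.data$p_gain),
                        .data$metabolite_a, .data$metabolite_b)
  if (!is.null(p_gain_min)) out <- dplyr::filter(out, .data$p_gain >= p_gain_min)
  if (!is.null(k)) out <- head(out, k)
  out
}
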