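#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted GGM
#'
#' @param x A [build_network()] result.
#' @param filtered Return only edges passing the dual-significance rule
#'   (default `FALSE`: the full per-pair audit table).
#' @param ... Unused.
#' @return A tibble, one row per metabolite pair, with both correlations,
#'   both p-values, `artifact_flag` and `passes_dual_rule`.
#' @method tidy ggm
#' @export
tidy.ggm <- function(x, filtered = FALSE, ...) {
  out <- tibble::as_tibble(x$edges)
  if (filtered) out <- dplyr::filter(out, .data$passes_dual_rule)
  out
}

#' @rdname tidy.ggm
#' @return For `glance()`: a one-row tibble with `p`, `n`, `lambda`,
#'   `n_pairs`, `n_edges`, `n_artifacts`, `alpha`, `threshold`.
#' @method glance ggm
#' @export
glance.ggm <- function(x, ...) {
  tibble::tibble(p = x$p, n = x$n, lambda = x$lambda,
                 n_pairs = nrow(x$edges),
                 n_edges = sum(x$edges$passes_dual_rule),
                 n_artifacts = sum(x$edges$artifact_flag),
                 alpha = x$alpha, threshold = x$threshold)
}

#' Tidy a shrinkage estimate
#'
#' @param x A [estimate_shrinkage()] result.
#' @param ... Unused.
#' @return A tibble of all pairs with `pearson_r` and `partial_r`.
#' @method tidy shrinkage_estimate
#' @export
tidy.shrinkage_estimate <- function(x, ...) {
  ut <- which(upper.tri(x$correlation), arr.ind = TRUE)
  ids <- x$metabolite_ids %||% paste0("V", seq_len(x$p))
  tibble::tibble(metabolite_a = ids[ut[, 1]], metabolite_b = ids[ut[, 2]],
                 pearson_r = x$correlation[ut],
                 partial_r = x$partial_correlation[ut])
}

#' @rdname tidy.shrinkage_estimate
#' @method glance shrinkage_estimate
#' @export
glance.shrinkage_estimate <- function(x, ...) {
  tibble::tibble(p = x$p, n = x$n, lambda = x$lambda)
}

#' Summaries of an association scan
#'
#' @param x An `assoc_table` from [run_scan()].
#' @param ... Unused.
#' @return One row per contrast: number of tests, the Bonferroni threshold,
#'   and how many metabolites reach metabolome-wide significance.
#' @method glance assoc_table
#' @export
glance.assoc_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(contrast = .data$contrast) |>
    dplyr::summarise(n_metabolites = dplyr::n(),
                     n_significant = sum(.data$significant, na.rm = TRUE),
                     min_p = min(.data$p_value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(alpha = attr(x, "alpha"), threshold = attr(x, "threshold"))
}

#' Long form of a metabolite classification
#'
#' @param x A [classify_metabolites()] result.
#' @param ... Unused.
#' @return A tibble with one row per (metabolite, set) membership.
#' @method tidy metab_classification
#' @export
tidy.metab_classification <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"metabolite_id", names_to = "set",
                        values_to = "member") |>
    dplyr::filter(.data$member) |>
    dplyr::select("metabolite_id", "set")
}
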