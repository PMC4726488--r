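#' Hardy-Weinberg equilibrium filter
#'
#' One-degree-of-freedom chi-square goodness-of-fit test per SNP on the
#' hard-call genotype counts against the Hardy-Weinberg expectation at the
#' estimated allele frequency; SNPs with `p < p_threshold` are removed. If
#' any dosage is fractional (imputed data), hard calls cannot be derived and
#' the filter is skipped with a warning.
#'
#' @param genotypes Dosage tibble (`sample_id` plus one column per SNP).
#' @param p_threshold Removal threshold (default 5e-6).
#' @return The filtered genotype tibble with the per-SNP test in the
#'   `"hwe"` attribute.
#' @export
hwe_filter <- function(genotypes, p_threshold = 5e-6) {
  snps <- setdiff(names(genotypes), "sample_id")
  dos <- as.matrix(genotypes[snps])
  if (any(dos %% 1 != 0, na.rm = TRUE)) {
    warn("fractional dosages present; HWE filter skipped.")
    return(genotypes)
  }
  hwe <- purrr::map_dfr(snps, function(s) {
    d <- dos[, s]
    d <- d[!is.na(d)]
    obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    n <- sum(obs)
    p_hat <- (2 * obs[3] + obs[2]) / (2 * n)
    if (p_hat == 0 || p_hat == 1) {        # monomorphic: nothing to test
      return(tibble::tibble(snp_id = s, chi_sq = 0, p_value = 1))
    }
    expd <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    chi_sq <- sum((obs - expd)^2 / expd)
    tibble::tibble(snp_id = s, chi_sq = chi_sq,
                   p_value = pchisq(chi_sq, df = 1, lower.tail = FALSE))
  })
  drop <- hwe$snp_id[hwe$p_value < p_threshold]
  if (length(drop)) {
    inform(sprintf("HWE filter removed %d SNP(s): %s.", length(drop),
                   paste(drop, collapse = ", ")))
  }
  out <- genotypes[c("sample_id", setdiff(snps, drop))]
  attr(out, "hwe") <- hwe
  out
}

#' Candidate-SNP metabogenomic scan
#'
#' Tests every (SNP, metabolite) pair for a genetically determined metabotype
#' in the population controls: OLS of the log metabolite concentration on the
#' additive allele dosage plus nine cofactors (BMI, age, sex, HDL, LDL and
#' total cholesterol, triglycerides, hypertension, diabetes), with a
#' two-sided t-test on the dosage coefficient. SNPs that are monomorphic or
#' below the minor-allele-frequency floor are skipped with a warning.
#' Significance is Bonferroni-controlled over the full grid:
#' `alpha / (n_snps_tested * n_metabolites)` (0.05 over 32 SNPs x 456
#' metabolites gives 3.43e-6).
#'
#' @param genotypes Dosage tibble (`sample_id` plus SNP columns).
#' @param matrix A LOG-scale [metab_matrix()].
#' @param annotation Sample annotation; the scan keeps CONTROL samples with
#'   complete cofactors (listwise deletion).
#' @param alpha Family-wise level (default 0.05).
#' @param maf_min Minor allele frequency floor (default 0.01).
#' @param cofactors Annotation columns adjusted for.
#' @return A tibble of class `mgwas_table`, one row per (SNP, metabolite):
#'   `snp_id`, `metabolite_id`, `beta`, `se`, `t_stat`, `p_value`, `n_used`,
#'   `significant`; the per-test threshold is in the `"threshold"` attribute.
#' @export
snp_metabolite_scan <- function(genotypes, matrix, annotation, alpha = 0.05,
                                maf_min = 0.01,
                                cofactors = c("bmi", "age", "sex", "hdl",
                                              "ldl", "total_cholesterol",
                                              "triglycerides", "hypertension",
                                              "diabetes")) {
  ann <- validate_annotation(annotation, require = c("sample_id", "group",
                                                     "age", "sex"))
  miss_cof <- setdiff(setdiff(cofactors, c("age", "sex")), names(ann))
  if (length(miss_cof)) {
    abort(paste0("annotation lacks cofactor(s): ", paste(miss_cof, collapse = ", ")))
  }
  ann <- ann[ann$group == "CONTROL", , drop = FALSE]
  if (!nrow(ann)) abort("no CONTROL samples for the metabogenomic scan.")
  covars <- covariate_design(ann, cofactors)
  keep <- stats::complete.cases(covars)
  ann <- ann[keep, , drop = FALSE]
  covars <- covars[keep, , drop = FALSE]

  ids <- intersect(intersect(ann$sample_id, genotypes$sample_id),
                   matrix$sample_id)
  if (length(ids) < ncol(covars) + 4) abort("too few control samples with all data.")
  ann_i <- match(ids, ann$sample_id)
  vals <- metab_values(matrix)[match(ids, matrix$sample_id), , drop = FALSE]
  covars <- covars[ann_i, , drop = FALSE]
  snps <- setdiff(names(genotypes), "sample_id")
  dos <- as.matrix(genotypes[match(ids, genotypes$sample_id), snps, drop = FALSE])

  maf <- vapply(snps, function(s) {
    f <- mean(dos[, s], na.rm = TRUE) / 2
    min(f, 1 - f)
  }, numeric(1))
  tested <- snps[maf >= maf_min & maf > 0]
  skipped <- setdiff(snps, tested)
  if (length(skipped)) {
    warn(sprintf("skipping %d SNP(s) (monomorphic or MAF < %g): %s.",
                 length(skipped), maf_min, paste(skipped, collapse = ", ")))
  }
  if (!length(tested)) abort("no SNPs survive the MAF filter.")
  met_ids <- colnames(vals)
  threshold <- bonferroni_threshold(alpha, length(tested) * length(met_ids))
  out <- purrr::map_dfr(tested, function(s) {
    rows <- !is.na(dos[, s])
    X <- cbind(intercept = 1, dosage = dos[rows, s],
               covars[rows, , drop = FALSE])
    fit <- ols_scan(X, vals[rows, , drop = FALSE], term = 2L)
    tibble::tibble(snp_id = s, metabolite_id = met_ids,
                   beta = fit$beta, se = fit$se, t_stat = fit$t,
                   p_value = fit$p, n_used = fit$n_used,
                   significant = fit$p < threshold)
  })
  structure(out, threshold = threshold, alpha = alpha,
            n_snps_tested = length(tested),
            class = c("mgwas_table", class(out)))
}
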