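# Shared fixtures, all built in code.

# A reduced synthetic study: same structure as the default cohort but small
# enough for per-test use.
small_cohort <- function(seed = 42, n_control = 300, n_pd = 40, n_rls = 40,
                         n_metabolites = 30, ...) {
  n_eff <- max(1L, n_metabolites %/% 10L)
  simulate_cohort(sim_config(n_control = n_control, n_pd = n_pd, n_rls = n_rls,
                             n_metabolites = n_metabolites, n_days = 5,
                             n_snps = 8, n_group_effects = n_eff,
                             n_snp_effects = min(2L, n_metabolites - 2L * n_eff),
                             seed = seed, ...))
}

# Annotation without optional cofactors, for association-only tests.
toy_annotation <- function(n_control, n_case, case_group = "PD", seed = 1) {
  set.seed(seed)
  n <- n_control + n_case
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    group = factor(rep(c("CONTROL", case_group), c(n_control, n_case)),
                   levels = c("CONTROL", "PD", "RLS")),
    age = round(rnorm(n, 62, 8), 1),
    sex = factor(sample(c("MALE", "FEMALE"), n, replace = TRUE),
                 levels = c("MALE", "FEMALE")))
}

# Wrap a plain numeric matrix as a single-run-day metab_matrix.
as_metab <- function(values, scale = "LOG", sample_ids = NULL, day = "d1") {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met%03d", seq_len(ncol(values)))
  }
  metab_matrix(values, sample_ids %||% sprintf("S%04d", seq_len(n)),
               colnames(values), rep(day, n), scale = scale)
}

# Canonical unordered pair keys for edge set comparison.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Hand-built chain precision matrix (1-2, 2-3, ..., (p-1)-p) with off-diagonal
# weight -w; used as a closed-form GGM truth.
chain_precision <- function(p, w = 0.3) {
  omega <- diag(p)
  for (i in seq_len(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -w
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.1) diag(omega) <- diag(omega) + (0.1 - ev)
  omega
}

# Draw n samples from the zero-mean Gaussian with the given precision matrix.
rmvnorm_precision <- function(n, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- chol2inv(chol(omega))
  matrix(rnorm(n * nrow(omega)), n) %*% chol(sigma)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
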