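#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the structure of the study the pipeline targets: 1272
#' population controls, 82 Parkinson's disease (PD) and 95 restless legs
#' syndrome (RLS) cases, 456 serum metabolites measured over 20 run days on a
#' semi-quantitative MS platform, and 32 candidate SNPs.
#'
#' @param n_control,n_pd,n_rls Group sample counts.
#' @param n_metabolites Number of metabolites.
#' @param n_days Number of instrument run days; samples are assigned to days
#'   uniformly at random.
#' @param precision_density Fraction of nonzero off-diagonal entries in the
#'   ground-truth precision matrix (the GGM edge density).
#' @param day_effect_sd SD of the per-(day, metabolite) log-normal
#'   multiplicative batch factor on the raw scale.
#' @param n_group_effects Number of metabolites carrying a true mean shift for
#'   each of PD and RLS (disjoint sets).
#' @param effect_size_sd SD of the injected standardized (per latent-SD) mean
#'   shifts on the log scale.
#' @param censor_quantile Left-censoring point: per metabolite, raw values
#'   below this quantile of the control distribution become missing,
#'   emulating intensity-dependent MS dropout.
#' @param random_missing_rate Additional uniform random missingness.
#' @param n_snps Number of candidate SNPs.
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param n_snp_effects Number of (SNP, metabolite) pairs with a true
#'   per-allele effect.
#' @param snp_effect_size Per-allele shift, in latent-SD units, on the log
#'   scale for affected pairs.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 1272, n_pd = 82, n_rls = 95,
                       n_metabolites = 456, n_days = 20,
                       precision_density = 0.02, day_effect_sd = 0.3,
                       n_group_effects = 30, effect_size_sd = 0.5,
                       censor_quantile = 0.05, random_missing_rate = 0.01,
                       n_snps = 32, maf_range = c(0.1, 0.5),
                       n_snp_effects = 4, snp_effect_size = 0.3, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_control, n_pd, n_rls, n_metabolites, n_days, n_snps)
  if (any(counts <= 0)) abort("all counts must be positive.")
  if (precision_density <= 0 || precision_density >= 1) {
    abort("`precision_density` must lie in (0, 1).")
  }
  if (censor_quantile < 0 || censor_quantile >= 0.5) {
    abort("`censor_quantile` must lie in [0, 0.5).")
  }
  if (random_missing_rate < 0 || random_missing_rate >= 1) {
    abort("`random_missing_rate` must lie in [0, 1).")
  }
  if (day_effect_sd < 0 || effect_size_sd < 0) abort("SDs must be non-negative.")
  structure(cfg, class = "sim_config")
}

#' Generate a sparse symmetric positive-definite precision matrix
#'
#' Edge support is drawn Bernoulli(`density`) over the upper triangle; edge
#' precision entries get magnitudes uniform in `[0.3, 0.6]` with random sign,
#' which puts the implied partial correlations in the band typical of
#' biochemically adjacent metabolite pairs in serum metabolomics networks.
#' The diagonal starts at 1 and is raised uniformly just enough to keep the
#' minimum eigenvalue at or above 0.1, so the matrix is always positive
#' definite while hub nodes dilute their partial correlations only as much as
#' the spectrum requires. Draws are retried until every true edge implies a
#' partial correlation of magnitude at least `min_partial`.
#'
#' @param p Dimension (>= 2).
#' @param density Target off-diagonal fill in (0, 1); `density = 0` is allowed
#'   and yields the identity (no edges).
#' @param seed Optional integer seed.
#' @param min_partial Minimum implied partial correlation magnitude on edges.
#' @param max_tries Retries before giving up.
#' @return A `p x p` precision matrix with attribute `"edges"`: a two-column
#'   matrix of upper-triangle edge indices.
#' @export
generate_precision_matrix <- function(p, density, seed = NULL,
                                      min_partial = 0.05, max_tries = 10L) {
  if (p < 2) abort("`p` must be at least 2.")
  if (density < 0 || density >= 1) abort("`density` must lie in [0, 1).")
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  for (try in seq_len(max_tries)) {
    omega <- diag(p)
    on <- runif(nrow(ut)) < density
    if (any(on)) {
      vals <- runif(sum(on), 0.3, 0.6) * sample(c(-1, 1), sum(on), replace = TRUE)
      omega[ut[on, , drop = FALSE]] <- vals
      omega[ut[on, , drop = FALSE][, 2:1, drop = FALSE]] <- vals
    }
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0.1) diag(omega) <- diag(omega) + (0.1 - ev_min)
    pc <- precision_to_partial(omega)
    edges <- ut[on, , drop = FALSE]
    if (!nrow(edges) || all(abs(pc[edges]) >= min_partial)) {
      attr(omega, "edges") <- edges
      return(omega)
    }
  }
  abort("could not generate a conforming precision matrix; relax density or min_partial.")
}

# Partial correlations implied by a precision matrix: -w_ij / sqrt(w_ii w_jj),
# diagonal set to 1 by convention.
precision_to_partial <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' Simulate a complete synthetic study
#'
#' Draws latent log-abundances from the multivariate normal implied by a
#' sparse precision matrix, adds group mean shifts (PD and RLS, disjoint
#' metabolite sets) and additive per-allele genotype effects on the log scale,
#' exponentiates, multiplies by per-(day, metabolite) log-normal batch
#' factors, and finally applies left-censoring below each metabolite's
#' control-distribution quantile plus uniform random missingness. Ages are
#' truncated-normal (>= 18 years) with the study's group means/SDs
#' (controls 64.1 +/- 5.5, PD 70.0 +/- 8.7, RLS 60.6 +/- 17.0) and sex
#' proportions per group (47.7%, 50.0%, 70.5% female); the annotation also
#' carries the lipid/comorbidity cofactors the metabogenomic scan adjusts for.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `matrix` (RAW-scale
#'   [metab_matrix()]), `annotation`, `genotypes`, and `truth` (ground truth:
#'   precision matrix, true edges, injected effects, day factors, censoring
#'   thresholds and masks).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (2 * config$n_group_effects + config$n_snp_effects > config$n_metabolites) {
    abort("n_metabolites too small for the requested group and SNP effects.")
  }
  if (config$n_snp_effects > config$n_snps) {
    abort("`n_snp_effects` cannot exceed `n_snps`.")
  }
  set.seed(config$seed)
  p <- config$n_metabolites
  n <- config$n_control + config$n_pd + config$n_rls
  met_ids <- sprintf("met%03d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("snp%02d", seq_len(config$n_snps))

  omega <- generate_precision_matrix(p, config$precision_density)
  sigma <- chol2inv(chol(omega))
  sd_lat <- sqrt(diag(sigma))

  annotation <- simulate_annotation(config, sample_ids)

  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  dosages <- vapply(maf, function(f) rbinom(n, 2L, f), numeric(n))
  colnames(dosages) <- snp_ids
  genotypes <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                                tibble::as_tibble(dosages))

  # latent log-abundance: baseline + correlated noise + injected effects
  mu <- runif(p, 10, 14)
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  logx <- sweep(z, 2, mu, "+")

  eff_idx <- sample.int(p, 2 * config$n_group_effects)
  pd_idx <- eff_idx[seq_len(config$n_group_effects)]
  rls_idx <- eff_idx[config$n_group_effects + seq_len(config$n_group_effects)]
  pd_shift <- rnorm(config$n_group_effects, 0, config$effect_size_sd)
  rls_shift <- rnorm(config$n_group_effects, 0, config$effect_size_sd)
  is_pd <- annotation$group == "PD"
  is_rls <- annotation$group == "RLS"
  logx[is_pd, pd_idx] <- logx[is_pd, pd_idx] +
    rep(pd_shift * sd_lat[pd_idx], each = sum(is_pd))
  logx[is_rls, rls_idx] <- logx[is_rls, rls_idx] +
    rep(rls_shift * sd_lat[rls_idx], each = sum(is_rls))

  snp_eff <- tibble::tibble(snp_id = character(0), metabolite_id = character(0),
                            slope = numeric(0))
  if (config$n_snp_effects > 0) {
    eff_snps <- sample.int(config$n_snps, config$n_snp_effects, replace = FALSE)
    eff_mets <- sample(setdiff(seq_len(p), eff_idx), config$n_snp_effects)
    slopes <- config$snp_effect_size * sd_lat[eff_mets] *
      sample(c(-1, 1), config$n_snp_effects, replace = TRUE)
    for (k in seq_len(config$n_snp_effects)) {
      logx[, eff_mets[k]] <- logx[, eff_mets[k]] + slopes[k] * dosages[, eff_snps[k]]
    }
    snp_eff <- tibble::tibble(snp_id = snp_ids[eff_snps],
                              metabolite_id = met_ids[eff_mets],
                              slope = slopes)
  }

  day_labels <- sprintf("day%02d", seq_len(config$n_days))
  run_day <- sample(day_labels, n, replace = TRUE)
  day_factors <- matrix(exp(rnorm(config$n_days * p, 0, config$day_effect_sd)),
                        config$n_days, p,
                        dimnames = list(day_labels, met_ids))
  raw <- exp(logx) * day_factors[run_day, , drop = FALSE]

  # intensity-dependent (left-censored) missingness from the control
  # distribution, then independent random dropout
  is_ctrl <- annotation$group == "CONTROL"
  thresholds <- if (config$censor_quantile > 0) {
    apply(raw[is_ctrl, , drop = FALSE], 2, quantile,
          probs = config$censor_quantile)
  } else {
    rep(-Inf, p)
  }
  censored <- sweep(raw, 2, thresholds, "<")
  random_mask <- matrix(runif(n * p) < config$random_missing_rate, n, p) & !censored
  raw[censored | random_mask] <- NA_real_

  truth <- structure(list(
    precision_matrix = omega,
    true_edges = tibble::tibble(
      metabolite_a = met_ids[attr(omega, "edges")[, 1]],
      metabolite_b = met_ids[attr(omega, "edges")[, 2]],
      partial_r = precision_to_partial(omega)[attr(omega, "edges")]),
    group_effects = dplyr::bind_rows(
      tibble::tibble(contrast = "PD_vs_CONTROL", metabolite_id = met_ids[pd_idx],
                     shift = pd_shift, shift_log = pd_shift * sd_lat[pd_idx]),
      tibble::tibble(contrast = "RLS_vs_CONTROL", metabolite_id = met_ids[rls_idx],
                     shift = rls_shift, shift_log = rls_shift * sd_lat[rls_idx])),
    snp_effects = snp_eff,
    day_factors = day_factors,
    censor_thresholds = setNames(thresholds, met_ids),
    censored_mask = censored,
    random_mask = random_mask,
    latent_mu = setNames(mu, met_ids),
    latent_sd = setNames(sd_lat, met_ids),
    maf = setNames(maf, snp_ids)), class = "sim_truth")

  structure(list(
    matrix = metab_matrix(raw, sample_ids, met_ids, run_day, scale = "RAW"),
    annotation = annotation,
    genotypes = genotypes,
    truth = truth,
    config = config), class = "sim_cohort")
}

# Age/sex and the metabogenomic cofactors; distributions chosen to be
# realistic for an adult European population sample.
simulate_annotation <- function(config, sample_ids) {
  groups <- rep(GROUP_LEVELS, c(config$n_control, config$n_pd, config$n_rls))
  age_mean <- c(CONTROL = 64.1, PD = 70.0, RLS = 60.6)[groups]
  age_sd <- c(CONTROL = 5.5, PD = 8.7, RLS = 17.0)[groups]
  age <- rnorm(length(groups), age_mean, age_sd)
  while (any(age < 18)) {  # truncation at adulthood
    redo <- age < 18
    age[redo] <- rnorm(sum(redo), age_mean[redo], age_sd[redo])
  }
  p_female <- c(CONTROL = 0.477, PD = 0.500, RLS = 0.705)[groups]
  sex <- ifelse(runif(length(groups)) < p_female, "FEMALE", "MALE")
  n <- length(groups)
  hdl <- pmax(rnorm(n, 55, 15), 15)
  ldl <- pmax(rnorm(n, 140, 35), 30)
  trig <- exp(rnorm(n, log(120), 0.45))
  tibble::tibble(
    sample_id = sample_ids,
    group = factor(groups, GROUP_LEVELS),
    age = age,
    sex = factor(sex, SEX_LEVELS),
    bmi = pmax(rnorm(n, 27.5, 4.5), 15),
    hdl = hdl,
    ldl = ldl,
    total_cholesterol = hdl + ldl + trig / 5 + rnorm(n, 0, 10),
    triglycerides = trig,
    hypertension = runif(n) < 0.4,
    diabetes = runif(n) < 0.08)
}

#' Tabulate the ground truth of a simulated cohort
#'
#' One row per injected group effect, per injected SNP effect, and per true
#' network edge; used by the recovery tests.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @return A tibble with columns `kind`, `contrast`, `snp_id`,
#'   `metabolite_a`, `metabolite_b`, `metabolite_id`, `value`.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  dplyr::bind_rows(
    truth$group_effects |>
      dplyr::transmute(kind = "group_effect", contrast = .data$contrast,
                       metabolite_id = .data$metabolite_id, value = .data$shift),
    truth$snp_effects |>
      dplyr::transmute(kind = "snp_effect", snp_id = .data$snp_id,
                       metabolite_id = .data$metabolite_id, value = .data$slope),
    truth$true_edges |>
      dplyr::transmute(kind = "edge", metabolite_a = .data$metabolite_a,
                       metabolite_b = .data$metabolite_b, value = .data$partial_r))
}
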