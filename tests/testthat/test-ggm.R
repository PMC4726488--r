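test_that("residualization removes covariate structure and nothing else", {
  coh <- small_cohort(seed = 40, n_metabolites = 6)
  pp <- preprocess(coh$matrix, seed = 1)
  # empty covariate list: identity
  expect_identical(metab_values(residualize(pp$std_matrix, coh$annotation,
                                            character(0))),
                   metab_values(pp$std_matrix))

  # metabolite built as age + independent noise loses its age correlation
  set.seed(41)
  ann <- toy_annotation(500, 500)
  vals <- cbind(aged = scale(ann$age + rnorm(1000, 0, 5))[, 1],
                pure = rnorm(1000))
  m <- as_metab(scale(vals), scale = "STANDARDIZED",
                sample_ids = ann$sample_id)
  res <- residualize(m, ann, c("age", "sex"))
  expect_lt(abs(cor(metab_values(res)[, "aged"], ann$age)), 0.02)

  # a metabolite equal to a covariate dies with a named error
  vals2 <- cbind(isage = scale(ann$age)[, 1], ok = rnorm(1000))
  m2 <- as_metab(scale(vals2), scale = "STANDARDIZED",
                 sample_ids = ann$sample_id)
  expect_error(residualize(m2, ann, c("age", "sex")), "isage")
})

test_that("shrinkage estimation recovers known partial correlation structure", {
  # identity precision: every partial correlation is sampling noise
  x <- rmvnorm_precision(5000, diag(10), seed = 50)
  est <- estimate_shrinkage(x)
  off <- est$partial_correlation[upper.tri(est$partial_correlation)]
  expect_lt(max(abs(off)), 0.05)

  # forcing lambda = 1 gives the identity: all partials exactly zero
  est1 <- estimate_shrinkage(x, lambda = 1)
  expect_equal(max(abs(est1$partial_correlation[upper.tri(diag(10))])), 0)

  # 3-chain truth: A-B and B-C present, A-C conditionally independent
  om <- chain_precision(3, 0.3)
  truth_pc <- metabnet:::precision_to_partial(om)
  xc <- rmvnorm_precision(5000, om, seed = 51)
  estc <- estimate_shrinkage(xc)
  pc <- estc$partial_correlation
  expect_lt(abs(pc[1, 3]), 0.05)
  expect_lt(abs(pc[1, 2] - truth_pc[1, 2]), 0.05)
  expect_lt(abs(pc[2, 3] - truth_pc[2, 3]), 0.05)
})

test_that("the analytic shrinkage intensity matches a brute-force oracle", {
  set.seed(52)
  x <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 1, 1, 2, 1, 1))
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  est <- estimate_shrinkage(x)
  # direct evaluation: var-hat of each r_ij from the standardized products
  n <- nrow(x); xs <- scale(x)
  num <- den <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    w <- xs[, i] * xs[, j]
    r <- sum(w) / (n - 1)
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
    den <- den + r^2
  }
  expect_equal(est$lambda, min(1, num / den), tolerance = 1e-12)
})

test_that("lambda* stays in [0,1] and decreases with sample size", {
  om <- chain_precision(8, 0.35)
  lambdas <- vapply(c(50, 500, 5000), function(n) {
    estimate_shrinkage(rmvnorm_precision(n, om, seed = 53))$lambda
  }, numeric(1))
  expect_true(all(lambdas >= 0 & lambdas <= 1))
  expect_true(all(diff(lambdas) < 0))

  # p > n still yields a usable, bounded estimate
  set.seed(54)
  wide <- matrix(rnorm(20 * 40), 20, 40)
  estw <- estimate_shrinkage(wide)
  expect_gte(estw$lambda, 0)
  expect_lte(estw$lambda, 1)
  expect_true(all(is.finite(estw$partial_correlation)))
})

test_that("partial correlation matrices are symmetric and bounded", {
  for (seed in 55:57) {
    x <- rmvnorm_precision(200, chain_precision(12, 0.3), seed = seed)
    pc <- estimate_shrinkage(x)$partial_correlation
    expect_lt(max(abs(pc - t(pc))), 1e-10)
    expect_true(all(abs(pc) <= 1 + 1e-12))
    expect_equal(unname(diag(pc)), rep(1, 12))
  }
})

test_that("Fisher-z p-values match the closed form and the permutation null", {
  expect_equal(fisher_z_pvalue(0, 100), 1)
  expect_equal(fisher_z_pvalue(0.5, 100, 0),
               2 * pnorm(-atanh(0.5) * sqrt(97)), tolerance = 1e-15)
  expect_error(fisher_z_pvalue(0.3, 4, 2), "n - 3 - q")

  # null data: the Fisher-z Pearson test is calibrated across ~1000 pairs
  x <- rmvnorm_precision(500, diag(46), seed = 58)   # 1035 pairs
  pv <- edge_pvalues(estimate_shrinkage(x))
  frac <- mean(pv$pearson_p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  # Fisher-z and permutation agree within a factor of 2 for moderate p-values
  xs <- rmvnorm_precision(200, chain_precision(5, 0.35), seed = 59)
  est <- estimate_shrinkage(xs)
  fz <- edge_pvalues(est, method = "FISHER_Z")
  pm <- edge_pvalues(est, method = "PERMUTATION", B = 2000, seed = 60)
  both <- dplyr::inner_join(fz, pm, by = c("metabolite_a", "metabolite_b"),
                            suffix = c("_fz", "_pm"))
  mod <- dplyr::filter(both, pearson_p_fz > 0.01, pearson_p_fz < 1)
  expect_true(all(mod$pearson_p_pm / mod$pearson_p_fz < 2 &
                    mod$pearson_p_pm / mod$pearson_p_fz > 0.5))
  modp <- dplyr::filter(both, partial_p_fz > 0.01, partial_p_fz < 1)
  expect_true(all(modp$partial_p_pm / modp$partial_p_fz < 2 &
                    modp$partial_p_pm / modp$partial_p_fz > 0.5))

  # infeasible Fisher degrees of freedom fall back to permutation
  tiny <- rmvnorm_precision(10, diag(9), seed = 61)
  expect_warning(pv2 <- edge_pvalues(estimate_shrinkage(tiny), B = 99),
                 "falling back")
  expect_true(all(pv2$partial_p >= 1 / 100))
})

test_that("the dual rule calls no edges on identity-precision data", {
  false_edges <- 0
  for (seed in 62:66) {
    x <- rmvnorm_precision(2000, diag(20), seed = seed)
    m <- as_metab(scale(x), scale = "STANDARDIZED")
    net <- build_network(m, covariates = character(0))
    false_edges <- false_edges + sum(net$edges$passes_dual_rule)
  }
  expect_lte(false_edges, 1)
})

test_that("chain-structured truth is recovered exactly at n = 2000", {
  om <- chain_precision(10, 0.35)
  x <- rmvnorm_precision(2000, om, seed = 67)
  m <- as_metab(scale(x), scale = "STANDARDIZED")
  net <- build_network(m, covariates = character(0))
  called <- tidy(net, filtered = TRUE)
  truth <- edge_key(sprintf("met%03d", 1:9), sprintf("met%03d", 2:10))
  expect_setequal(edge_key(called$metabolite_a, called$metabolite_b), truth)
})

test_that("collider structure triggers the sign-artifact exclusion", {
  # x and y independent causes of z: marginally uncorrelated, but negatively
  # partially correlated given their common effect
  set.seed(68)
  n <- 3000
  x <- rnorm(n); y <- rnorm(n)
  z <- x + y + rnorm(n, 0, 0.3)
  m <- as_metab(scale(cbind(cx = x, cy = y, cz = z)), scale = "STANDARDIZED")
  net <- build_network(m, covariates = character(0))
  row <- net$edges[net$edges$metabolite_a == "cx" &
                     net$edges$metabolite_b == "cy", ]
  expect_lt(abs(row$pearson_r), 0.05)
  expect_lt(row$partial_r, 0)
  expect_true(row$artifact_flag)
  expect_false(row$passes_dual_rule)
})

test_that("build_network residualizes disease status before correlating", {
  # a strong PD shift on two otherwise-independent metabolites induces a
  # spurious marginal correlation; conditioning on the group removes it
  cfg <- sim_config(n_control = 700, n_pd = 700, n_rls = 50, n_metabolites = 12,
                    precision_density = 1e-9, n_group_effects = 2,
                    effect_size_sd = 2.5, n_snp_effects = 0,
                    censor_quantile = 0, random_missing_rate = 0,
                    day_effect_sd = 0, seed = 69)
  coh <- simulate_cohort(cfg)
  pd_mets <- coh$truth$group_effects |>
    dplyr::filter(contrast == "PD_vs_CONTROL", abs(shift) > 1)
  skip_if(nrow(pd_mets) < 2)  # needs two strong shifts from the draw
  pp <- preprocess(coh$matrix, seed = 1)
  raw_net <- build_network(pp$std_matrix, covariates = character(0))
  adj_net <- build_network(pp$std_matrix, coh$annotation)
  pair <- sort(pd_mets$metabolite_id[1:2])
  pick <- function(net) net$edges[net$edges$metabolite_a == pair[1] &
                                    net$edges$metabolite_b == pair[2], ]
  expect_gt(abs(pick(raw_net)$pearson_r), abs(pick(adj_net)$pearson_r))
  expect_lt(abs(pick(adj_net)$pearson_r), 0.1)
})

test_that("annotated networks carry association attributes on the nodes", {
  coh <- small_cohort(seed = 70, n_metabolites = 10)
  pp <- preprocess(coh$matrix, seed = 1)
  sc <- run_scan(pp$log_matrix, coh$annotation)
  net <- build_network(pp$std_matrix, coh$annotation)
  an <- annotate_network(net, sc)
  expect_identical(nrow(an$nodes), 10L)
  expect_true(all(c("PD_vs_CONTROL_direction", "PD_vs_CONTROL_mlog10p",
                    "RLS_vs_CONTROL_direction", "PD_vs_RLS_mlog10p")
                  %in% names(an$nodes)))
  # the node attribute sign equals the association direction
  ref <- sc[sc$contrast == "PD_vs_CONTROL", ]
  merged <- dplyr::inner_join(an$nodes, tibble::as_tibble(ref),
                              by = "metabolite_id")
  expect_identical(merged$PD_vs_CONTROL_direction, merged$direction)
  expect_true(all(merged$PD_vs_CONTROL_mlog10p > 0))

  # nodes absent from the association table are flagged, not dropped
  expect_warning(an2 <- annotate_network(net, sc[sc$metabolite_id != "met003", ]),
                 "absent")
  expect_true(is.na(an2$nodes$PD_vs_CONTROL_mlog10p[
    an2$nodes$metabolite_id == "met003"]))
})

test_that("tidy and glance expose the fit in broom style", {
  coh <- small_cohort(seed = 71, n_metabolites = 8)
  pp <- preprocess(coh$matrix, seed = 1)
  net <- build_network(pp$std_matrix, coh$annotation)
  td <- tidy(net)
  expect_identical(nrow(td), 28L)
  gl <- glance(net)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_edges, sum(td$passes_dual_rule))
  expect_identical(gl$n_pairs, 28L)
  est <- net$estimate
  expect_identical(nrow(tidy(est)), 28L)
  expect_identical(glance(est)$lambda, net$lambda)
})
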