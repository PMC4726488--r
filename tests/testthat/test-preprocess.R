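test_that("run-day normalization reproduces the hand-computed example", {
  # one metabolite over two days: day medians 3 and 12, overall median 6
  m <- metab_matrix(matrix(c(2, 4, 8, 16), 4, 1), paste0("s", 1:4), "m1",
                    run_day = c("d1", "d1", "d2", "d2"))
  norm <- run_day_normalize(m)
  expect_equal(unname(metab_values(norm)[, 1]), c(4, 8, 4, 8))
  # day medians of the normalized values equal the pre-normalization overall
  expect_equal(median(metab_values(norm)[1:2, 1]), 6)
  expect_equal(median(metab_values(norm)[3:4, 1]), 6)
})

test_that("normalization identity cases: single day, constant values", {
  single <- as_metab(matrix(c(3, 9, 27, 5, 2, 11), 3, 2), scale = "RAW")
  expect_equal(metab_values(run_day_normalize(single)), metab_values(single))

  const <- metab_matrix(matrix(7, 4, 2), paste0("s", 1:4), c("m1", "m2"),
                        run_day = c("a", "a", "b", "b"))
  expect_equal(unname(metab_values(run_day_normalize(const))),
               matrix(7, 4, 2))
})

test_that("normalization is idempotent and invariant to day rescaling", {
  coh <- small_cohort(seed = 10, n_metabolites = 12, censor_quantile = 0,
                      random_missing_rate = 0)
  m <- coh$matrix
  once <- run_day_normalize(m)
  again <- run_day_normalize(
    metab_matrix(metab_values(once), once$sample_id, metabolite_ids(once),
                 once$run_day, scale = "RAW"))
  expect_equal(metab_values(again), metab_values(once), tolerance = 1e-12)

  # rescaling one day's values of one metabolite by c > 0: the day-median
  # division cancels c exactly, so the normalized profile is unchanged up to
  # the metabolite-wide overall-median factor -- and exactly unchanged when
  # the rescaled day does not move the overall median
  vals <- metab_values(m)
  day1 <- m$run_day == m$run_day[1]
  vals[day1, 3] <- vals[day1, 3] * 17.3
  rescaled <- metab_matrix(vals, m$sample_id, metabolite_ids(m), m$run_day,
                           scale = "RAW")
  renorm <- metab_values(run_day_normalize(rescaled))
  ratio <- renorm[, 3] / metab_values(once)[, 3]
  expect_lt(diff(range(ratio)), 1e-12)                  # single common factor
  expect_equal(renorm[, -3], metab_values(once)[, -3],  # others untouched
               tolerance = 1e-12)

  # exact invariance when the day's values already sit above the overall
  # median and are scaled further up, so the median sample is unmoved
  vals2 <- metab_values(m)
  top_day <- m$run_day == m$run_day[1]
  vals2[top_day, 5] <- max(vals2[, 5]) * (1 + seq_len(sum(top_day)))
  base <- metab_matrix(vals2, m$sample_id, metabolite_ids(m), m$run_day,
                       scale = "RAW")
  vals3 <- vals2
  vals3[top_day, 5] <- vals3[top_day, 5] * 4.2
  up <- metab_matrix(vals3, m$sample_id, metabolite_ids(m), m$run_day,
                     scale = "RAW")
  expect_equal(metab_values(run_day_normalize(up)),
               metab_values(run_day_normalize(base)), tolerance = 1e-12)

  # and the full pipeline's standardized output is exactly invariant
  std_once <- standardize(log_transform(once))
  std_resc <- standardize(log_transform(run_day_normalize(rescaled)))
  expect_equal(metab_values(std_resc), metab_values(std_once),
               tolerance = 1e-10)
})

test_that("normalization preserves missingness and warns on empty days", {
  vals <- matrix(c(2, 4, NA, 16, 1, 2, 3, 4), 4, 2)
  m <- metab_matrix(vals, paste0("s", 1:4), c("m1", "m2"),
                    run_day = c("d1", "d1", "d2", "d2"))
  norm <- run_day_normalize(m)
  expect_true(is.na(metab_values(norm)[3, 1]))
  expect_identical(sum(is.na(metab_values(norm))), 1L)

  # a (day, metabolite) cell with no observations at all stays missing
  vals2 <- matrix(c(2, 4, NA, NA, 1, 2, 3, 4), 4, 2)
  m2 <- metab_matrix(vals2, paste0("s", 1:4), c("m1", "m2"),
                     run_day = c("d1", "d1", "d2", "d2"))
  expect_warning(norm2 <- run_day_normalize(m2), "no observed values")
  expect_true(all(is.na(metab_values(norm2)[3:4, 1])))
})

test_that("log transform is elementwise ln with missing preserved", {
  m <- as_metab(matrix(c(1, exp(1), 4, NA, 8, 16), 3, 2), scale = "NORMALIZED")
  lg <- log_transform(m)
  expect_equal(unname(metab_values(lg)[, 1]), c(0, 1, log(4)))
  expect_true(is.na(metab_values(lg)[1, 2]))
  # the two-day worked example carried through the log step
  norm <- run_day_normalize(metab_matrix(matrix(c(2, 4, 8, 16), 4, 1),
                                         paste0("s", 1:4), "m1",
                                         c("d1", "d1", "d2", "d2")))
  expect_equal(unname(metab_values(log_transform(norm))[, 1]),
               log(c(4, 8, 4, 8)))
})

test_that("missingness filter applies strict thresholds, metabolites first", {
  vals <- matrix(rnorm(50), 10, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  vals[1:3, 1] <- NA          # 30% missing -> dropped
  vals[1:2, 2] <- NA          # exactly 20% -> retained
  m <- as_metab(vals, scale = "LOG")
  res <- filter_missingness(m)
  expect_identical(res$report$dropped_metabolites, "m1")
  expect_true("m2" %in% metabolite_ids(res$matrix))
  # over the 4 retained metabolites, samples 1-2 are 25% missing -> dropped
  expect_identical(res$report$dropped_samples, c("S0001", "S0002"))
  expect_identical(res$report$n_missing_remaining, 0L)

  # a sample that only looks bad because of a doomed metabolite is kept
  vals2 <- matrix(rnorm(40), 10, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
  vals2[1:6, 1] <- NA                       # metabolite dropped (60%)
  vals2[1, 1] <- NA                         # sample 1: 1/4 missing overall,
  res2 <- filter_missingness(as_metab(vals2, scale = "LOG"))
  expect_identical(res2$report$dropped_metabolites, "m1")
  expect_identical(res2$report$dropped_samples, character(0))

  # complete matrix: nothing dropped, empty report
  res3 <- filter_missingness(as_metab(matrix(rnorm(20), 5, 4), scale = "LOG"))
  expect_identical(res3$report$dropped_metabolites, character(0))
  expect_identical(res3$report$dropped_samples, character(0))
  expect_identical(res3$report$n_missing_remaining, 0L)

  expect_error(filter_missingness(m, metabolite_threshold = 0),
               NA)  # thresholds at the boundary are legal
  all_bad <- as_metab(matrix(NA_real_, 4, 2), scale = "LOG")
  expect_error(filter_missingness(all_bad), "all metabolites")
})

test_that("filtering never increases a retained metabolite's missing fraction", {
  coh <- small_cohort(seed = 17, n_metabolites = 25, censor_quantile = 0.12,
                      random_missing_rate = 0.03)
  lg <- log_transform(run_day_normalize(coh$matrix))
  before <- colMeans(is.na(metab_values(lg)))
  res <- filter_missingness(lg)
  after <- colMeans(is.na(metab_values(res$matrix)))
  expect_true(all(after <= before[names(after)] + 1e-12))
})

test_that("chained imputation fills cells without touching observed values", {
  coh <- small_cohort(seed = 8, n_metabolites = 15)
  flt <- filter_missingness(log_transform(run_day_normalize(coh$matrix)))
  miss <- is.na(metab_values(flt$matrix))
  imp <- impute_chained(flt$matrix)
  vi <- metab_values(imp)
  expect_false(anyNA(vi))
  expect_identical(attr(imp, "n_imputed"), sum(miss))
  expect_identical(vi[!miss], metab_values(flt$matrix)[!miss])

  # a complete matrix passes through unchanged
  done <- impute_chained(imp)
  expect_identical(metab_values(done), vi)
  expect_identical(attr(done, "n_imputed"), 0L)
})

test_that("imputation tracks the conditional structure of the data", {
  # metabolite uncorrelated with all others: imputed value near its mean
  set.seed(31)
  vals <- matrix(rnorm(800), 200, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  vals[1, 4] <- NA
  imp <- impute_chained(as_metab(vals, scale = "LOG"))
  mu <- mean(vals[-1, 4])
  expect_lt(abs(metab_values(imp)[1, 4] - mu), 3 * sd(vals[-1, 4]))

  # perfectly collinear pair: the exact linear relation is recovered
  set.seed(32)
  x <- rnorm(100)
  vals2 <- cbind(m1 = x, m2 = 2 * x + 1, m3 = rnorm(100))
  truth <- vals2[7, 2]
  vals2[7, 2] <- NA
  imp2 <- impute_chained(as_metab(vals2, scale = "LOG"))
  expect_lt(abs(metab_values(imp2)[7, 2] - truth), 1e-6)
})

test_that("standardization yields exact zero mean and unit variance", {
  m <- as_metab(matrix(c(1, 2, 3, 5, 5, 8), 3, 2), scale = "LOG")
  std <- standardize(m)
  vals <- metab_values(std)
  expect_lt(max(abs(colMeans(vals))), 1e-10)
  expect_lt(max(abs(apply(vals, 2, sd) - 1)), 1e-10)
  expect_equal(unname(vals[, 1]), c(-1, 0, 1))

  # standardizing already-standardized values changes nothing
  again <- standardize(metab_matrix(vals, std$sample_id, metabolite_ids(std),
                                    std$run_day, scale = "LOG"))
  expect_equal(metab_values(again), vals, tolerance = 1e-12)

  degenerate <- as_metab(cbind(m1 = c(1, 1, 1), m2 = c(1, 2, 3)), scale = "LOG")
  expect_error(standardize(degenerate), "m1")
})

test_that("the preprocess wrapper chains all stages and reports them", {
  coh <- small_cohort(seed = 12, n_metabolites = 15)
  pp <- preprocess(coh$matrix, seed = 1)
  expect_identical(metab_scale(pp$log_matrix), "LOG")
  expect_identical(metab_scale(pp$std_matrix), "STANDARDIZED")
  expect_false(anyNA(metab_values(pp$std_matrix)))
  expect_identical(pp$report$imputed_cell_count,
                   sum(is.na(metab_values(filter_missingness(
                     log_transform(run_day_normalize(coh$matrix)))$matrix))))
  expect_s3_class(pp$report$day_median_table, "tbl_df")
  expect_identical(nrow(pp$report$day_median_table), 5L)   # one row per day
})
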