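# Multi-response ordinary least squares.
#
# Fits y ~ X for every column of Y with one QR of the shared design, and
# returns inference on one coefficient (`term`). Columns of Y containing NA
# are refit on their complete rows. Used by the association, ratio, and
# metabogenomic scans; cross-checked against stats::lm in the test suite.
#
# X: n x k numeric design (complete, includes intercept).
# Y: n x m numeric response matrix (NA allowed).
# term: column index of the coefficient of interest.
#
# Returns a list: beta, se, t, p, n_used (length m), df, residuals (n x m,
# NA where y missing), and xtx_inv_jj for the complete-row design.
ols_scan <- function(X, Y, term) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) abort("too few samples for the regression design.")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  xtx_inv <- chol2inv(qr.R(qrX))
  complete <- !colSums(is.na(Y))
  m <- ncol(Y)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  n_used <- rep(NA_integer_, m)
  resid <- matrix(NA_real_, n, m, dimnames = dimnames(Y))
  df <- n - k
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    coefs <- qr.coef(qrX, Yc)
    res <- Yc - X %*% coefs
    sigma2 <- colSums(res^2) / df
    beta[complete] <- coefs[term, ]
    se[complete] <- sqrt(sigma2 * xtx_inv[term, term])
    resid[, complete] <- res
    n_used[complete] <- n
  }
  for (j in which(!complete)) {
    ok <- !is.na(Y[, j])
    nj <- sum(ok)
    if (nj <= k + 1) next
    qj <- qr(X[ok, , drop = FALSE])
    if (qj$rank < k) next
    cj <- qr.coef(qj, Y[ok, j])
    rj <- Y[ok, j] - X[ok, , drop = FALSE] %*% cj
    s2 <- sum(rj^2) / (nj - k)
    beta[j] <- cj[term]
    se[j] <- sqrt(s2 * chol2inv(qr.R(qj))[term, term])
    n_used[j] <- nj
    resid[ok, j] <- rj
  }
  tval <- beta / se
  dfs <- n_used - k
  pval <- 2 * pt(-abs(tval), dfs)
  list(beta = unname(beta), se = unname(se), t = unname(tval),
       p = unname(pval), n_used = unname(n_used),
       df = df, residuals = resid, xtx_inv_jj = xtx_inv[term, term])
}

# Design matrix and response rows for a two-group contrast: rows restricted
# to the contrast's groups with complete covariates (listwise deletion).
contrast_design <- function(annotation, ctr) {
  ann <- validate_annotation(annotation)
  in_groups <- ann$group %in% c(ctr$case_group, ctr$reference_group)
  if (!any(ann$group == ctr$case_group) || !any(ann$group == ctr$reference_group)) {
    abort(sprintf("contrast '%s': one of the groups has no samples.", ctr$name))
  }
  covars <- covariate_design(ann, ctr$covariates)
  cov_ok <- if (ncol(covars)) stats::complete.cases(covars) else TRUE
  rows <- which(in_groups & cov_ok)
  X <- cbind(intercept = 1,
             case = as.numeric(ann$group[rows] == ctr$case_group),
             covars[rows, , drop = FALSE])
  list(rows = rows, X = X, sample_id = ann$sample_id[rows])
}

# Restrict an annotation table to the samples present in the matrix (samples
# removed by the missingness filter simply leave the analysis).
align_annotation <- function(matrix, annotation) {
  ann <- annotation[annotation$sample_id %in% matrix$sample_id, , drop = FALSE]
  if (!nrow(ann)) abort("no annotated samples present in the metabolite matrix.")
  ann
}
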