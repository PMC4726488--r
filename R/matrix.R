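#' Metabolite intensity table
#'
#' The pipeline's central container is an ordinary tibble in wide layout:
#' one row per sample, a `sample_id` column, a `run_day` column, and one
#' numeric column per metabolite. A `scale` attribute records where the table
#' sits in the fixed transformation chain
#' `RAW -> NORMALIZED -> LOG -> STANDARDIZED`; each preprocessing verb checks
#' the scale of its input and stamps the scale of its output, so a table
#' cannot silently skip a step. Missing intensities are `NA`.
#'
#' @param values Numeric matrix, samples in rows and metabolites in columns.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param metabolite_ids Character vector of unique metabolite identifiers.
#' @param run_day Character (or coercible) vector of per-sample run-day
#'   labels. Labels are opaque: only equality matters.
#' @param scale One of `"RAW"`, `"NORMALIZED"`, `"LOG"`, `"STANDARDIZED"`.
#'
#' @return A tibble of class `metab_matrix` with columns `sample_id`,
#'   `run_day`, then one column per metabolite.
#' @examples
#' m <- metab_matrix(matrix(1:6, 2), c("s1", "s2"), c("m1", "m2", "m3"),
#'                   run_day = c("d1", "d1"))
#' metab_scale(m)
#' @export
metab_matrix <- function(values, sample_ids, metabolite_ids, run_day,
                         scale = "RAW") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(sample_ids) || ncol(values) != length(metabolite_ids)) {
    abort("`values` dimensions must match `sample_ids` x `metabolite_ids`.")
  }
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids.")
  if (anyDuplicated(metabolite_ids)) abort("duplicate metabolite ids.")
  if (length(run_day) != length(sample_ids)) {
    abort("`run_day` must have one label per sample.")
  }
  scale <- match.arg(scale, SCALE_LEVELS)
  if (scale %in% c("RAW", "NORMALIZED") && any(values <= 0, na.rm = TRUE)) {
    abort(sprintf("%s-scale intensities must be strictly positive where observed.",
                  scale))
  }
  out <- tibble::tibble(sample_id = as.character(sample_ids),
                        run_day = as.character(run_day))
  vals <- tibble::as_tibble(values, .name_repair = "minimal")
  names(vals) <- as.character(metabolite_ids)
  out <- dplyr::bind_cols(out, vals)
  new_metab_matrix(out, scale)
}

new_metab_matrix <- function(tbl, scale) {
  structure(tbl,
            scale = match.arg(scale, SCALE_LEVELS),
            class = c("metab_matrix", class(tibble::tibble())))
}

#' @rdname metab_matrix
#' @param x A `metab_matrix`.
#' @export
metab_scale <- function(x) attr(x, "scale")

#' @rdname metab_matrix
#' @export
metabolite_ids <- function(x) setdiff(names(x), c("sample_id", "run_day"))

#' Extract the numeric intensity matrix
#'
#' @param x A `metab_matrix`.
#' @return Numeric matrix with sample ids as rownames and metabolite ids as
#'   colnames.
#' @export
metab_values <- function(x) {
  ids <- metabolite_ids(x)
  m <- as.matrix(as.data.frame(x)[, ids, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

# Replace the intensity block, keeping sample columns, and restamp the scale.
set_metab_values <- function(x, values, scale = metab_scale(x)) {
  ids <- metabolite_ids(x)
  stopifnot(ncol(values) == length(ids), nrow(values) == nrow(x))
  out <- tibble::as_tibble(as.data.frame(x)[c("sample_id", "run_day")])
  vals <- tibble::as_tibble(values, .name_repair = "minimal")
  names(vals) <- colnames(values) %||% ids
  new_metab_matrix(dplyr::bind_cols(out, vals), scale)
}

# Guard used by every preprocessing verb.
check_scale <- function(x, expected, op) {
  if (!inherits(x, "metab_matrix")) {
    abort(sprintf("`%s()` expects a metab_matrix; see `metab_matrix()`.", op))
  }
  if (!identical(metab_scale(x), expected)) {
    abort(sprintf("`%s()` expects a %s-scale matrix, got %s.",
                  op, expected, metab_scale(x)))
  }
  invisible(x)
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("# metab_matrix: %d samples x %d metabolites [%s scale]\n",
              nrow(x), length(metabolite_ids(x)), metab_scale(x)))
  NextMethod()
}

#' Define a case/reference contrast
#'
#' A contrast names the case and reference group of a two-group comparison and
#' the annotation columns used as adjustment covariates in the per-metabolite
#' linear model.
#'
#' @param case_group,reference_group Group labels among
#'   `"CONTROL"`, `"PD"`, `"RLS"`; must differ.
#' @param covariates Character vector of annotation column names adjusted for;
#'   defaults to age and sex.
#' @param name Contrast label; defaults to `"CASE_vs_REFERENCE"`.
#' @return A list of class `contrast`.
#' @examples
#' contrast("PD", "CONTROL")
#' @export
contrast <- function(case_group, reference_group,
                     covariates = c("age", "sex"), name = NULL) {
  case_group <- match.arg(case_group, GROUP_LEVELS)
  reference_group <- match.arg(reference_group, GROUP_LEVELS)
  if (identical(case_group, reference_group)) {
    abort("case and reference group must differ.")
  }
  structure(list(name = name %||% paste0(case_group, "_vs_", reference_group),
                 case_group = case_group,
                 reference_group = reference_group,
                 covariates = covariates),
            class = "contrast")
}

#' The study's three standard contrasts
#'
#' PD vs control, RLS vs control, and the direct PD vs RLS comparison, each
#' adjusted for age and sex.
#'
#' @param covariates Covariates shared by all three contrasts.
#' @return List of three [contrast()] objects.
#' @export
default_contrasts <- function(covariates = c("age", "sex")) {
  list(contrast("PD", "CONTROL", covariates),
       contrast("RLS", "CONTROL", covariates),
       contrast("PD", "RLS", covariates))
}

# Validate a sample annotation tibble; returns it with enum columns as factors.
validate_annotation <- function(annotation, require = c("sample_id", "group",
                                                        "age", "sex")) {
  missing_cols <- setdiff(require, names(annotation))
  if (length(missing_cols)) {
    abort(paste0("annotation lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(annotation$sample_id)) abort("duplicate sample ids in annotation.")
  bad_group <- setdiff(unique(as.character(annotation$group)), GROUP_LEVELS)
  if (length(bad_group)) {
    abort(sprintf("unknown group label(s) %s; allowed: %s",
                  paste(bad_group, collapse = ", "),
                  paste(GROUP_LEVELS, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(as.character(annotation$sex)), SEX_LEVELS)
  if (length(bad_sex)) {
    abort(sprintf("unknown sex label(s) %s; allowed: %s",
                  paste(bad_sex, collapse = ", "),
                  paste(SEX_LEVELS, collapse = ", ")))
  }
  if (any(annotation$age <= 0, na.rm = TRUE)) abort("ages must be positive.")
  annotation$group <- factor(as.character(annotation$group), GROUP_LEVELS)
  annotation$sex <- factor(as.character(annotation$sex), SEX_LEVELS)
  annotation
}

# Numeric design columns for a covariate list. Sex is coded MALE=0/FEMALE=1;
# group indicators PD/RLS are 0/1; logicals become 0/1.
covariate_design <- function(annotation, covariates) {
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow = nrow(annotation), ncol = 0))
  }
  cols <- lapply(covariates, function(cv) {
    if (cv == "sex") {
      as.numeric(annotation$sex == "FEMALE")
    } else if (cv == "group") {
      cbind(PD = as.numeric(annotation$group == "PD"),
            RLS = as.numeric(annotation$group == "RLS"))
    } else if (cv %in% names(annotation)) {
      v <- annotation[[cv]]
      if (is.logical(v)) as.numeric(v) else as.numeric(v)
    } else {
      abort(sprintf("covariate '%s' absent from annotation.", cv))
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- make.unique(unlist(lapply(seq_along(covariates), function(i) {
    if (is.matrix(cols[[i]])) colnames(cols[[i]]) else covariates[[i]]
  })))
  mat
}
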