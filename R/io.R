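#' Read a sample-by-metabolite intensity table
#'
#' Expects a delimited text file with one row per sample, a `sample_id`
#' column, a run-day column, and one numeric column per metabolite. Empty
#' cells and the string `"NA"` are read as missing; any other unparseable
#' cell also becomes missing and the total is reported.
#'
#' @param path File path.
#' @param delim Field delimiter (`","` default; use `"\t"` for TSV).
#' @param run_day_col Name of the run-day column (default `"run_day"`).
#' @param scale Scale to stamp on the result (files normally hold RAW data).
#' @return A [metab_matrix()].
#' @export
read_metabolite_matrix <- function(path, delim = ",", run_day_col = "run_day",
                                   scale = "RAW") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()))
  if (!run_day_col %in% names(raw)) {
    abort(sprintf("file '%s' lacks the run-day column '%s'.", path, run_day_col))
  }
  if (!"sample_id" %in% names(raw)) abort("file lacks a 'sample_id' column.")
  if (anyDuplicated(raw$sample_id)) abort("duplicate sample ids in file.")
  ids <- setdiff(names(raw), c("sample_id", run_day_col))
  vals <- suppressWarnings(
    vapply(raw[ids], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, ids))
  n_na_cells <- sum(is.na(vals))
  n_blank <- sum(is.na(as.matrix(raw[ids])) | as.matrix(raw[ids]) %in% c("", "NA"))
  if (n_na_cells > n_blank) {
    inform(sprintf("%d unparseable cell(s) set to missing.", n_na_cells - n_blank))
  }
  if (n_na_cells > 0) {
    inform(sprintf("read %d missing value(s) from '%s'.", n_na_cells, basename(path)))
  }
  metab_matrix(vals, raw$sample_id, ids, raw[[run_day_col]], scale = scale)
}

#' Write a metabolite table to delimited text
#'
#' Missing values are written as `"NA"`; columns are `sample_id`, `run_day`,
#' then metabolites in their current order, so [read_metabolite_matrix()]
#' round-trips the file.
#'
#' @param x A [metab_matrix()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_metabolite_matrix <- function(x, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(as.data.frame(x)), path, delim = delim,
                     na = "NA")
  invisible(path)
}

#' Read the sample annotation table
#'
#' Requires columns `sample_id`, `group`, `age`, `sex`; the optional
#' covariates `bmi`, `hdl`, `ldl`, `total_cholesterol`, `triglycerides`,
#' `hypertension`, `diabetes` are parsed when present (the last two as
#' 0/1 or TRUE/FALSE). Group must be one of CONTROL/PD/RLS and sex one of
#' MALE/FEMALE; anything else is a hard error.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble, one row per sample, `group` and `sex` as factors.
#' @export
read_annotation <- function(path, delim = ",") {
  ann <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_double()))
  for (bin in intersect(c("hypertension", "diabetes"), names(ann))) {
    ann[[bin]] <- as.logical(ann[[bin]])
  }
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation Annotation tibble to write.
#' @export
write_annotation <- function(annotation, path, delim = ",") {
  out <- annotation
  out$group <- as.character(out$group)
  out$sex <- as.character(out$sex)
  for (bin in intersect(c("hypertension", "diabetes"), names(out))) {
    out[[bin]] <- as.integer(out[[bin]])
  }
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read candidate-SNP genotypes
#'
#' Genotypes are additive alternate-allele dosages in `[0, 2]`. Two formats
#' are supported: a delimited table (`sample_id` column plus one numeric
#' column per SNP) and plain-text VCF, in which dosage is the count of
#' alternate alleles in the `GT` field. Half-missing genotypes (`./0` etc.)
#' are treated as missing; multi-allelic VCF records are skipped with a
#' warning.
#'
#' @param path File path.
#' @param format `"TABLE"` or `"VCF"`.
#' @param delim Delimiter for `format = "TABLE"`.
#' @return A tibble with `sample_id` plus one dosage column per SNP.
#' @export
read_genotypes <- function(path, format = c("TABLE", "VCF"), delim = ",") {
  format <- match.arg(format)
  if (format == "TABLE") {
    g <- readr::read_delim(path, delim = delim, col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_double()))
    check_dosages(g)
    return(g)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic VCF record(s).", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  snp_ids <- fix$ID[!multi]
  snp_ids[is.na(snp_ids) | snp_ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[!multi][is.na(snp_ids) | snp_ids == "."]
  dose <- apply(gt, c(1, 2), gt_to_dosage)
  out <- tibble::tibble(sample_id = colnames(gt))
  dm <- tibble::as_tibble(t(dose), .name_repair = "minimal")
  names(dm) <- snp_ids
  dplyr::bind_cols(out, dm)
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

check_dosages <- function(g) {
  vals <- as.matrix(g[setdiff(names(g), "sample_id")])
  if (any(vals < 0 | vals > 2, na.rm = TRUE)) {
    abort("dosages must lie in [0, 2].")
  }
  invisible(g)
}

#' @rdname read_genotypes
#' @param genotypes Dosage tibble to write as a table.
#' @export
write_genotypes <- function(genotypes, path, delim = ",") {
  readr::write_delim(genotypes, path, delim = delim, na = "NA")
  invisible(path)
}

#' Write an association (or ratio / mGWAS) table as TSV
#'
#' Column order is fixed so downstream tooling sees a stable header.
#'
#' @param table Result tibble from [run_scan()], [ratio_scan()] or
#'   [snp_metabolite_scan()].
#' @param path Output path.
#' @export
write_association_table <- function(table, path) {
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}

#' Export an annotated network
#'
#' Writes the dual-rule-filtered network with node attributes (per-contrast
#' effect sign and -log10 p) and edge attributes (Pearson and partial r and
#' their p-values) either as GraphML or as a plain edge list TSV.
#'
#' @param network A [annotate_network()] result (class `metab_network`), or a
#'   `ggm` fit (exported without node annotation).
#' @param path Output path.
#' @param format `"GRAPHML"` or `"EDGELIST"`.
#' @export
write_network <- function(network, path, format = c("GRAPHML", "EDGELIST")) {
  format <- match.arg(format)
  g <- as_igraph_network(network)
  if (format == "GRAPHML") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), path, na = "NA")
  }
  invisible(path)
}

as_igraph_network <- function(network) {
  if (inherits(network, "ggm")) network <- annotate_network(network, NULL)
  if (!inherits(network, "metab_network")) {
    abort("`network` must be a metab_network or ggm object.")
  }
  edges <- network$edges
  nodes <- network$nodes
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[c("metabolite_a", "metabolite_b",
                          setdiff(names(edges), c("metabolite_a", "metabolite_b")))]),
    directed = FALSE,
    vertices = as.data.frame(nodes))
  g
}
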