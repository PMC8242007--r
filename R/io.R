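#' Read and write gene-level log2 expression matrices
#'
#' The on-disk format is a TSV whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values are written with 15
#' significant digits so a write/read round trip is an identity to numeric
#' text precision.
#'
#' @param path file path.
#' @return `read_expression` returns a numeric matrix (genes x samples) with
#'   unique dimnames and finite values.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column and >=1 sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated gene identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  sid <- colnames(df)[-1L]
  if (anyDuplicated(sid)) stop("duplicated sample identifier(s): ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (any(!is.finite(m))) stop("non-finite expression values in ", path)
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with one row per sample. Required columns: `sample_id`, `group`,
#' `batch`, `time_to_delivery` (weeks, > 0). Optional columns (e.g.
#' `gestational_age_at_amnio`, `reference_group`, clinical binaries) are
#' carried through untouched.
#'
#' @param path CSV file path.
#' @return data.frame of per-sample metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "batch", "time_to_delivery")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) stop("metadata missing required column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  if (any(!is.finite(df$time_to_delivery)) || any(df$time_to_delivery <= 0))
    stop("time_to_delivery must be finite and > 0 (weeks)")
  df
}

#' @rdname read_metadata
#' @param samples data.frame of sample metadata.
#' @export
write_metadata <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Set names must be unique and sets non-empty. Sets are written sorted by
#' name so output files are diffable.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a `gene_sets` object (named list of character
#'   vectors) with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                        paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated gene-set name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  structure(sets, class = "gene_sets",
            descriptions = stats::setNames(vapply(fields, `[[`, "", 2L), nm))
}

#' @rdname read_gmt
#' @param sets named list of character vectors (or `gene_sets` object).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  desc <- attr(sets, "descriptions")
  ord <- order(names(sets))
  lines <- vapply(ord, function(i) {
    d <- if (!is.null(desc)) desc[[names(sets)[i]]] else "na"
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a tissue reference atlas
#'
#' TSV with tissues in rows (first column `tissue`) and genes in columns;
#' linear-scale nonnegative values.
#'
#' @param path TSV file path.
#' @return a `tissue_atlas` object.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  tis <- as.character(df[[1L]])
  if (anyDuplicated(tis)) stop("duplicated tissue label(s)")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicated gene identifier(s)")
  if (any(m < 0)) stop("atlas values must be nonnegative")
  rownames(m) <- tis
  structure(list(values = m, tissues = tis, genes = colnames(m)),
            class = "tissue_atlas")
}

#' @rdname read_atlas
#' @param atlas a `tissue_atlas` object.
#' @export
write_atlas <- function(atlas, path) {
  df <- data.frame(tissue = atlas$tissues,
                   format(atlas$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("tissue", atlas$genes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with study defaults
#'
#' Thresholds and sizes used across the pipeline. Defaults are the published
#' analysis settings: differential expression called at fold change > 1.25
#' and q < 0.1; enrichment and signature comparisons at q < 0.05; tissue
#' specificity screen at a 30-fold median ratio with top-20 signature genes;
#' 1000-tree random forests; risk horizons at 24 h, 1 week and 2 weeks.
#'
#' @param ... named overrides of the defaults listed below.
#' @return an object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    fc_threshold = 1.25,
    de_q_threshold = 0.1,
    enrich_q_threshold = 0.05,
    signature_q_threshold = 0.05,
    specificity_ratio = 30,
    top_n_signature = 20L,
    n_trees = 1000L,
    auroc_horizons_weeks = c(24 / 168, 1, 2),
    target_size = 50L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over[setdiff(names(over), unknown)])
  stopifnot(cfg$fc_threshold > 1, cfg$de_q_threshold > 0,
            cfg$enrich_q_threshold > 0, cfg$signature_q_threshold > 0,
            cfg$specificity_ratio > 0, cfg$top_n_signature >= 1,
            cfg$n_trees >= 1, all(cfg$auroc_horizons_weeks > 0),
            cfg$target_size >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified keys take the [pipeline_config()] defaults; unknown keys warn
#' and are ignored.
#'
#' @param path `.yaml`/`.yml` or `.json` file; an empty file yields all
#'   defaults.
#' @return a `pipeline_config` object.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Write the cohort truth ledger as JSON
#'
#' @param truth the `truth` component of an [generate_cohort()] result.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(response_genes = truth$response_genes,
         response_sign = truth$response_sign,
         inflammation = as.list(truth$inflammation)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
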