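#' Read a gene-by-sample expression matrix from TSV
#'
#' Reads a dense tab-separated expression table (first column gene identifier,
#' header row of sample identifiers, remaining cells non-negative numbers on an
#' FPKM/RSEM-like scale). Gene identifier version suffixes are stripped. Cells
#' that are missing, non-numeric or negative, ragged rows, and duplicated gene
#' rows are all rejected with messages naming the offending gene and sample.
#'
#' @param tsv_path Path to the TSV file.
#' @param dataset_id Dataset label attached to the matrix (defaults to the
#'   file name without extension).
#' @return An `expr_tbl`: a tibble with a `gene_id` column followed by one
#'   numeric column per sample, carrying a `dataset_id` attribute.
#' @export
read_expression <- function(tsv_path, dataset_id = NULL) {
  check_file_exists(tsv_path, "expression TSV")
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(tsv_path))

  lines <- readLines(tsv_path, warn = FALSE)
  if (length(lines) < 2L) {
    abort(sprintf("expression TSV '%s' has no data rows", tsv_path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # A leading corner cell for the gene-id column is optional in the header.
  body_width <- length(fields[[2]])
  sample_ids <- if (length(header) == body_width) header[-1] else header
  if (length(sample_ids) != body_width - 1L) {
    abort(sprintf(
      "expression TSV '%s': header has %d sample ids but rows have %d value columns",
      tsv_path, length(sample_ids), body_width - 1L
    ))
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("expression TSV '%s': duplicated sample ids", tsv_path))
  }

  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != body_width)) {
    bad <- which(widths != body_width)[1]
    abort(sprintf(
      "expression TSV '%s': ragged row %d (gene '%s') has %d fields, expected %d",
      tsv_path, bad + 1L, body[[bad]][1], widths[bad], body_width
    ))
  }

  gene_ids <- strip_version(map_chr(body, 1L))
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort(sprintf("expression TSV '%s': duplicate gene row '%s'", tsv_path, dup))
  }

  values <- matrix(
    suppressWarnings(as.numeric(unlist(map(body, `[`, -1L)))),
    nrow = length(body), ncol = body_width - 1L, byrow = TRUE,
    dimnames = list(gene_ids, sample_ids)
  )
  raw <- matrix(unlist(map(body, `[`, -1L)),
    nrow = length(body), byrow = TRUE
  )
  bad_cell <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    abort(sprintf(
      "expression TSV '%s': non-numeric value '%s' for gene '%s', sample '%s'",
      tsv_path, raw[bad_cell[1, 1], bad_cell[1, 2]],
      gene_ids[bad_cell[1, 1]], sample_ids[bad_cell[1, 2]]
    ))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    abort(sprintf(
      "expression TSV '%s': negative value %g for gene '%s', sample '%s'",
      tsv_path, values[neg[1, 1], neg[1, 2]],
      gene_ids[neg[1, 1]], sample_ids[neg[1, 2]]
    ))
  }

  out <- expr_tbl_from_matrix(values, dataset_id)
  log_info(sprintf(
    "expression '%s': %d genes x %d samples read", dataset_id,
    nrow(values), ncol(values)
  ))
  out
}

#' Build an expression table from a numeric matrix
#'
#' @param values Numeric gene-by-sample matrix with row and column names.
#' @param dataset_id Dataset label.
#' @return An `expr_tbl` tibble.
#' @export
expr_tbl_from_matrix <- function(values, dataset_id) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) {
    abort("expression values must be non-negative")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene ids in expression matrix")
  }
  out <- as_tibble(values, rownames = "gene_id")
  attr(out, "dataset_id") <- dataset_id
  class(out) <- c("expr_tbl", class(out))
  out
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf(
    "<expr_tbl> dataset '%s': %d genes x %d samples\n",
    dataset_id(x), nrow(x), ncol(x) - 1L
  ))
  NextMethod()
}

#' Dataset identifier of an expression table
#' @param x An `expr_tbl`.
#' @return The dataset id string.
#' @export
dataset_id <- function(x) {
  attr(x, "dataset_id") %||% "dataset"
}

#' Sample identifiers of an expression table
#' @param x An `expr_tbl`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(x) {
  setdiff(names(x), "gene_id")
}

# Internal: numeric matrix view (genes x samples).
expr_matrix <- function(x) {
  m <- as.matrix(x[, sample_ids(x), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample. Numbers are written with full round-trip precision.
#'
#' @param x An `expr_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_tbl"))
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Filter an expression matrix to expressed genes
#'
#' Removes genes below the expression detection threshold before any
#' co-expression analysis. In `"mean"` mode a gene is kept when its mean
#' expression exceeds the threshold; in `"fraction"` mode when it exceeds the
#' threshold in at least half of the samples. The sample set is unchanged.
#' The default threshold of 0.001 suits FPKM/RSEM-scale values.
#'
#' @param x An `expr_tbl`.
#' @param threshold Non-negative expression threshold (default 0.001).
#' @param mode `"mean"` or `"fraction"`.
#' @return The filtered `expr_tbl`.
#' @export
filter_expressed <- function(x, threshold = 0.001, mode = c("mean", "fraction")) {
  stopifnot(inherits(x, "expr_tbl"), is.numeric(threshold), threshold >= 0)
  mode <- match.arg(mode)
  m <- expr_matrix(x)
  keep <- switch(mode,
    mean = rowMeans(m) > threshold,
    fraction = rowMeans(m > threshold) >= 0.5
  )
  if (!any(keep)) {
    abort(sprintf(
      "no genes pass the expression threshold %g (%s mode) in dataset '%s'",
      threshold, mode, dataset_id(x)
    ))
  }
  log_info(sprintf(
    "expression filter (%s > %g): %d of %d genes retained in '%s'",
    mode, threshold, sum(keep), nrow(m), dataset_id(x)
  ))
  out <- x[keep, , drop = FALSE]
  attr(out, "dataset_id") <- dataset_id(x)
  class(out) <- class(x)
  out
}

#' Split an expression table by gene class
#'
#' Partitions a combined expression matrix into lncRNA and protein-coding
#' sub-matrices using a gene catalog; genes absent from the catalog are
#' dropped with a log message.
#'
#' @param x An `expr_tbl`.
#' @param catalog A `gene_catalog`.
#' @return List with elements `lnc` and `pcg`, both `expr_tbl`.
#' @export
split_expression <- function(x, catalog) {
  stopifnot(inherits(x, "expr_tbl"), inherits(catalog, "gene_catalog"))
  cls <- catalog$biotype_class[match(x$gene_id, catalog$gene_id)]
  n_drop <- sum(is.na(cls))
  if (n_drop > 0L) {
    log_info(sprintf(
      "split_expression: %d genes absent from catalog dropped", n_drop
    ))
  }
  subset_cls <- function(which_cls) {
    out <- x[!is.na(cls) & cls == which_cls, , drop = FALSE]
    attr(out, "dataset_id") <- dataset_id(x)
    class(out) <- class(x)
    out
  }
  list(lnc = subset_cls("LNCRNA"), pcg = subset_cls("PROTEIN_CODING"))
}
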