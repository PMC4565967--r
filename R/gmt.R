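#' Read a gene-set collection from a GMT file
#'
#' Parses the Broad GMT dialect: one term per line, tab-separated fields
#' `term_id`, `description`, then one or more member genes. Member lists are
#' deduplicated and version-stripped; lines with fewer than three fields and
#' duplicated term identifiers are rejected. The description field is kept as
#' the term name, which is why this reader does not delegate to list-only GMT
#' loaders.
#'
#' @param gmt_path Path to the GMT file.
#' @param category Function-space category of the collection: one of
#'   `"GO_BP"`, `"GO_CC"`, `"GO_MF"`, `"KEGG"`.
#' @return A `gene_sets` tibble with columns `category`, `term_id`,
#'   `term_name`, `genes` (list column of member ids), `n_genes`.
#' @export
read_gmt <- function(gmt_path, category = c("GO_BP", "GO_CC", "GO_MF", "KEGG")) {
  check_file_exists(gmt_path, "GMT file")
  category <- match.arg(category)
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("GMT file '%s' is empty", gmt_path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf(
      "malformed GMT line %d in '%s': expected at least 3 tab-separated fields, found %d",
      short[1], gmt_path, lengths(fields)[short[1]]
    ))
  }
  out <- tibble(
    category = category,
    term_id = map_chr(fields, 1L),
    term_name = map_chr(fields, 2L),
    genes = map(fields, ~ unique(strip_version(.x[-c(1L, 2L)])))
  ) |>
    mutate(n_genes = lengths(.data$genes))
  if (anyDuplicated(out$term_id)) {
    abort(sprintf(
      "GMT file '%s': duplicated term id '%s'",
      gmt_path, out$term_id[duplicated(out$term_id)][1]
    ))
  }
  if (any(out$n_genes == 0L)) {
    abort(sprintf(
      "GMT file '%s': term '%s' has an empty member list",
      gmt_path, out$term_id[out$n_genes == 0L][1]
    ))
  }
  log_info(sprintf(
    "gene sets '%s' (%s): %d terms, %d distinct genes",
    basename(gmt_path), category, nrow(out), length(unique(unlist(out$genes)))
  ))
  new_gene_sets(out)
}

new_gene_sets <- function(x) {
  structure(as_tibble(x), class = c("gene_sets", class(as_tibble(x))))
}

#' Write a gene-set collection to GMT
#'
#' Canonical form: members sorted and deduplicated, so reading the written
#' file back yields an identical collection.
#'
#' @param x A `gene_sets` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- map_chr(seq_len(nrow(x)), function(i) {
    paste(c(x$term_id[i], x$term_name[i], sort(unique(x$genes[[i]]))),
      collapse = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}
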