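#' GENCODE long non-coding RNA gene biotypes
#'
#' The gene biotypes that GENCODE collects in its long non-coding RNA gene
#' annotation. Used by [read_gene_catalog()] in single-GTF mode to decide which
#' `gene_type` values count as lncRNA; recent GENCODE releases collapse most of
#' these into the single biotype `"lncRNA"`.
#'
#' @return Character vector of biotype strings.
#' @export
#' @examples
#' gencode_lncrna_biotypes()
gencode_lncrna_biotypes <- function() {
  c(
    "lncRNA", "lincRNA", "antisense", "sense_intronic", "sense_overlapping",
    "3prime_overlapping_ncRNA", "3prime_overlapping_ncrna",
    "bidirectional_promoter_lncRNA", "macro_lncRNA", "non_coding",
    "processed_transcript"
  )
}

#' Read a gene catalog from GTF annotation
#'
#' Builds a catalog of lncRNA and protein-coding genes from GENCODE-style GTF
#' annotation. Two modes are supported: a single GTF classified on its
#' `gene_type`/`gene_biotype` attribute, or the GENCODE convention of a main
#' GTF (protein-coding genes taken from the `protein_coding` biotype) plus a
#' separate lncRNA GTF whose every gene is treated as lncRNA. Genes of any
#' other biotype are dropped, and `.N` identifier version suffixes are
#' stripped. A gene present in both files keeps the lncRNA class.
#'
#' @param gtf_path Path to a GTF file (9 tab-separated columns with an
#'   attribute block carrying at least `gene_id`).
#' @param lncrna_gtf Optional path to a separate lncRNA-only GTF. When given,
#'   all of its genes are classified `LNCRNA` and `gtf_path` contributes only
#'   `protein_coding` genes.
#' @param lncrna_biotypes Biotypes counted as lncRNA in single-GTF mode.
#'   Defaults to the GENCODE long non-coding set ([gencode_lncrna_biotypes()]).
#' @return A `gene_catalog` tibble with columns `gene_id` (version-stripped,
#'   unique), `symbol`, and `biotype_class` (`"LNCRNA"` or `"PROTEIN_CODING"`).
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "SIM", "gene", 1, 1000, ".", "+", ".",
#'   'gene_id "G1.2"; gene_name "MALAT1"; gene_type "lncRNA";',
#'   sep = "\t"), gtf)
#' read_gene_catalog(gtf)
read_gene_catalog <- function(gtf_path, lncrna_gtf = NULL,
                              lncrna_biotypes = gencode_lncrna_biotypes()) {
  check_file_exists(gtf_path, "GTF file")
  main <- parse_gtf_genes(gtf_path)

  if (is.null(lncrna_gtf)) {
    catalog <- main |>
      mutate(biotype_class = case_when(
        .data$biotype %in% lncrna_biotypes ~ "LNCRNA",
        .data$biotype == "protein_coding" ~ "PROTEIN_CODING",
        TRUE ~ NA_character_
      ))
  } else {
    check_file_exists(lncrna_gtf, "lncRNA GTF file")
    lnc <- parse_gtf_genes(lncrna_gtf) |>
      mutate(biotype_class = "LNCRNA")
    pcg <- main |>
      filter(.data$biotype == "protein_coding") |>
      mutate(biotype_class = "PROTEIN_CODING") |>
      filter(!.data$gene_id %in% lnc$gene_id)
    catalog <- bind_rows(lnc, pcg)
  }

  n_seen <- nrow(catalog)
  catalog <- catalog |>
    filter(!is.na(.data$biotype_class)) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "symbol", "biotype_class")

  if (nrow(catalog) == 0L) {
    abort("no lncRNA or protein-coding genes retained from GTF annotation")
  }
  log_info(sprintf(
    "gene catalog: %d genes retained (%d LNCRNA, %d PROTEIN_CODING), %d other-biotype genes dropped",
    nrow(catalog), sum(catalog$biotype_class == "LNCRNA"),
    sum(catalog$biotype_class == "PROTEIN_CODING"), n_seen - nrow(catalog)
  ))
  new_gene_catalog(catalog)
}

new_gene_catalog <- function(x) {
  structure(as_tibble(x), class = c("gene_catalog", class(as_tibble(x))))
}

# Validate the 9-field GTF layout line by line (rtracklayer's own errors carry
# no line numbers), then hand parsing proper to rtracklayer::import.
parse_gtf_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields != 9L]
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed GTF line %d in '%s': expected 9 tab-separated fields, found %d",
      bad[1], path, nfields[which(body == bad[1])]
    ))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(meta)) {
    abort(sprintf("GTF '%s' has no gene_id attribute", path))
  }
  biotype_col <- intersect(c("gene_type", "gene_biotype"), names(meta))[1]
  tibble(
    gene_id = strip_version(as.character(meta$gene_id)),
    symbol = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else {
      strip_version(as.character(meta$gene_id))
    },
    biotype = if (!is.na(biotype_col)) {
      as.character(meta[[biotype_col]])
    } else {
      NA_character_
    }
  ) |>
    filter(!is.na(.data$gene_id), nzchar(.data$gene_id)) |>
    distinct(.data$gene_id, .keep_all = TRUE)
}

#' Resolve gene names against a catalog
#'
#' Maps user-supplied gene names to catalog identifiers. Each name is matched
#' first as an exact (version-stripped) gene identifier, then as an exact
#' symbol. Symbols shared by more than one gene are reported as ambiguous and
#' never silently expanded.
#'
#' @param names Character vector of gene identifiers or symbols.
#' @param catalog A `gene_catalog` from [read_gene_catalog()].
#' @return A list with `resolved` (tibble of `input`, `gene_id`,
#'   `biotype_class`), `unresolved` (character), and `ambiguous` (character).
#' @export
resolve_genes <- function(names, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  names <- strip_version(as.character(names))
  symbol_counts <- table(catalog$symbol)

  hit <- function(nm) {
    by_id <- which(catalog$gene_id == nm)
    if (length(by_id) == 1L) {
      return(list(status = "resolved", row = by_id))
    }
    by_sym <- which(catalog$symbol == nm)
    if (length(by_sym) == 1L) {
      return(list(status = "resolved", row = by_sym))
    }
    if (length(by_sym) > 1L) {
      return(list(status = "ambiguous", row = NA_integer_))
    }
    list(status = "unresolved", row = NA_integer_)
  }

  hits <- map(names, hit)
  status <- map_chr(hits, "status")
  rows <- map_int(hits, "row")
  resolved_idx <- status == "resolved"
  list(
    resolved = tibble(
      input = names[resolved_idx],
      gene_id = catalog$gene_id[rows[resolved_idx]],
      biotype_class = catalog$biotype_class[rows[resolved_idx]]
    ),
    unresolved = names[status == "unresolved"],
    ambiguous = names[status == "ambiguous"]
  )
}
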