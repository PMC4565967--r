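# Orchestration layer behind the CLI subcommands. Each cmd_*() reads inputs,
# runs the corresponding analysis modules, writes deterministic TSV outputs
# plus a JSON run manifest, and returns the in-memory result invisibly.

#' Write a run manifest
#'
#' Records the command, the fully resolved configuration, MD5 content hashes
#' of every input file, the package version, and the seed (when randomness is
#' involved). Re-running a command with an identical manifest reproduces its
#' outputs byte for byte; nothing time-dependent is recorded.
#'
#' @param out_dir Output directory.
#' @param command Subcommand name.
#' @param config_snapshot Named list of resolved parameters.
#' @param inputs Character vector of input file paths to hash.
#' @param seed Optional integer seed.
#' @return Path of the manifest written, invisibly.
#' @export
write_manifest <- function(out_dir, command, config_snapshot, inputs = character(),
                           seed = NULL) {
  hashes <- tools::md5sum(inputs)
  names(hashes) <- basename(inputs) # keyed by name so reruns from any
  # working directory produce identical manifests
  manifest <- list(
    command = command,
    tool_version = as.character(packageVersion("lncoex")),
    config_snapshot = config_snapshot,
    input_hashes = as.list(hashes),
    seed = seed
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

ensure_out_dir <- function(out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) abort(sprintf("cannot create output directory '%s'", out))
  invisible(out)
}

# Shared front half of the analysis commands: read annotation + expression,
# resolve the query genes (error listing offenders), split by biotype, filter
# to expressed genes, and run the association stage.
run_cegs_stage <- function(expression, gtf, genes, config, lncrna_gtf = NULL,
                           dataset_id = NULL) {
  catalog <- read_gene_catalog(gtf, lncrna_gtf = lncrna_gtf)
  expr <- read_expression(expression, dataset_id = dataset_id)
  res <- resolve_genes(genes, catalog)
  if (length(res$unresolved) > 0L || length(res$ambiguous) > 0L) {
    abort(sprintf(
      "could not resolve gene name(s)%s%s",
      if (length(res$unresolved)) {
        paste0(" — unresolved: ", paste(res$unresolved, collapse = ", "))
      } else "",
      if (length(res$ambiguous)) {
        paste0(" — ambiguous symbols: ", paste(res$ambiguous, collapse = ", "))
      } else ""
    ))
  }
  non_lnc <- res$resolved$input[res$resolved$biotype_class != "LNCRNA"]
  if (length(non_lnc) > 0L) {
    abort(sprintf(
      "not annotated as lncRNA: %s", paste(non_lnc, collapse = ", ")
    ))
  }
  parts <- split_expression(expr, catalog)
  lnc_f <- filter_expressed(parts$lnc, config$expr_threshold, config$expr_filter_mode)
  pcg_f <- filter_expressed(parts$pcg, config$expr_threshold, config$expr_filter_mode)
  result <- compute_cegs(lnc_f, pcg_f, res$resolved$gene_id, config)
  list(result = result, catalog = catalog)
}

#' Run the CEGs module: co-expressed genes of a lncRNA list in one dataset
#'
#' Reads an expression matrix and GTF annotation, resolves the query lncRNAs,
#' applies the expression filter, tests every lncRNA–protein-coding pair, and
#' writes `associations.tsv`, `cegs.tsv` and `manifest.json` to `out`.
#'
#' @param expression Path to the expression TSV (lncRNAs and protein-coding
#'   genes in one matrix; the catalog splits them).
#' @param gtf Path to the gene-annotation GTF.
#' @param genes Character vector of lncRNA ids or symbols to analyse.
#' @param out Output directory.
#' @param config A [coex_config()].
#' @param lncrna_gtf Optional separate lncRNA GTF (see [read_gene_catalog()]).
#' @param dataset_id Optional dataset label.
#' @return The `coex_result`, invisibly.
#' @export
cmd_cegs <- function(expression, gtf, genes, out, config = coex_config(),
                     lncrna_gtf = NULL, dataset_id = NULL) {
  ensure_out_dir(out)
  stage <- run_cegs_stage(expression, gtf, genes, config, lncrna_gtf, dataset_id)
  result <- stage$result
  write_associations(result, file.path(out, "associations.tsv"))
  write_cegs(result, file.path(out, "cegs.tsv"))
  write_manifest(out, "cegs",
    config_snapshot = c(unclass(config), list(genes = genes)),
    inputs = c(expression, gtf, lncrna_gtf)
  )
  invisible(result)
}

#' Run the CEGsFuncs module: combinatorial enrichment in one dataset
#'
#' Computes the CEG sets of the query lncRNAs, merges them within the dataset
#' by union or intersection, and tests the merged set for enrichment against
#' each supplied gene-set collection. Writes `cegs.tsv`, `merged_cegs.tsv`,
#' one `enrichment_<CATEGORY>.tsv` per collection, and `manifest.json`.
#' An empty merged set yields empty outputs with a warning, not an error.
#'
#' @inheritParams cmd_cegs
#' @param gmt Named character vector of GMT paths; names are categories
#'   (`GO_BP`, `GO_CC`, `GO_MF`, `KEGG`).
#' @param within `"union"` or `"intersection"` across the query lncRNAs.
#' @param enrichment A [enrich_config()].
#' @return List with `result` (`coex_result`), `merged` (gene-id vector), and
#'   `enrichment` (named list of `coex_enrichment`), invisibly.
#' @export
cmd_cegsfuncs <- function(expression, gtf, gmt, genes, out,
                          within = c("union", "intersection"),
                          config = coex_config(),
                          enrichment = enrich_config(),
                          lncrna_gtf = NULL, dataset_id = NULL) {
  within <- match.arg(within)
  ensure_out_dir(out)
  if (is.null(names(gmt)) || any(!nzchar(names(gmt)))) {
    abort("gmt must be a named vector of paths, named by category (GO_BP, GO_CC, GO_MF, KEGG)")
  }
  stage <- run_cegs_stage(expression, gtf, genes, config, lncrna_gtf, dataset_id)
  result <- stage$result
  lnc_queried <- unique(result$associations$lnc_id)
  merged <- merge_within_dataset(result, within, lnc_ids = lnc_queried)
  write_cegs(result, file.path(out, "cegs.tsv"))
  readr::write_tsv(tibble(gene_id = merged), file.path(out, "merged_cegs.tsv"))

  enr <- run_enrichment_files(merged, gmt, result$expressed_pcgs, enrichment, out)
  write_manifest(out, "cegsfuncs",
    config_snapshot = c(
      unclass(config),
      list(genes = genes, within = within),
      unclass(enrichment)
    ),
    inputs = c(expression, gtf, unname(gmt), lncrna_gtf)
  )
  invisible(list(result = result, merged = merged, enrichment = enr))
}

run_enrichment_files <- function(merged, gmt, expressed_pcgs, enrichment, out) {
  if (length(merged) == 0L) {
    warn("merged CEG set is empty; writing empty enrichment results")
  }
  enr <- imap(gmt, function(path, category) {
    sets <- read_gmt(path, category = category)
    e <- if (length(merged) == 0L) {
      suppressWarnings(enrich(character(0), sets, expressed_pcgs, enrichment))
    } else {
      enrich(merged, sets, expressed_pcgs, enrichment)
    }
    write_enrichment(e, file.path(out, sprintf("enrichment_%s.tsv", category)))
    e
  })
  enr
}

#' Run the merge-CEGsFuncs module: cross-dataset combinatorial enrichment
#'
#' Two-level merge: within each dataset the CEG sets of the query lncRNAs are
#' merged first (`within` mode), then the per-dataset sets are merged across
#' datasets (`across` mode), and the integrative set is tested for
#' enrichment. The enrichment background is the union of the datasets'
#' expressed protein-coding genes. Writes per-dataset CEG files, a
#' `merged_cegs.tsv` membership report with per-dataset indicator columns,
#' enrichment tables, and `manifest.json`. A single dataset reduces exactly
#' to [cmd_cegsfuncs()].
#'
#' @param datasets List of per-dataset specs, each a list with `expression`
#'   (TSV path) and optional `dataset_id`.
#' @inheritParams cmd_cegsfuncs
#' @param across `"union"` or `"intersection"` across datasets.
#' @return List with `merged` (`merged_cegs`), `results` (per-dataset
#'   `coex_result` list), and `enrichment`, invisibly.
#' @export
cmd_merge_cegsfuncs <- function(datasets, gtf, gmt, genes, out,
                                within = c("union", "intersection"),
                                across = c("union", "intersection"),
                                config = coex_config(),
                                enrichment = enrich_config(),
                                lncrna_gtf = NULL) {
  within <- match.arg(within)
  across <- match.arg(across)
  ensure_out_dir(out)
  if (length(datasets) < 1L) abort("at least one dataset is required")

  results <- map(datasets, function(ds) {
    stage <- run_cegs_stage(
      ds$expression, gtf, genes, config, lncrna_gtf,
      dataset_id = ds$dataset_id
    )
    stage$result
  })
  ids <- map_chr(results, "dataset_id")
  if (anyDuplicated(ids)) abort("duplicate dataset_id across datasets")
  names(results) <- ids

  per_dataset <- map(results, function(res) {
    merge_within_dataset(res, within, lnc_ids = unique(res$associations$lnc_id))
  })
  merged <- merge_across_datasets(per_dataset, across)

  for (id in ids) {
    write_cegs(results[[id]], file.path(out, sprintf("cegs_%s.tsv", id)))
  }
  write_merged_cegs(merged, file.path(out, "merged_cegs.tsv"))

  background <- sort(unique(unlist(map(results, "expressed_pcgs"))))
  enr <- run_enrichment_files(merged$members, gmt, background, enrichment, out)
  write_manifest(out, "merge-cegsfuncs",
    config_snapshot = c(
      unclass(config),
      list(genes = genes, within = within, across = across, datasets = ids),
      unclass(enrichment)
    ),
    inputs = c(map_chr(datasets, "expression"), gtf, unname(gmt), lncrna_gtf)
  )
  invisible(list(merged = merged, results = results, enrichment = enr))
}

#' Run the CEGsNet module: export the lncRNA–CEG network
#'
#' Builds the bipartite co-expression network from one or more CEG files
#' (written by [cmd_cegs()] / [cmd_merge_cegsfuncs()]) and writes it in the
#' requested format plus `manifest.json`.
#'
#' @param ceg_files Character vector of CEG TSV paths with provenance columns.
#' @param out Output directory.
#' @param format `"graphml"`, `"sif"`, or `"tsv"`.
#' @param collapse Collapse parallel multi-dataset edges, keeping the smallest
#'   p-value (default `FALSE`).
#' @return The `coex_graph`, invisibly.
#' @export
cmd_cegsnet <- function(ceg_files, out, format = c("graphml", "sif", "tsv"),
                        collapse = FALSE) {
  format <- match.arg(format)
  ensure_out_dir(out)
  cegs <- map(ceg_files, read_cegs)
  graph <- build_network(cegs)
  if (collapse) graph <- collapse_edges(graph)
  base <- file.path(out, switch(format,
    graphml = "network.graphml", sif = "network.sif", tsv = "network"
  ))
  write_network(graph, base, format = format)
  write_manifest(out, "cegsnet",
    config_snapshot = list(format = format, collapse = collapse),
    inputs = ceg_files
  )
  log_info(sprintf(
    "cegsnet: %d nodes, %d edges written as %s", nrow(graph$nodes),
    nrow(graph$edges), format
  ))
  invisible(graph)
}

#' Run the simulate module: write a synthetic benchmark fixture
#'
#' @param out Output directory.
#' @param params A [sim_params()].
#' @return The `sim_bundle`, invisibly.
#' @export
cmd_simulate <- function(out, params = sim_params()) {
  ensure_out_dir(out)
  bundle <- simulate_dataset(params)
  files <- write_fixture(bundle, out)
  write_manifest(out, "simulate",
    config_snapshot = unclass(params),
    inputs = character(), seed = params$seed
  )
  log_info(sprintf("simulate: fixture written to '%s'", out))
  invisible(bundle)
}
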