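#' Parameters for the synthetic co-expression benchmark
#'
#' Describes a synthetic RNA-Seq-like dataset with planted lncRNA–mRNA
#' co-expression and planted enriched terms. Each lncRNA is a latent standard
#' Gaussian signal; each of its target genes mixes that signal with
#' independent noise at latent correlation `target_correlation`; all latent
#' profiles are then mapped through `exp(meanlog + sdlog * z)` to a lognormal
#' FPKM-like scale. The lognormal map is monotone, so rank-based statistics
#' see the latent correlation exactly; for a bivariate Gaussian the expected
#' Spearman coefficient is `(6 / pi) * asin(rho / 2)`.
#'
#' The defaults describe the standard benchmark condition used throughout the
#' package's tests: 50 samples (a typical RNA-Seq dataset size), 2 lncRNAs
#' with 50 targets each at latent correlation 0.8 (a strong but noisy
#' regulatory signal), 2000 unrelated null genes, and per lncRNA one planted
#' term plus 10 decoy terms drawn only from null genes.
#'
#' @param n_samples Number of samples (default 50).
#' @param n_lncrnas Number of lncRNAs (default 2).
#' @param n_pcgs Number of protein-coding genes, targets included (default
#'   2100 = 2 x 50 targets + 2000 nulls).
#' @param targets_per_lnc Planted targets per lncRNA (default 50).
#' @param target_correlation Latent Gaussian correlation of target and lncRNA
#'   signals, in (0, 1) (default 0.8).
#' @param decoy_terms_per_lnc Decoy terms per lncRNA (default 10); total terms
#'   = `n_lncrnas * (1 + decoy_terms_per_lnc)`.
#' @param planted_term_overlap Fraction of a lncRNA's targets placed in its
#'   planted term, in (0, 1] (default 0.8); the rest of the term is filled
#'   with random null genes so every planted term has `targets_per_lnc`
#'   members.
#' @param meanlog,sdlog Location and scale of the lognormal expression map
#'   (defaults 1 and 1, i.e. a median around 2.7 FPKM with a heavy right
#'   tail).
#' @param seed RNG seed; the whole bundle is reproducible from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_samples = 50L, n_lncrnas = 2L, n_pcgs = 2100L,
                       targets_per_lnc = 50L, target_correlation = 0.8,
                       decoy_terms_per_lnc = 10L, planted_term_overlap = 0.8,
                       meanlog = 1, sdlog = 1, seed = 1L) {
  stopifnot(
    n_samples >= 3, n_lncrnas >= 1, n_pcgs >= 1, targets_per_lnc >= 0,
    target_correlation > 0, target_correlation < 1,
    decoy_terms_per_lnc >= 0,
    planted_term_overlap > 0, planted_term_overlap <= 1,
    sdlog > 0
  )
  if (targets_per_lnc * n_lncrnas > n_pcgs) {
    abort("infeasible counts: targets_per_lnc * n_lncrnas exceeds n_pcgs")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_lncrnas = as.integer(n_lncrnas),
      n_pcgs = as.integer(n_pcgs), targets_per_lnc = as.integer(targets_per_lnc),
      target_correlation = target_correlation,
      decoy_terms_per_lnc = as.integer(decoy_terms_per_lnc),
      planted_term_overlap = planted_term_overlap,
      meanlog = meanlog, sdlog = sdlog, seed = as.integer(seed),
      n_terms = as.integer(n_lncrnas * (1 + decoy_terms_per_lnc)),
      noise_model = "lognormal"
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d samples, %d lncRNAs x %d targets (rho=%g), %d PCGs, %d terms, seed %d\n",
    x$n_samples, x$n_lncrnas, x$targets_per_lnc, x$target_correlation,
    x$n_pcgs, x$n_terms, x$seed
  ))
  invisible(x)
}

#' Simulate a synthetic co-expression dataset with ground truth
#'
#' Generates a combined lncRNA + protein-coding expression matrix, a matching
#' gene catalog, a gene-set collection with one planted term per lncRNA plus
#' decoy terms, and the ground truth (planted edges, planted terms, realized
#' Spearman correlation per planted edge). Decoy terms are sampled only from
#' null (non-target) genes so planted and decoy terms are cleanly separated.
#' Output is bit-reproducible from `params$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param params A [sim_params()].
#' @param dataset_id Dataset label (default `"sim<seed>"`).
#' @return A `sim_bundle`: `expression` (`expr_tbl` of all genes), `catalog`
#'   (`gene_catalog`), `gene_sets` (`gene_sets`, KEGG category), `truth`
#'   (list of `planted_edges`, `planted_terms`, tibbles), and `params`.
#' @export
simulate_dataset <- function(params = sim_params(), dataset_id = NULL) {
  stopifnot(inherits(params, "sim_params"))
  dataset_id <- dataset_id %||% paste0("sim", params$seed)
  with_seed(params$seed, {
    p <- params
    lnc_ids <- sprintf("SIMLNC%04d", seq_len(p$n_lncrnas))
    pcg_ids <- sprintf("SIMPCG%05d", seq_len(p$n_pcgs))
    sample_labels <- sprintf("S%03d", seq_len(p$n_samples))

    lnc_z <- matrix(rnorm(p$n_lncrnas * p$n_samples),
      nrow = p$n_lncrnas, dimnames = list(lnc_ids, sample_labels)
    )
    pcg_z <- matrix(rnorm(p$n_pcgs * p$n_samples),
      nrow = p$n_pcgs, dimnames = list(pcg_ids, sample_labels)
    )

    targets <- list()
    if (p$targets_per_lnc > 0L) {
      for (i in seq_len(p$n_lncrnas)) {
        idx <- ((i - 1L) * p$targets_per_lnc + 1L):(i * p$targets_per_lnc)
        rho <- p$target_correlation
        pcg_z[idx, ] <- rho * matrix(lnc_z[i, ],
          nrow = length(idx), ncol = p$n_samples, byrow = TRUE
        ) + sqrt(1 - rho^2) * pcg_z[idx, , drop = FALSE]
        targets[[lnc_ids[i]]] <- pcg_ids[idx]
      }
    }
    null_genes <- setdiff(pcg_ids, unlist(targets))

    to_expr <- function(z) exp(p$meanlog + p$sdlog * z)
    values <- rbind(to_expr(lnc_z), to_expr(pcg_z))
    expression <- expr_tbl_from_matrix(values, dataset_id)

    catalog <- new_gene_catalog(tibble(
      gene_id = c(lnc_ids, pcg_ids),
      symbol = c(sprintf("SLNC%d", seq_len(p$n_lncrnas)),
                 sprintf("SPCG%d", seq_len(p$n_pcgs))),
      biotype_class = rep(c("LNCRNA", "PROTEIN_CODING"), c(p$n_lncrnas, p$n_pcgs))
    ))

    sets <- list()
    planted_terms <- tibble(lnc_id = character(), term_id = character())
    for (i in seq_len(p$n_lncrnas)) {
      lnc <- lnc_ids[i]
      tgt <- targets[[lnc]] %||% character(0)
      n_in <- max(1L, round(p$planted_term_overlap * length(tgt)))
      planted_members <- sort(sample(tgt, min(n_in, length(tgt))))
      # with no planted targets the "planted" term degenerates to a null term
      # of nominal size 20 so it stays a valid GMT entry
      term_size <- if (length(tgt) > 0L) p$targets_per_lnc else min(20L, length(null_genes))
      n_fill <- max(0L, term_size - length(planted_members))
      fillers <- if (n_fill > 0L && length(null_genes) >= n_fill) {
        sample(null_genes, n_fill)
      } else {
        character(0)
      }
      term_id <- sprintf("PLANTED_%s", lnc)
      sets[[term_id]] <- tibble(
        term_id = term_id,
        term_name = sprintf("planted targets of %s", lnc),
        genes = list(sort(unique(c(planted_members, fillers))))
      )
      planted_terms <- bind_rows(planted_terms, tibble(lnc_id = lnc, term_id = term_id))
      for (d in seq_len(p$decoy_terms_per_lnc)) {
        size <- sample(20:60, 1L)
        did <- sprintf("DECOY_%s_%02d", lnc, d)
        sets[[did]] <- tibble(
          term_id = did,
          term_name = sprintf("decoy term %d for %s", d, lnc),
          genes = list(sort(sample(null_genes, min(size, length(null_genes)))))
        )
      }
    }
    gene_sets <- new_gene_sets(
      bind_rows(sets) |>
        mutate(category = "KEGG", .before = 1L) |>
        mutate(n_genes = lengths(.data$genes))
    )

    planted_edges <- bind_rows(imap(
      targets,
      ~ tibble(lnc_id = .y, pcg_id = .x)
    ))
    if (nrow(planted_edges) > 0L) {
      planted_edges$realized_spearman <- map2_dbl(
        planted_edges$lnc_id, planted_edges$pcg_id,
        function(l, g) cor(rank(values[l, ]), rank(values[g, ]))
      )
    } else {
      planted_edges <- tibble(
        lnc_id = character(), pcg_id = character(), realized_spearman = double()
      )
    }

    structure(
      list(
        expression = expression,
        catalog = catalog,
        gene_sets = gene_sets,
        truth = list(planted_edges = planted_edges, planted_terms = planted_terms),
        params = p,
        dataset_id = dataset_id
      ),
      class = "sim_bundle"
    )
  })
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> '%s': %d genes x %d samples, %d planted edges, %d terms (%d planted)\n",
    x$dataset_id, nrow(x$expression), length(sample_ids(x$expression)),
    nrow(x$truth$planted_edges), nrow(x$gene_sets), nrow(x$truth$planted_terms)
  ))
  invisible(x)
}

#' Write a simulated bundle as plain-text fixture files
#'
#' Emits the exact dialects the readers consume: `expression.tsv`
#' ([read_expression()]), `genes.gtf` ([read_gene_catalog()], single-GTF
#' mode), `sets.gmt` ([read_gmt()]), `truth_edges.tsv`, `truth_terms.tsv`,
#' and `params.yaml`.
#'
#' @param bundle A `sim_bundle`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    gtf = file.path(out_dir, "genes.gtf"),
    gmt = file.path(out_dir, "sets.gmt"),
    truth_edges = file.path(out_dir, "truth_edges.tsv"),
    truth_terms = file.path(out_dir, "truth_terms.tsv"),
    params = file.path(out_dir, "params.yaml")
  )
  write_expression(bundle$expression, paths[["expression"]])
  write_catalog_gtf(bundle$catalog, paths[["gtf"]])
  write_gmt(bundle$gene_sets, paths[["gmt"]])
  readr::write_tsv(bundle$truth$planted_edges, paths[["truth_edges"]])
  readr::write_tsv(bundle$truth$planted_terms, paths[["truth_terms"]])
  yaml::write_yaml(unclass(bundle$params), paths[["params"]])
  invisible(paths)
}

# Minimal synthetic single-GTF serialisation of a catalog (one gene row per
# record, biotype in gene_type).
write_catalog_gtf <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  biotype <- ifelse(catalog$biotype_class == "LNCRNA", "lncRNA", "protein_coding")
  start <- seq_len(nrow(catalog)) * 2000L
  lines <- sprintf(
    "chr1\tSIM\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"%s\";",
    start, start + 999L, catalog$gene_id, catalog$symbol, biotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back the parameters of a written fixture
#'
#' @param path `params.yaml` written by [write_fixture()].
#' @return A `sim_params`.
#' @export
read_sim_params <- function(path) {
  check_file_exists(path, "params.yaml")
  y <- yaml::read_yaml(path)
  sim_params(
    n_samples = y$n_samples, n_lncrnas = y$n_lncrnas, n_pcgs = y$n_pcgs,
    targets_per_lnc = y$targets_per_lnc,
    target_correlation = y$target_correlation,
    decoy_terms_per_lnc = y$decoy_terms_per_lnc,
    planted_term_overlap = y$planted_term_overlap,
    meanlog = y$meanlog, sdlog = y$sdlog, seed = y$seed
  )
}
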