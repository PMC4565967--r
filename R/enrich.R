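#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' Probability of drawing at least `k` members of a term of size `K` when `n`
#' genes are sampled without replacement from a universe of `N` genes:
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' The sum is accumulated in log space (log-binomials plus log-sum-exp) so
#' small tail probabilities on genome-scale universes do not underflow term by
#' term. Vectorised over `k`, `K`, `n`, `N`.
#'
#' @param k Overlap count(s), `0 <= k <= min(n, K)`.
#' @param K Term size(s) in the universe.
#' @param n Query-set size(s) in the universe.
#' @param N Universe size(s); `K <= N`, `n <= N`.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`; `k = 0`
#'   gives exactly 1.
#' @export
#' @examples
#' hypergeom_pvalue(4, K = 5, n = 8, N = 20)
hypergeom_pvalue <- function(k, K, n, N) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  with(args, {
    if (any(k != floor(k) | K != floor(K) | n != floor(n) | N != floor(N))) {
      abort("k, K, n, N must be integers")
    }
    if (any(K > N) || any(n > N) || any(k < 0) || any(k > pmin(n, K))) {
      bad <- which(K > N | n > N | k < 0 | k > pmin(n, K))[1]
      abort(sprintf(
        "invalid hypergeometric bounds: k=%d, K=%d, n=%d, N=%d (need 0 <= k <= min(n, K), K <= N, n <= N)",
        k[bad], K[bad], n[bad], N[bad]
      ))
    }
    map_dbl(seq_along(k), function(j) {
      if (k[j] == 0) {
        return(1)
      }
      i <- k[j]:min(n[j], K[j])
      logterms <- lchoose(K[j], i) + lchoose(N[j] - K[j], n[j] - i) -
        lchoose(N[j], n[j])
      m <- max(logterms)
      min(1, exp(m + log(sum(exp(logterms - m)))))
    })
  })
}

# Minimal common-length recycling with scalar broadcast.
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != n & lengths(args) != 1L
  if (any(bad)) {
    abort("arguments must have length 1 or a common length")
  }
  map(args, rep_len, n)
}

#' Multiple-testing correction of enrichment p-values
#'
#' Offers the two corrections of the enrichment engine — Bonferroni
#' (`min(1, m * p)`) and Benjamini–Hochberg step-up FDR — plus `"none"`.
#' Delegates to [stats::p.adjust()]; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"`, `"bonferroni"`, or `"none"`.
#' @return Adjusted p-values in input order, each in `[0, 1]`.
#' @export
adjust_pvalues <- function(p_values, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(tolower(method), c("bh", "bonferroni", "none"))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = switch(method,
    bh = "BH", bonferroni = "bonferroni", none = "none"
  ))
}

#' Enrichment analysis configuration
#'
#' @param correction `"bh"`, `"bonferroni"`, or `"none"`.
#' @param alpha Significance threshold on the adjusted p-value (raw p when
#'   `correction = "none"`); default 0.05.
#' @param universe `"annotated"` (default): the background is the expressed
#'   protein-coding genes carrying at least one annotation in the collection
#'   under test; `"all"`: every expressed protein-coding gene. Unannotated
#'   genes can never contribute to an overlap, so the annotated background is
#'   the conservative default.
#' @param min_term_size,max_term_size Term-size bounds applied after universe
#'   restriction (defaults 5 and 1000); set to `c(1, Inf)` to disable.
#' @return An `enrich_config` list.
#' @export
enrich_config <- function(correction = c("bh", "bonferroni", "none"),
                          alpha = 0.05,
                          universe = c("annotated", "all"),
                          min_term_size = 5L,
                          max_term_size = 1000L) {
  correction <- match.arg(tolower(correction), c("bh", "bonferroni", "none"))
  universe <- match.arg(universe)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
    min_term_size >= 1, max_term_size >= min_term_size
  )
  structure(
    list(
      correction = correction, alpha = alpha, universe = universe,
      min_term_size = min_term_size, max_term_size = max_term_size
    ),
    class = "enrich_config"
  )
}

#' Hypergeometric gene-set enrichment of a CEG set
#'
#' Tests a (merged) CEG set against every term of a gene-set collection with
#' the one-sided upper-tail hypergeometric test, corrects within the
#' collection, and returns the terms significant at the configured threshold,
#' sorted by raw p-value. Terms with no overlap are never reported as
#' significant. Each category in `gene_sets` is treated as its own
#' multiple-testing family, matching the convention of reporting GO BP / CC /
#' MF and KEGG as separate lists.
#'
#' @param ceg_genes Character vector (or `merged_cegs`) of query gene ids;
#'   genes outside `expressed_pcgs` are dropped with a warning.
#' @param gene_sets A `gene_sets` collection from [read_gmt()].
#' @param expressed_pcgs Background candidates: the expressed protein-coding
#'   gene ids of the dataset(s) analysed.
#' @param config An [enrich_config()].
#' @param keep_all Return all tested terms instead of only the significant
#'   ones (default `FALSE`).
#' @return A `coex_enrichment` tibble: `category`, `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_adjusted`, `overlap_genes` (list column),
#'   sorted ascending by `p_raw`. Attributes `config`, `n_terms_tested`,
#'   `universe_size`.
#' @export
enrich <- function(ceg_genes, gene_sets, expressed_pcgs,
                   config = enrich_config(), keep_all = FALSE) {
  stopifnot(inherits(gene_sets, "gene_sets"), inherits(config, "enrich_config"))
  if (inherits(ceg_genes, "merged_cegs")) ceg_genes <- ceg_genes$members
  ceg_genes <- unique(as.character(ceg_genes))
  expressed_pcgs <- unique(as.character(expressed_pcgs))

  outside <- setdiff(ceg_genes, expressed_pcgs)
  if (length(outside) > 0L) {
    warn(sprintf(
      "%d CEG(s) outside the expressed background dropped from enrichment",
      length(outside)
    ))
    ceg_genes <- intersect(ceg_genes, expressed_pcgs)
  }

  empty <- new_enrichment(
    tibble(
      category = character(), term_id = character(), term_name = character(),
      k = integer(), n = integer(), K = integer(), N = integer(),
      p_raw = double(), p_adjusted = double(), overlap_genes = list()
    ),
    config, 0L, 0L
  )

  results <- map(split(seq_len(nrow(gene_sets)), gene_sets$category), function(rows) {
    coll <- gene_sets[rows, , drop = FALSE]
    universe <- switch(config$universe,
      annotated = intersect(expressed_pcgs, unique(unlist(coll$genes))),
      all = expressed_pcgs
    )
    N <- length(universe)
    query <- intersect(ceg_genes, universe)
    n <- length(query)
    if (N == 0L || n == 0L) {
      warn(sprintf(
        "empty %s for category %s; no enrichment computed",
        if (N == 0L) "universe" else "CEG set within the universe",
        coll$category[1]
      ))
      return(NULL)
    }
    members <- map(coll$genes, intersect, universe)
    K <- lengths(members)
    keep <- K >= config$min_term_size & K <= config$max_term_size
    if (!any(keep)) {
      return(NULL)
    }
    overlap <- map(members[keep], intersect, query)
    k <- lengths(overlap)
    K_kept <- K[keep]
    p_raw <- hypergeom_pvalue(k, K_kept, n, N)
    tibble(
      category = coll$category[keep],
      term_id = coll$term_id[keep],
      term_name = coll$term_name[keep],
      k = as.integer(k),
      n = n,
      K = as.integer(K_kept),
      N = N,
      p_raw = p_raw,
      overlap_genes = map(overlap, sort)
    ) |>
      mutate(p_adjusted = adjust_pvalues(.data$p_raw, config$correction))
  })
  results <- bind_rows(results)
  if (nrow(results) == 0L) {
    return(empty)
  }

  n_tested <- nrow(results)
  p_filter <- if (config$correction == "none") results$p_raw else results$p_adjusted
  n_sig <- sum(p_filter <= config$alpha & results$k > 0L)
  if (!keep_all) {
    results <- results[p_filter <= config$alpha & results$k > 0L, , drop = FALSE]
  }
  results <- arrange(results, .data$p_raw) |>
    relocate("p_adjusted", .after = "p_raw")
  log_info(sprintf(
    "enrichment: %d terms tested, %d significant at %s %g",
    n_tested, n_sig, config$correction, config$alpha
  ))
  new_enrichment(results, config, n_tested, max(c(results$N, 0L)))
}

new_enrichment <- function(x, config, n_terms_tested, universe_size) {
  out <- as_tibble(x)
  attr(out, "config") <- config
  attr(out, "n_terms_tested") <- n_terms_tested
  attr(out, "universe_size") <- universe_size
  class(out) <- c("coex_enrichment", class(out))
  out
}

#' @rdname enrich
#' @param x A `coex_enrichment`.
#' @param ... Unused.
#' @method glance coex_enrichment
#' @export
glance.coex_enrichment <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    correction = cfg$correction,
    alpha = cfg$alpha,
    n_terms_tested = attr(x, "n_terms_tested"),
    n_significant = nrow(x),
    min_p_raw = if (nrow(x)) min(x$p_raw) else NA_real_
  )
}

#' Write enrichment results to TSV
#'
#' One row per term with counts, raw and adjusted p, and the overlapping genes
#' comma-joined, mirroring the enriched-function tables of the web modules.
#'
#' @param x A `coex_enrichment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "coex_enrichment"))
  flat <- as_tibble(x) |>
    mutate(overlap_genes = map_chr(.data$overlap_genes, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Bar-chart overview of enriched terms
#'
#' @param object A `coex_enrichment`.
#' @param top_n Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coex_enrichment
#' @export
autoplot.coex_enrichment <- function(object, top_n = 15, ...) {
  dat <- head(as_tibble(object), top_n) |>
    mutate(term = factor(.data$term_name, levels = rev(unique(.data$term_name))))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = -log10(pmax(.data$p_adjusted, 1e-300)), y = .data$term,
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = expression(-log[10] ~ adjusted ~ p), y = NULL,
      title = "Enriched terms"
    ) +
    ggplot2::theme_minimal()
}
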