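#' Co-expression analysis configuration
#'
#' Bundles the knobs of the co-expression stage. Defaults follow the tool's
#' standard operating point for RNA-Seq: linear regression on log2(x + 1)
#' expression, an expression-detection threshold of 0.001 on the mean, and a
#' coefficient-significance threshold of 0.01; no minimum effect size.
#' At least one of `coef_threshold` / `p_threshold` must be set, and both
#' configured thresholds must pass for a pair to count as co-expressed.
#'
#' @param method Association method: `"regression"` (ordinary least squares of
#'   protein-coding expression on lncRNA expression, slope t-test) or
#'   `"spearman"` (rank correlation, t-approximation p-value).
#' @param expr_threshold Expression-detection threshold (default 0.001).
#' @param expr_filter_mode `"mean"` or `"fraction"`; see [filter_expressed()].
#' @param coef_threshold Optional minimum absolute correlation-scale effect
#'   `|r|` for CEG membership. Applied to `r` rather than the raw slope so one
#'   threshold serves both methods.
#' @param p_threshold Optional significance threshold on the coefficient
#'   p-value (default 0.01).
#' @param log_transform Apply log2(x + 1) before regression (default `TRUE`).
#'   Rank-based Spearman analysis is unaffected by monotone transforms, so the
#'   flag only matters for regression.
#' @return A `coex_config` list.
#' @export
coex_config <- function(method = c("regression", "spearman"),
                        expr_threshold = 0.001,
                        expr_filter_mode = c("mean", "fraction"),
                        coef_threshold = NULL,
                        p_threshold = 0.01,
                        log_transform = TRUE) {
  method <- match.arg(method)
  expr_filter_mode <- match.arg(expr_filter_mode)
  stopifnot(
    is.numeric(expr_threshold), length(expr_threshold) == 1L, expr_threshold >= 0,
    is.logical(log_transform), length(log_transform) == 1L
  )
  if (!is.null(coef_threshold)) {
    stopifnot(is.numeric(coef_threshold), coef_threshold >= 0, coef_threshold <= 1)
  }
  if (!is.null(p_threshold)) {
    stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1)
  }
  if (is.null(coef_threshold) && is.null(p_threshold)) {
    abort("at least one of coef_threshold / p_threshold must be set")
  }
  structure(
    list(
      method = method, expr_threshold = expr_threshold,
      expr_filter_mode = expr_filter_mode, coef_threshold = coef_threshold,
      p_threshold = p_threshold, log_transform = log_transform
    ),
    class = "coex_config"
  )
}

#' @export
print.coex_config <- function(x, ...) {
  cat(sprintf(
    "<coex_config> method=%s, expr>%g (%s), |r|>=%s, p<=%s, log2(x+1)=%s\n",
    x$method, x$expr_threshold, x$expr_filter_mode,
    x$coef_threshold %||% "-", x$p_threshold %||% "-", x$log_transform
  ))
  invisible(x)
}

# Two-sided p-value for a correlation-scale effect r on n - 2 df via
# t = r * sqrt((n - 2) / (1 - r^2)); |r| = 1 gives t = Inf hence p = 0.
cor_t_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(0, 1 - r^2))
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Spearman rank correlation with coefficient significance
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' average-ranked values (ties receive mean ranks) and its two-sided p-value
#' from the t-approximation on `n - 2` degrees of freedom. The t-approximation
#' is used at every sample size; it is coarse below about 10 samples.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return One-row tibble with `rho`, `p_value`, `n_samples`.
#' @export
#' @examples
#' spearman_assoc(1:5, c(5, 6, 7, 8, 7))
spearman_assoc <- function(x, y) {
  check_assoc_input(x, y, require_y_varies = TRUE)
  rho <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  tibble(
    rho = rho,
    p_value = cor_t_pvalue(rho, length(x)),
    n_samples = length(x)
  )
}

#' Simple linear regression with slope significance
#'
#' Ordinary least squares of `y` (protein-coding expression) on `x` (lncRNA
#' expression): slope `Sxy/Sxx`, two-sided slope t-test on `n - 2` degrees of
#' freedom, plus the signed Pearson correlation `r` as the correlation-scale
#' effect. The slope p-value equals the Pearson correlation-test p-value, an
#' algebraic identity of simple OLS.
#'
#' @param x Predictor vector (must not be constant), length at least 3.
#' @param y Response vector of the same length.
#' @return One-row tibble with `slope`, `r`, `p_value`, `n_samples`.
#' @export
#' @examples
#' regression_assoc(c(1, 2, 3), c(1, 3, 2))
regression_assoc <- function(x, y) {
  check_assoc_input(x, y, require_y_varies = FALSE)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  p <- if (syy == 0) 1 else cor_t_pvalue(r, length(x))
  tibble(slope = slope, r = r, p_value = p, n_samples = length(x))
}

check_assoc_input <- function(x, y, require_y_varies) {
  if (length(x) != length(y)) {
    abort(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  }
  if (length(x) < 3L) {
    abort("at least 3 paired observations are required")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("missing values are not allowed")
  }
  if (sd(x) == 0) {
    abort("x is constant; association is undefined")
  }
  if (require_y_varies && sd(y) == 0) {
    abort("y is constant; association is undefined")
  }
  invisible(NULL)
}

# Vectorised association of one lncRNA profile against every row of a
# protein-coding matrix. Returns r (correlation scale), coefficient (rho or
# slope), and p. Constant protein-coding rows come back as NA.
assoc_one_lnc <- function(lnc_vec, pcg_mat, method, log_transform) {
  n <- length(lnc_vec)
  if (method == "spearman") {
    x <- rank(lnc_vec, ties.method = "average")
    ym <- t(apply(pcg_mat, 1L, rank, ties.method = "average"))
  } else {
    if (log_transform) {
      x <- log2(lnc_vec + 1)
      ym <- log2(pcg_mat + 1)
    } else {
      x <- lnc_vec
      ym <- pcg_mat
    }
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- ym - rowMeans(ym)
  sxy <- as.vector(yc %*% xc)
  syy <- rowSums(yc^2)
  r <- ifelse(syy == 0, NA_real_, sxy / sqrt(sxx * syy))
  coefficient <- if (method == "spearman") r else sxy / sxx
  tibble(
    pcg_id = rownames(pcg_mat),
    coefficient = coefficient,
    r = r,
    p_value = ifelse(is.na(r), NA_real_, cor_t_pvalue(r, n)),
    n_samples = n
  )
}

#' Compute lncRNA co-expressed gene (CEG) sets for one dataset
#'
#' Tests every (lncRNA, expressed protein-coding gene) pair in one dataset
#' with the configured association method and extracts the CEG set of each
#' lncRNA by thresholding. A gene is a CEG of a lncRNA when its coefficient
#' p-value passes `p_threshold` and its absolute correlation-scale effect
#' passes `coef_threshold` (each only if configured). Datasets are analysed
#' independently; matrices are used as given, so apply [filter_expressed()]
#' first (the [cmd_cegs()] pipeline does).
#'
#' @param lnc_expr `expr_tbl` of lncRNA expression.
#' @param pcg_expr `expr_tbl` of protein-coding expression over the same
#'   samples in the same order.
#' @param lnc_ids lncRNA gene ids to analyse. Ids absent from `lnc_expr`
#'   (e.g. removed by the expression filter) are excluded with a warning.
#' @param config A [coex_config()].
#' @return A `coex_result` with `associations` (tibble: `lnc_id`, `pcg_id`,
#'   `method`, `coefficient`, `r`, `p_value`, `n_samples`), `cegs` (the rows
#'   passing thresholds, plus `dataset_id`), `dataset_id`, `config`, and
#'   `expressed_pcgs`.
#' @export
compute_cegs <- function(lnc_expr, pcg_expr, lnc_ids, config = coex_config()) {
  stopifnot(
    inherits(lnc_expr, "expr_tbl"), inherits(pcg_expr, "expr_tbl"),
    inherits(config, "coex_config")
  )
  if (!identical(sample_ids(lnc_expr), sample_ids(pcg_expr))) {
    abort("lncRNA and protein-coding matrices must share identical sample ids in identical order")
  }
  if (length(sample_ids(lnc_expr)) < 3L) {
    abort("at least 3 samples are required for association testing")
  }

  lnc_ids <- unique(strip_version(lnc_ids))
  missing <- setdiff(lnc_ids, lnc_expr$gene_id)
  if (length(missing) > 0L) {
    warn(sprintf(
      "%d lncRNA(s) absent from the filtered expression matrix and excluded: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
    lnc_ids <- setdiff(lnc_ids, missing)
  }
  if (length(lnc_ids) == 0L) {
    abort("no requested lncRNAs remain after expression filtering")
  }

  lnc_mat <- expr_matrix(lnc_expr)
  pcg_mat <- expr_matrix(pcg_expr)
  constant_lnc <- lnc_ids[apply(lnc_mat[lnc_ids, , drop = FALSE], 1L, sd) == 0]
  if (length(constant_lnc) > 0L) {
    warn(sprintf(
      "lncRNA(s) constant across samples excluded: %s",
      paste(constant_lnc, collapse = ", ")
    ))
    lnc_ids <- setdiff(lnc_ids, constant_lnc)
    if (length(lnc_ids) == 0L) abort("no analysable lncRNAs remain")
  }

  associations <- map(lnc_ids, function(lnc) {
    assoc_one_lnc(lnc_mat[lnc, ], pcg_mat, config$method, config$log_transform) |>
      mutate(lnc_id = lnc, .before = 1L)
  }) |>
    bind_rows() |>
    mutate(method = config$method, .after = "pcg_id")

  n_const <- sum(is.na(associations$r))
  if (n_const > 0L) {
    log_info(sprintf(
      "compute_cegs: %d pair(s) with constant protein-coding expression skipped",
      n_const
    ))
    associations <- filter(associations, !is.na(.data$r))
  }

  cegs <- extract_cegs(associations, config$coef_threshold, config$p_threshold) |>
    mutate(dataset_id = dataset_id(pcg_expr), .before = 1L)

  log_info(sprintf(
    "compute_cegs '%s': %d lncRNAs x %d pairs tested, %d CEG associations retained",
    dataset_id(pcg_expr), length(lnc_ids), nrow(associations), nrow(cegs)
  ))
  structure(
    list(
      associations = associations,
      cegs = cegs,
      dataset_id = dataset_id(pcg_expr),
      config = config,
      expressed_pcgs = rownames(pcg_mat)
    ),
    class = "coex_result"
  )
}

#' Threshold an association table into CEG rows
#'
#' Both configured thresholds must pass; an unset threshold is ignored, but at
#' least one must be set. Tightening either threshold can only shrink the
#' result.
#'
#' @param associations Association tibble as produced by [compute_cegs()].
#' @param coef_threshold Minimum `|r|`, or `NULL`.
#' @param p_threshold Maximum p-value, or `NULL`.
#' @return The subset of rows passing every configured threshold.
#' @export
extract_cegs <- function(associations, coef_threshold = NULL, p_threshold = NULL) {
  if (is.null(coef_threshold) && is.null(p_threshold)) {
    abort("at least one of coef_threshold / p_threshold must be set")
  }
  keep <- rep(TRUE, nrow(associations))
  if (!is.null(coef_threshold)) {
    keep <- keep & abs(associations$r) >= coef_threshold
  }
  if (!is.null(p_threshold)) {
    keep <- keep & associations$p_value <= p_threshold
  }
  associations[keep, , drop = FALSE]
}

#' CEG membership of a result as named sets
#'
#' @param x A `coex_result` or a CEG tibble with `lnc_id` and `pcg_id`.
#' @return Named list mapping each lncRNA id to its sorted CEG member vector.
#' @export
ceg_members <- function(x) {
  cegs <- if (inherits(x, "coex_result")) x$cegs else x
  lncs <- unique(cegs$lnc_id)
  setNames(
    map(lncs, ~ sort(unique(cegs$pcg_id[cegs$lnc_id == .x]))),
    lncs
  )
}

#' @export
print.coex_result <- function(x, ...) {
  cat(sprintf(
    "<coex_result> dataset '%s' (%s): %d associations tested, %d CEG pairs across %d lncRNA(s)\n",
    x$dataset_id, x$config$method, nrow(x$associations), nrow(x$cegs),
    length(unique(x$cegs$lnc_id))
  ))
  invisible(x)
}

#' @rdname compute_cegs
#' @param x A `coex_result`.
#' @param ... Unused.
#' @method tidy coex_result
#' @export
tidy.coex_result <- function(x, ...) {
  as_tibble(x$associations)
}

#' @rdname compute_cegs
#' @method glance coex_result
#' @export
glance.coex_result <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id,
    method = x$config$method,
    n_lncrnas = length(unique(x$associations$lnc_id)),
    n_pairs_tested = nrow(x$associations),
    n_ceg_pairs = nrow(x$cegs),
    n_expressed_pcgs = length(x$expressed_pcgs)
  )
}

#' Write the association table of a co-expression result
#'
#' Columns `lnc_id`, `pcg_id`, `method`, `coefficient`, `r`, `p_value`,
#' `n_samples`, mirroring the per-pair download of the CEGs module.
#'
#' @param x A `coex_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  stopifnot(inherits(x, "coex_result"))
  readr::write_tsv(x$associations, path)
  invisible(path)
}

#' Write CEG rows (one gene per line, with provenance)
#'
#' @param x A `coex_result` or CEG tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cegs <- function(x, path) {
  cegs <- if (inherits(x, "coex_result")) x$cegs else x
  readr::write_tsv(cegs, path)
  invisible(path)
}

#' Read a CEG table written by [write_cegs()]
#'
#' @param path CEG TSV path.
#' @return CEG tibble with provenance columns.
#' @export
read_cegs <- function(path) {
  check_file_exists(path, "CEG file")
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("dataset_id", "lnc_id", "pcg_id", "coefficient", "r", "p_value")
  miss <- setdiff(required, names(out))
  if (length(miss) > 0L) {
    abort(sprintf(
      "malformed CEG file '%s': missing column(s) %s",
      path, paste(miss, collapse = ", ")
    ))
  }
  out
}

#' Volcano-style overview of a co-expression result
#'
#' Plots the correlation-scale effect against -log10 p for every tested pair,
#' marking the pairs retained as CEGs.
#'
#' @param object A `coex_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coex_result
#' @export
autoplot.coex_result <- function(object, ...) {
  dat <- object$associations |>
    mutate(
      ceg = paste(.data$lnc_id, .data$pcg_id) %in%
        paste(object$cegs$lnc_id, object$cegs$pcg_id)
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$r, y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$ceg
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~lnc_id) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = "CEG"
    ) +
    ggplot2::labs(
      x = "correlation-scale effect r",
      y = expression(-log[10] ~ p),
      title = sprintf("Co-expression, dataset '%s'", object$dataset_id)
    ) +
    ggplot2::theme_minimal()
}
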