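test_that("expression filter applies mean and fraction modes", {
  m <- matrix(
    c(
      0, 0, 0, 0, # all-zero gene
      0.0005, 0.0005, 0.0005, 0.0005, # below threshold everywhere
      0.5, 0.5, 0.5, 0.5, # comfortably expressed
      0.5, 0, 0, 0 # mean 0.125 but detected in 1/4 samples
    ),
    nrow = 4, byrow = TRUE
  )
  rownames(m) <- c("zero", "low", "high", "bursty")
  x <- make_expr(m)

  by_mean <- filter_expressed(x, threshold = 0.001, mode = "mean")
  expect_setequal(by_mean$gene_id, c("high", "bursty"))
  by_frac <- filter_expressed(x, threshold = 0.001, mode = "fraction")
  expect_setequal(by_frac$gene_id, "high")
  # sample set unchanged
  expect_equal(sample_ids(by_mean), sample_ids(x))
  expect_error(filter_expressed(x, threshold = 10), "no genes pass")
})

test_that("spearman matches hand-derived values and handles the exact cases", {
  expect_equal(spearman_assoc(1:5, 1:5)$rho, 1)
  expect_equal(spearman_assoc(1:5, 1:5)$p_value, 0)
  expect_equal(spearman_assoc(1:5, 5:1)$rho, -1)
  expect_equal(spearman_assoc(1:5, 5:1)$p_value, 0)
  a <- spearman_assoc(1:5, c(5, 6, 7, 8, 7))
  expect_equal(a$rho, 0.820782681668123, tolerance = 1e-12)
  expect_error(spearman_assoc(1:5, rep(2, 5)), "constant")
  expect_error(spearman_assoc(1:4, 1:5), "length mismatch")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    base <- spearman_assoc(x, y)
    expect_equal(spearman_assoc(exp(x), y), base, tolerance = 1e-12)
    expect_equal(spearman_assoc(x, y^3 + 5 * y), base, tolerance = 1e-12)
  }
})

test_that("tie-free spearman equals the 1 - 6 sum d^2 closed form", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- sample(seq_len(1000), n) # tie-free
    y <- sample(seq_len(1000), n)
    d <- rank(x) - rank(y)
    closed <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(spearman_assoc(x, y)$rho, closed, tolerance = 1e-12)
  }
})

test_that("spearman agrees with cor.test as an independent route", {
  set.seed(44)
  x <- rnorm(25)
  y <- 0.5 * x + rnorm(25)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman_assoc(x, y)$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("regression recovers exact lines and hand-computed slopes", {
  x <- c(1, 2, 3, 4, 5)
  exact <- regression_assoc(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r, 1)
  expect_equal(exact$p_value, 0)
  expect_equal(regression_assoc(c(1, 2, 3), c(1, 3, 2))$slope, 0.5)
  expect_error(regression_assoc(rep(2, 4), 1:4), "constant")
  expect_error(regression_assoc(1:2, 1:2), "at least 3")
})

test_that("regression matches lm() and the correlation-test p identity", {
  set.seed(45)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- rnorm(n, sd = runif(1, 0.5, 3)) + runif(1, -1, 1) * x
    ours <- regression_assoc(x, y)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(ours$slope, fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(ours$p_value, fit["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(ours$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("compute_cegs admits a planted near-perfect pair at p <= 0.01", {
  set.seed(46)
  x <- rlnorm(20)
  m_lnc <- matrix(x, nrow = 1, dimnames = list("LNC1", sprintf("S%02d", 1:20)))
  m_pcg <- rbind(
    target = x + rnorm(20, sd = 1e-3),
    noise = rlnorm(20)
  )
  colnames(m_pcg) <- colnames(m_lnc)
  res <- compute_cegs(
    make_expr(m_lnc), make_expr(m_pcg), "LNC1",
    coex_config(p_threshold = 0.01)
  )
  expect_true("target" %in% res$cegs$pcg_id)
  expect_equal(nrow(res$associations), 2L)
})

test_that("compute_cegs enforces sample alignment and warns on dropped lncRNAs", {
  m <- matrix(rlnorm(40), nrow = 2, dimnames = list(c("L1", "P1"), sprintf("S%02d", 1:20)))
  lnc <- make_expr(m["L1", , drop = FALSE])
  pcg <- make_expr(m["P1", , drop = FALSE])
  pcg_swapped <- pcg[, c("gene_id", rev(sample_ids(pcg)))]
  class(pcg_swapped) <- class(pcg)
  attr(pcg_swapped, "dataset_id") <- "test"
  expect_error(compute_cegs(lnc, pcg_swapped, "L1"), "identical sample ids")
  expect_warning(
    res <- compute_cegs(lnc, pcg, c("L1", "GONE")),
    "GONE"
  )
  expect_equal(unique(res$associations$lnc_id), "L1")
  expect_error(suppressWarnings(compute_cegs(lnc, pcg, "GONE")), "no requested lncRNAs")
})

test_that("constant protein-coding genes are skipped, not fatal", {
  set.seed(47)
  m_lnc <- matrix(rlnorm(15), nrow = 1, dimnames = list("L1", sprintf("S%02d", 1:15)))
  m_pcg <- rbind(flat = rep(2, 15), ok = rlnorm(15))
  colnames(m_pcg) <- colnames(m_lnc)
  res <- compute_cegs(make_expr(m_lnc), make_expr(m_pcg), "L1")
  expect_equal(res$associations$pcg_id, "ok")
})

test_that("null admission rate tracks the significance threshold", {
  # 1000 independent null genes at n = 50: the fraction admitted at p <= 0.01
  # must sit inside the binomial 99% band around 0.01.
  set.seed(48)
  n <- 50
  m_lnc <- matrix(rlnorm(n), nrow = 1, dimnames = list("L1", sprintf("S%03d", 1:n)))
  m_pcg <- matrix(rlnorm(1000 * n),
    nrow = 1000,
    dimnames = list(sprintf("N%04d", 1:1000), colnames(m_lnc))
  )
  res <- compute_cegs(
    make_expr(m_lnc), make_expr(m_pcg), "L1",
    coex_config(p_threshold = 0.01)
  )
  admitted <- nrow(res$cegs)
  band <- qbinom(c(0.005, 0.995), 1000, 0.01)
  expect_gte(admitted, band[1])
  expect_lte(admitted, band[2])
})

test_that("tightening either threshold never grows a CEG set", {
  res <- benchmark_result()
  assoc <- res$associations
  p_grid <- c(0.05, 0.01, 0.001)
  r_grid <- c(0, 0.3, 0.6)
  prev <- NULL
  for (p in p_grid) {
    cur <- extract_cegs(assoc, p_threshold = p)
    if (!is.null(prev)) {
      expect_true(all(
        paste(cur$lnc_id, cur$pcg_id) %in% paste(prev$lnc_id, prev$pcg_id)
      ))
    }
    prev <- cur
  }
  prev <- NULL
  for (r in r_grid) {
    cur <- extract_cegs(assoc, coef_threshold = r, p_threshold = 0.01)
    if (!is.null(prev)) {
      expect_lte(nrow(cur), nrow(prev))
    }
    prev <- cur
  }
  expect_error(extract_cegs(assoc), "at least one")
})

test_that("permuting samples identically in both matrices changes nothing", {
  b <- simulate_dataset(sim_params(
    n_samples = 25, n_pcgs = 120, targets_per_lnc = 15, seed = 9
  ))
  parts <- split_expression(b$expression, b$catalog)
  lnc_ids <- b$catalog$gene_id[b$catalog$biotype_class == "LNCRNA"]
  set.seed(1)
  perm <- sample(sample_ids(parts$lnc))
  permute <- function(x) {
    out <- x[, c("gene_id", perm)]
    attr(out, "dataset_id") <- dataset_id(x)
    class(out) <- class(x)
    out
  }
  res1 <- compute_cegs(parts$lnc, parts$pcg, lnc_ids)
  res2 <- compute_cegs(permute(parts$lnc), permute(parts$pcg), lnc_ids)
  expect_equal(res1$associations, res2$associations)
  expect_equal(res1$cegs, res2$cegs)
})

test_that("tidy and glance summarise a co-expression result", {
  res <- benchmark_result()
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("lnc_id", "pcg_id", "method", "coefficient", "r", "p_value", "n_samples"))
  gl <- glance(res)
  expect_equal(gl$n_pairs_tested, nrow(td))
  expect_equal(gl$method, "regression")
})
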