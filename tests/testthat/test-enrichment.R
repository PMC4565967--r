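test_that("hypergeometric tail matches frozen values and boundary cases", {
  expect_equal(hypergeom_pvalue(0, 5, 8, 20), 1)
  expect_equal(hypergeom_pvalue(0, 0, 0, 10), 1)
  expect_equal(hypergeom_pvalue(4, 5, 8, 20), 0.0577915376676987, tolerance = 1e-12)
  expect_error(hypergeom_pvalue(6, 5, 8, 20), "bounds")
  expect_error(hypergeom_pvalue(1, 25, 8, 20), "bounds")
  expect_error(hypergeom_pvalue(0.5, 5, 8, 20), "integers")
})

test_that("hypergeometric tail equals exact enumeration on small universes", {
  set.seed(11)
  cases <- random_hyper_cases(200, n_max = 30)
  for (i in seq_len(nrow(cases))) {
    got <- hypergeom_pvalue(cases[i, 1], cases[i, 2], cases[i, 3], cases[i, 4])
    want <- hyper_oracle(cases[i, 1], cases[i, 2], cases[i, 3], cases[i, 4])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # and against phyper on larger universes
  expect_equal(
    hypergeom_pvalue(40, 300, 500, 15000),
    phyper(39, 300, 14700, 500, lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("hypergeometric tail is non-increasing in k", {
  K <- 10
  n <- 12
  N <- 40
  p <- hypergeom_pvalue(0:min(n, K), K, n, N)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("p-value corrections match their definitions", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01) # m = 1 identity
  expect_equal(
    adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
    c(0.04, 0.04, 0.04, 0.04)
  )
  expect_equal(adjust_pvalues(c(0.5, 0.9), "bonferroni"), c(1, 1)) # capped
  expect_equal(adjust_pvalues(c(0.2, 0.7), "none"), c(0.2, 0.7))
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    bh <- adjust_pvalues(p, "bh")
    bonf <- adjust_pvalues(p, "bonferroni")
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh <= bonf + 1e-15)) # BH dominated by Bonferroni
    expect_true(all(bh >= p - 1e-15)) # adjusted >= raw
    # permutation invariance: permute, adjust, unpermute
    perm <- sample(seq_along(p))
    expect_equal(adjust_pvalues(p[perm], "bh")[order(perm)], bh, tolerance = 1e-15)
  }
})

make_sets <- function(terms, category = "KEGG") {
  lines <- vapply(
    names(terms),
    function(t) paste(c(t, paste0(t, " name"), terms[[t]]), collapse = "\t"),
    ""
  )
  read_gmt(write_toy_gmt(unname(lines)), category)
}

test_that("a fully recovered planted term ranks first", {
  universe <- sprintf("u%03d", 1:200)
  planted <- universe[1:20]
  decoys <- split(universe[21:130], rep(1:10, each = 11))
  terms <- c(list(PLANT = planted), setNames(decoys, sprintf("DEC%02d", 1:10)))
  sets <- make_sets(terms)
  ceg <- c(planted, universe[131:140]) # n = 30 containing all of K = 20
  res <- enrich(ceg, sets, universe, enrich_config(universe = "all"), keep_all = TRUE)
  expect_equal(res$term_id[1], "PLANT")
  expect_equal(res$k[res$term_id == "PLANT"], 20L)
  expect_equal(res$N[1], 200L)
  expect_true(all(res$p_raw[res$term_id == "PLANT"] <= min(res$p_raw)))
  # oracle: direct hypergeometric evaluation per term
  for (i in seq_len(nrow(res))) {
    expect_equal(
      res$p_raw[i],
      hyper_oracle(res$k[i], res$K[i], res$n[i], res$N[i]),
      tolerance = 1e-10
    )
  }
})

test_that("enrichment counts follow the configured universe mode", {
  universe <- sprintf("u%03d", 1:100)
  annotated <- universe[1:60]
  sets <- make_sets(list(T1 = annotated[1:20], T2 = annotated[21:60]))
  ceg <- universe[c(1:10, 91:95)] # 5 CEGs unannotated
  res_ann <- enrich(ceg, sets, universe, enrich_config(universe = "annotated"), keep_all = TRUE)
  res_all <- enrich(ceg, sets, universe, enrich_config(universe = "all"), keep_all = TRUE)
  expect_equal(unique(res_ann$N), 60L)
  expect_equal(unique(res_all$N), 100L)
  expect_equal(unique(res_ann$n), 10L) # unannotated CEGs leave the universe
  expect_equal(unique(res_all$n), 15L)
  # at fixed (k, K, n), a larger universe lowers the expected overlap n*K/N,
  # so the same observed overlap becomes more surprising: p falls as N grows
  expect_lt(
    hypergeom_pvalue(10, 20, 10, 100),
    hypergeom_pvalue(10, 20, 10, 60)
  )
})

test_that("term-size bounds, zero-overlap terms and empty inputs are handled", {
  universe <- sprintf("u%03d", 1:100)
  sets <- make_sets(list(
    TINY = universe[1:2], BIG = universe, OK = universe[1:30], FAR = universe[71:100]
  ))
  cfg <- enrich_config(min_term_size = 5, max_term_size = 50, alpha = 1)
  res <- enrich(universe[1:10], sets, universe, cfg, keep_all = TRUE)
  expect_setequal(res$term_id, c("OK", "FAR")) # TINY/BIG size-filtered
  # k = 0 terms are never reported significant, even at alpha = 1
  sig <- enrich(universe[1:10], sets, universe, cfg)
  expect_false("FAR" %in% sig$term_id)
  expect_true("OK" %in% sig$term_id)

  expect_warning(out <- enrich(character(0), sets, universe, cfg), "empty")
  expect_equal(nrow(out), 0L)
  expect_warning(
    enrich(c(universe[1], "alien"), sets, universe, cfg),
    "outside the expressed background"
  )
})

test_that("correction families are per category and filtering respects alpha", {
  universe <- sprintf("u%03d", 1:100)
  ceg <- universe[1:10]
  lines <- c(
    paste(c("A1", "a", universe[1:10]), collapse = "\t"),
    paste(c("A2", "a", universe[40:60]), collapse = "\t")
  )
  kegg <- read_gmt(write_toy_gmt(lines), "KEGG")
  bp <- read_gmt(write_toy_gmt(lines), "GO_BP")
  both <- new_sets <- dplyr::bind_rows(as.data.frame(kegg), as.data.frame(bp))
  class(both) <- class(kegg)
  res <- enrich(ceg, both, universe, enrich_config(universe = "all", alpha = 1), keep_all = TRUE)
  # each category adjusted within itself: identical p_adjusted across families
  expect_equal(
    res$p_adjusted[res$category == "KEGG"][order(res$term_id[res$category == "KEGG"])],
    res$p_adjusted[res$category == "GO_BP"][order(res$term_id[res$category == "GO_BP"])]
  )
  expect_equal(res$p_raw, sort(res$p_raw))
})
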