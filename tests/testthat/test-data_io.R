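test_that("gene catalog keeps only lncRNA and protein-coding biotypes", {
  gtf <- write_toy_gtf(data.frame(
    gene_id = c("L1.3", "L2", "P1.10", "P2", "P3", "PS1"),
    symbol = c("LNCA", "LNCB", "GENE1", "GENE2", "GENE3", "PSEUDO"),
    biotype = c("lncRNA", "antisense", rep("protein_coding", 3), "processed_pseudogene")
  ))
  cat <- read_gene_catalog(gtf)
  expect_s3_class(cat, "gene_catalog")
  expect_equal(nrow(cat), 5L)
  expect_false("PS1" %in% cat$gene_id)
  expect_setequal(cat$biotype_class[cat$gene_id %in% c("L1", "L2")], "LNCRNA")
  # version suffixes stripped
  expect_true(all(c("L1", "P1") %in% cat$gene_id))
  expect_false(any(grepl("\\.", cat$gene_id)))
  # classification is a partition
  expect_equal(anyDuplicated(cat$gene_id), 0L)
})

test_that("gene catalog deduplicates repeated gene rows (exon lines)", {
  path <- tempfile(fileext = ".gtf")
  attr9 <- 'gene_id "G1.2"; gene_name "SYM1"; gene_type "lncRNA";'
  writeLines(c(
    paste("chr1", "T", "gene", 1, 900, ".", "+", ".", attr9, sep = "\t"),
    paste("chr1", "T", "exon", 1, 400, ".", "+", ".", attr9, sep = "\t"),
    paste("chr1", "T", "exon", 500, 900, ".", "+", ".", attr9, sep = "\t")
  ), path)
  cat <- read_gene_catalog(path)
  expect_equal(cat$gene_id, "G1")
})

test_that("malformed GTF lines are rejected with a line number", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "T", "gene", 1, 900, ".", "+", ".",
      'gene_id "G1"; gene_type "lncRNA";',
      sep = "\t"
    ),
    "chr1\tonly\tthree"
  ), path)
  expect_error(read_gene_catalog(path), "line 2")
})

test_that("catalog errors when no gene is retained", {
  gtf <- write_toy_gtf(data.frame(
    gene_id = "X1", symbol = "X", biotype = "snoRNA"
  ))
  expect_error(read_gene_catalog(gtf), "retained")
})

test_that("two-file GENCODE mode classifies the whole lncRNA GTF as lncRNA", {
  main <- write_toy_gtf(data.frame(
    gene_id = c("P1", "P2", "MISC1"),
    symbol = c("GENE1", "GENE2", "MISC"),
    biotype = c("protein_coding", "protein_coding", "misc_RNA")
  ))
  # biotype attribute deliberately not in the lncRNA list: separate-file mode
  # must classify it as lncRNA anyway
  lnc <- write_toy_gtf(data.frame(
    gene_id = "L9", symbol = "LNCX", biotype = "TEC"
  ))
  cat <- read_gene_catalog(main, lncrna_gtf = lnc)
  expect_setequal(cat$gene_id, c("L9", "P1", "P2"))
  expect_equal(cat$biotype_class[cat$gene_id == "L9"], "LNCRNA")
})

test_that("expression reader validates shape, cells and signs", {
  path <- write_toy_expression(c(
    "gene\tS1\tS2\tS3\tS4",
    "G1.5\t0\t1\t2\t3",
    "G2\t1.5\t2.5\t3.5\t4.5",
    "G3\t0.1\t0.2\t0.3\t0.4"
  ))
  x <- read_expression(path, "d1")
  expect_s3_class(x, "expr_tbl")
  expect_equal(nrow(x), 3L)
  expect_equal(sample_ids(x), c("S1", "S2", "S3", "S4"))
  expect_equal(x$gene_id[1], "G1") # version stripped
  expect_equal(dataset_id(x), "d1")

  expect_error(
    read_expression(write_toy_expression(c(
      "gene\tS1\tS2\tS3", "G1\t1\tNA\t2", "G2\t1\t2\t3"
    ))),
    "'NA' for gene 'G1', sample 'S2'"
  )
  expect_error(
    read_expression(write_toy_expression(c(
      "gene\tS1\tS2\tS3", "G1\t1\t-1.0\t2"
    ))),
    "negative value -1 for gene 'G1', sample 'S2'"
  )
  expect_error(
    read_expression(write_toy_expression(c(
      "gene\tS1\tS2\tS3", "G1\t1\t2\t3", "G2\t1\t2"
    ))),
    "ragged"
  )
  expect_error(
    read_expression(write_toy_expression(c(
      "gene\tS1\tS2", "G1\t1\t2", "G1.2\t3\t4"
    ))),
    "duplicate gene row"
  )
})

test_that("expression write/read round trip preserves the numeric table", {
  m <- matrix(c(0, 0.25, 1.5, 12.125, 3.75, 100.5), nrow = 2)
  x <- make_expr(m, "rt")
  path <- tempfile(fileext = ".tsv")
  write_expression(x, path)
  y <- read_expression(path, "rt")
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("GMT reader deduplicates members and enforces the 3-field contract", {
  gmt <- write_toy_gmt(c(
    "T1\tdesc one\tg1\tg2\tg2",
    "T2\tdesc two\tg3\tg4"
  ))
  sets <- read_gmt(gmt, "GO_BP")
  expect_s3_class(sets, "gene_sets")
  expect_equal(nrow(sets), 2L)
  expect_setequal(sets$genes[[1]], c("g1", "g2"))
  expect_equal(sets$term_name, c("desc one", "desc two"))
  expect_equal(sets$category, c("GO_BP", "GO_BP"))

  expect_error(read_gmt(write_toy_gmt(c("T1\tdesc\tg1", "T2\tdesc")), "KEGG"), "line 2")
  expect_error(
    read_gmt(write_toy_gmt(c("T1\td\tg1", "T1\td\tg2")), "KEGG"),
    "duplicated term id"
  )
})

test_that("GMT write/read is the identity on canonicalised collections", {
  gmt <- write_toy_gmt(c(
    "T1\tfirst\tg3\tg1\tg2",
    "T2\tsecond\tg9\tg4"
  ))
  sets <- read_gmt(gmt, "KEGG")
  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  again <- read_gmt(out, "KEGG")
  canon <- function(s) dplyr::mutate(as.data.frame(s), genes = lapply(genes, sort))
  expect_equal(canon(again), canon(sets))
})

test_that("gene resolution matches ids first, then symbols, and flags ambiguity", {
  gtf <- write_toy_gtf(data.frame(
    gene_id = c("ENSG00000251562", "L2", "L3", "P1"),
    symbol = c("MALAT1", "SHARED", "SHARED", "GENE1"),
    biotype = c("lncRNA", "lncRNA", "lncRNA", "protein_coding")
  ))
  cat <- read_gene_catalog(gtf)
  res <- resolve_genes(
    c("ENSG00000251562.8", "MALAT1", "SHARED", "NOPE"),
    cat
  )
  expect_equal(res$resolved$gene_id, c("ENSG00000251562", "ENSG00000251562"))
  expect_equal(res$ambiguous, "SHARED")
  expect_equal(res$unresolved, "NOPE")
  expect_false("SHARED" %in% res$resolved$input)
})
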