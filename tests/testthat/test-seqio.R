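test_that("miRBase FASTA reading canonicalizes and applies header convention", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hsa-miR-21-3p MIMAT0004494 Homo sapiens miR-21-3p",
               "caacaccagucgaugggcugu",
               ">x", "ACGT"), tf)
  recs <- read_mirna_fasta(tf)
  expect_equal(recs$id, c("hsa-miR-21-3p", "x"))
  expect_equal(recs$sequence[1], "CAACACCAGUCGAUGGGCUGU")
  expect_equal(recs$sequence[2], "ACGU")  # T -> U
  expect_equal(recs$description[1], "MIMAT0004494 Homo sapiens miR-21-3p")
  expect_equal(recs$description[2], "")

  # strict mode refuses DNA alphabet rather than repairing it
  expect_error(read_mirna_fasta(tf, canonicalize = FALSE),
               class = "mirdiag_format_error")
})

test_that("FASTA reader rejects duplicates, bad alphabet, and malformed files", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU", ">x", "GGGG"), tf)
  expect_error(read_mirna_fasta(tf), "duplicate",
               class = "mirdiag_format_error")

  writeLines(c(">x", "ACGN"), tf)
  expect_error(read_mirna_fasta(tf), "non-ACGU",
               class = "mirdiag_format_error")

  writeLines(c("ACGU", ">x", "ACGU"), tf)
  expect_error(read_mirna_fasta(tf), "line 1", class = "mirdiag_format_error")

  writeLines(c(">x", "ACGU", ">y"), tf)
  expect_error(read_mirna_fasta(tf), "line 3", class = "mirdiag_format_error")
})

test_that("FASTA round-trip preserves id and sequence for 1000 random records", {
  withr::local_seed(11)
  recs <- mirna_set(sprintf("mir-%04d", 1:1000), random_rna(1000))
  tf <- withr::local_tempfile(fileext = ".fa")
  write_mirna_fasta(recs, tf)
  back <- read_mirna_fasta(tf)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("target-table reader parses scores, headers, and rejects bad rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\ttarget\tscore",
               "hsa-miR-21-3p\tMAPK1\t92",
               "hsa-miR-21-3p\ttp53\t85.5"), tf)
  tg <- read_target_table(tf)
  expect_equal(nrow(tg), 2)
  expect_equal(tg$score[tg$gene == "MAPK1"], 92)
  expect_true("TP53" %in% tg$gene)  # uppercased

  writeLines(character(), tf)
  expect_equal(nrow(read_target_table(tf)), 0)

  writeLines(c("a\tB\t50", "b\tC\tabc"), tf)
  expect_error(read_target_table(tf), "row 2", class = "mirdiag_format_error")

  writeLines("a\tB", tf)
  expect_error(read_target_table(tf), class = "mirdiag_format_error")

  writeLines(c("a\tB\t50", "a\tB\t60"), tf)
  expect_error(read_target_table(tf), "conflicting",
               class = "mirdiag_format_error")
})

test_that("pathway reader handles TSV and GMT, canonicalizes, validates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p53 signaling pathway\tTP53,CDKN1A",
               "",
               "MAPK signaling pathway\tmapk1\takt1"), tf)
  ps <- read_pathway_sets(tf)
  expect_equal(sort(ps[["p53 signaling pathway"]]), c("CDKN1A", "TP53"))
  expect_equal(sort(ps[["MAPK signaling pathway"]]), c("AKT1", "MAPK1"))

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("mTOR signaling pathway\tsource\tMTOR\tRPS6KB1", gmt)
  ps2 <- read_pathway_sets(gmt)
  expect_equal(ps2[["mTOR signaling pathway"]], c("MTOR", "RPS6KB1"))

  writeLines(c("a\tX", "a\tY"), tf)
  expect_error(read_pathway_sets(tf), "duplicate",
               class = "mirdiag_format_error")
  writeLines("empty one\t", tf)
  expect_error(read_pathway_sets(tf), "no genes",
               class = "mirdiag_format_error")
})

test_that("ARFF round-trip reproduces ids, kinds, values, and labels", {
  withr::local_seed(5)
  v <- cbind(x = rnorm(6), `odd name!` = runif(6),
             flag = rep(c(0, 1), 3))
  rownames(v) <- sprintf("hsa-miR-%d", 1:6)
  tab <- feature_table(v, c("numeric", "numeric", "binary"),
                       labels = rep(c("negative", "positive"), 3))
  tf <- withr::local_tempfile(fileext = ".arff")
  write_arff(tab, tf)
  back <- read_arff(tf)
  expect_identical(back$values, tab$values)
  expect_identical(unname(back$kinds), unname(tab$kinds))
  expect_identical(as.character(back$labels), as.character(tab$labels))

  # unlabeled table: class written as "?" and read back as NULL labels
  tab2 <- feature_table(v, c("numeric", "numeric", "binary"))
  write_arff(tab2, tf)
  expect_true(any(grepl(",\\?$", readLines(tf))))
  expect_null(read_arff(tf)$labels)

  # 0-instance table: header-only ARFF still round-trips
  tab0 <- feature_table(v[0, , drop = FALSE], c("numeric", "numeric", "binary"))
  write_arff(tab0, tf)
  back0 <- read_arff(tf)
  expect_equal(nrow(back0$values), 0)
  expect_equal(ft_attributes(back0), ft_attributes(tab0))
})

test_that("ARFF writes are byte-identical across calls and foreign can read them", {
  withr::local_seed(6)
  v <- cbind(a = rnorm(10), b = rep(c(0, 1), 5))
  rownames(v) <- sprintf("m%d", 1:10)
  tab <- feature_table(v, c("numeric", "binary"),
                       labels = rep(c("negative", "positive"), each = 5))
  f1 <- withr::local_tempfile(fileext = ".arff")
  f2 <- withr::local_tempfile(fileext = ".arff")
  write_arff(tab, f1)
  write_arff(tab, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # independent reader: WEKA-format parser from the foreign package
  fa <- foreign::read.arff(f1)
  expect_equal(nrow(fa), 10)
  expect_equal(fa$a, unname(tab$values[, "a"]))
  expect_equal(as.character(fa$class),
               as.character(tab$labels))
})

test_that("CSV mirror round-trips values, labels, and kind inference", {
  withr::local_seed(7)
  v <- cbind(num = rnorm(8), bin = rep(c(0, 1), 4))
  rownames(v) <- sprintf("m%d", 1:8)
  tab <- feature_table(v, c("numeric", "binary"),
                       labels = rep(c("negative", "positive"), 4))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, tf)
  back <- read_feature_csv(tf)
  expect_identical(back$values, tab$values)
  # 'bin' holds only 0/1 so it is inferred binary; 'num' stays numeric
  expect_identical(unname(back$kinds[c("num", "bin")]), c("numeric", "binary"))
  expect_identical(as.character(back$labels), as.character(tab$labels))
})

test_that("feature_table enforces its invariants", {
  v <- cbind(a = c(0, 2))
  rownames(v) <- c("x", "y")
  expect_error(feature_table(v, "binary"), class = "mirdiag_domain_error")
  v2 <- cbind(a = c(0, 1)); rownames(v2) <- c("x", "x")
  expect_error(feature_table(v2, "binary"), class = "mirdiag_domain_error")
  v3 <- cbind(a = c(0, 1), a = c(1, 0)); rownames(v3) <- c("x", "y")
  expect_error(feature_table(v3, "binary"), class = "mirdiag_domain_error")
  v4 <- cbind(a = c(0, 1)); rownames(v4) <- c("x", "y")
  expect_error(feature_table(v4, "binary", labels = "positive"),
               class = "mirdiag_domain_error")
})
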