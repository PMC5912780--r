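# Readers/writers: coordinate conventions, validation, round trips.

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_gff3 <- c(
  "##gff-version 3",
  "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
  "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
  "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
  "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=gA.t1.e2;Parent=gA.t1",
  "chr1\tsrc\tgene\t1001\t1400\t.\t-\t.\tID=gB",
  "chr1\tsrc\tmRNA\t1001\t1400\t.\t-\t.\tID=gB.t1;Parent=gB",
  "chr1\tsrc\texon\t1001\t1400\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1")

test_that("GFF3 coordinates convert 1-based inclusive to 0-based half-open", {
  models <- read_gene_annotation(write_tmp(tiny_gff3, ".gff3"), "gff3")
  a <- models[models$gene_id == "gA", ]
  expect_equal(a$start, c(100, 300))
  expect_equal(a$end, c(200, 400))
  # internal length equals (end - start + 1) of the source line
  expect_equal(a$end - a$start, c(200 - 101 + 1, 400 - 301 + 1))
  expect_setequal(unique(models$gene_id), c("gA", "gB"))
})

test_that("genes without exons are dropped and orphan exons skipped, with warnings", {
  gff <- c(tiny_gff3,
           "chr1\tsrc\tgene\t5001\t5400\t.\t+\t.\tID=gC",
           "chr1\tsrc\texon\t7001\t7100\t.\t+\t.\tID=x;Parent=missing.t9")
  warns <- capture_warnings(
    models <- read_gene_annotation(write_tmp(gff, ".gff3"), "gff3"))
  expect_length(warns, 2)
  expect_match(warns, "orphan|parent|without exons", all = FALSE)
  expect_setequal(unique(models$gene_id), c("gA", "gB"))
})

test_that("malformed annotation lines are reported with their line number", {
  gff <- c(tiny_gff3[1:4], "chr1\tsrc\texon\t301")
  expect_error(read_gene_annotation(write_tmp(gff, ".gff3"), "gff3"),
               "line 5")
})

test_that("GTF exons resolve gene/transcript identity from attributes", {
  gtf <- c(paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
                 "gene_id \"gA\"; transcript_id \"gA.t1\";", sep = "\t"),
           paste("chr1", "src", "exon", "301", "400", ".", "+", ".",
                 "gene_id \"gA\"; transcript_id \"gA.t1\";", sep = "\t"))
  models <- read_gene_annotation(write_tmp(gtf, ".gtf"), "gtf")
  expect_equal(models$gene_id, c("gA", "gA"))
  expect_equal(models$transcript_id, c("gA.t1", "gA.t1"))
  expect_equal(models$start, c(100, 300))
  expect_equal(models$end, c(200, 400))
})

test_that("broadPeak lines map to peak records, sorted by (chrom, start)", {
  pk <- read_peaks(write_tmp(
    c("chr2 700 900 p2 10 . 1.5 -1 -1",
      "chr1 100 600 p1 50 . 4.2 -1 -1",
      "chr1 50 80 p0 5 . 0.7 -1 -1"), ".broadPeak"))
  expect_equal(pk$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(pk$start[2], 100)
  expect_equal(pk$end[2], 600)
  expect_equal(pk$signal_value, c(0.7, 4.2, 1.5))
  expect_false(is.unsorted(order(pk$chrom, pk$start, pk$end)))
})

test_that("broadPeak format errors are rejected", {
  expect_equal(nrow(read_peaks(write_tmp(character(0), ".broadPeak"))), 0)
  expect_error(read_peaks(write_tmp("chr1 100 600 p1 50 .", ".broadPeak")),
               ">= 7 columns")
  expect_error(read_peaks(write_tmp("chr1 -5 600 p1 50 . 1 -1 -1",
                                    ".broadPeak")),
               "negative start")
})

test_that("typed tables validate rows with row-numbered messages", {
  eff <- write_tmp(c("gene_id\tguide_sequence\tefficiency\tfunctional",
                     paste("ca6", strrep("AC", 10), "35.0", "TRUE",
                           sep = "\t")), ".tsv")
  rec <- read_table(eff, "efficiency")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$efficiency, 35)
  expect_true(rec$functional)

  bad_eff <- write_tmp(c("gene_id\tguide_sequence\tefficiency\tfunctional",
                         paste("ca6", strrep("AC", 10), "135", "TRUE",
                               sep = "\t")), ".tsv")
  expect_error(read_table(bad_eff, "efficiency"), "row\\(s\\) 1")

  bad_stage <- write_tmp(c("gene_id\tstage\trpkm", "gA\t10hpf\t1.0"), ".tsv")
  expect_error(read_table(bad_stage, "expression"), "invalid row")

  zero_probe <- write_tmp(c("gene_id\tprobe_id\tarray_id\tmedian_intensity",
                            "gA\tp1\ta1\t0"), ".tsv")
  expect_error(read_table(zero_probe, "probes"), "invalid row")

  no_col <- write_tmp(c("gene\tstage\trpkm", "gA\t36hpf\t1"), ".tsv")
  expect_error(read_table(no_col, "expression"), "missing column")
})

test_that("feature-table writes are deterministic and round trip", {
  ft <- data.frame(gene_id = c("gB", "gA"),
                   atac_coefficient = c(1.0533333, NA),
                   methylation_coefficient = c(0.25, 1),
                   promoter_score = c(-2.123456789, 3),
                   efficiency = c(40.5, 12.25),
                   stringsAsFactors = FALSE)
  p1 <- tempfile(); p2 <- tempfile()
  write_feature_table(ft, p1)
  write_feature_table(ft, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_feature_table(p1)
  expect_equal(back$gene_id, c("gA", "gB"))   # gene-sorted rows
  expect_equal(back$atac_coefficient, c(NA, 1.0533333), tolerance = 1e-5)
  expect_equal(back$promoter_score, c(3, -2.123456789), tolerance = 1e-5)

  empty <- ft[0, , drop = FALSE]
  p3 <- tempfile()
  write_feature_table(empty, p3)
  expect_length(readLines(p3), 1)   # header only
})

test_that("simulator outputs round trip through the readers", {
  b <- simulate_study(sim_config(n_genes = 25, seed = 11))
  dir <- tempfile()
  paths <- write_bundle(b, dir)
  models2 <- read_gene_annotation(paths[["annotation"]], "gff3")
  expect_equal(models2[order(models2$gene_id, models2$transcript_id,
                             models2$start),
                       c("gene_id", "transcript_id", "chrom", "strand",
                         "start", "end")],
               b$models[, c("gene_id", "transcript_id", "chrom", "strand",
                            "start", "end")],
               ignore_attr = TRUE)
  atac2 <- read_peaks(paths[["atac"]])
  expect_equal(atac2[, c("chrom", "start", "end")],
               b$atac[, c("chrom", "start", "end")], ignore_attr = TRUE)
  expect_equal(atac2$signal_value, b$atac$signal_value, tolerance = 1e-5)
  eff2 <- read_table(paths[["efficiency"]], "efficiency")
  expect_equal(eff2$gene_id, b$efficiency$gene_id)
  expect_equal(eff2$efficiency, b$efficiency$efficiency, tolerance = 1e-5)
  expr2 <- read_table(paths[["expression"]], "expression")
  expect_equal(nrow(expr2), nrow(b$expression))
})

test_that("alias map translates identifiers before joining", {
  map_path <- write_tmp(c("from\tto", "ca6\tg0001"), ".tsv")
  alias <- read_alias_map(map_path)
  expect_equal(apply_alias(c("ca6", "g0002"), alias), c("g0001", "g0002"))
  expect_equal(apply_alias(c("ca6"), NULL), "ca6")
})
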