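test_that("sequence lookup is strand-aware and rejects out-of-range queries", {
  g <- Biostrings::DNAStringSet(c(I = "ACGTACGTAA"))
  expect_identical(get_seq(g, "I", 1, 4, "+"), "ACGT")
  expect_identical(get_seq(g, "I", 1, 4, "-"), "ACGT")
  expect_identical(get_seq(g, "I", 7, 10, "-"), "TTAC")
  expect_error(get_seq(g, "I", 0, 4), "out-of-range")
  expect_error(get_seq(g, "I", 8, 12), "out-of-range")
  expect_error(get_seq(g, "II", 1, 2), "not present")
})

test_that("windows clip to contig bounds and report what was lost", {
  g <- Biostrings::DNAStringSet(c(I = "ACGTACGTAA"))
  w <- get_window(g, "I", -2, 3, "+")
  expect_identical(w$seq, "ACG")
  expect_identical(w$clipped_start, 3L)
  w <- get_window(g, "I", 9, 14, "-")
  expect_identical(w$seq, "TT")
  expect_identical(w$clipped_end, 4L)
})

test_that("gene models merge exons and locate the 3'-most stop codon", {
  m <- fixture_models()
  expect_identical(nrow(m$genes), 2L)
  # overlapping exons are merged
  genes <- data.frame(gene_id = "g1", biotype = "protein_coding",
                      contig = "I", strand = "+", stop_codon = 150L)
  exons <- data.frame(gene_id = "g1", contig = "I", strand = "+",
                      start = c(100L, 140L), end = c(160L, 200L))
  gm <- gene_models(genes, exons)
  expect_identical(nrow(gm$exons), 1L)
  expect_identical(gm$exons$start, 100L)
  expect_identical(gm$exons$end, 200L)
  # stop codon must lie within an exon
  genes$stop_codon <- 300L
  expect_error(gene_models(genes, exons), "stop codon outside exons")
})

test_that("GFF3 annotation round-trips through write and read", {
  m <- fixture_models()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(m, path)
  m2 <- read_annotation(path)
  expect_identical(m2$genes[order(gene_id), stop_codon],
                   m$genes[order(gene_id), stop_codon])
  expect_identical(m2$genes[order(gene_id), biotype],
                   m$genes[order(gene_id), biotype])
  expect_identical(
    m2$exons[order(gene_id, start), .(gene_id, start, end)],
    m$exons[order(gene_id, start), .(gene_id, start, end)])
})

test_that("minus-strand stop codon is the minimum CDS coordinate", {
  m <- fixture_models()
  path <- withr::local_tempfile(fileext = ".gff3")
  # gB is minus strand: CDS spans stop_codon..gene end, so min start = 5000
  write_annotation_gff3(m, path)
  m2 <- read_annotation(path)
  expect_identical(m2$genes[gene_id == "gB", stop_codon], 5000L)
})

test_that("annotation parsing is idempotent and feature-order independent", {
  m <- fixture_models()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(m, path)
  lines <- readLines(path)
  shuffled <- c(lines[1], rev(lines[-1]))
  path2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(shuffled, path2)
  a <- read_annotation(path)
  b <- read_annotation(path2)
  expect_identical(a$genes, b$genes)
  expect_identical(a$exons[order(gene_id, start)],
                   b$exons[order(gene_id, start)])
})

test_that("malformed annotation lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "I\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "I\tsrc\texon\t1\t100"), path)
  expect_error(read_annotation(path), "line 3")
})

test_that("exon features without a resolvable gene id are an error", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "I\tsrc\texon\t1\t100\t.\t+\t.\tnote=orphan"), path)
  expect_error(read_annotation(path), "gene id")
})

test_that("GTF dialect is accepted via gene_id attributes", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("I\tsrc\texon\t400\t500\t.\t+\t.\t",
           "gene_id \"gA\"; transcript_id \"gA.1\";"),
    paste0("I\tsrc\texon\t600\t800\t.\t+\t.\t",
           "gene_id \"gA\"; transcript_id \"gA.1\";"),
    paste0("I\tsrc\tCDS\t400\t700\t.\t+\t0\t",
           "gene_id \"gA\"; transcript_id \"gA.1\";")), path)
  m <- read_annotation(path)
  expect_identical(m$genes$gene_id, "gA")
  expect_identical(m$genes$stop_codon, 700L)
  expect_identical(m$genes$biotype, "protein_coding")
})

test_that("CPA BED6 output round-trips exactly and uses 0-based intervals", {
  u <- data.table::data.table(
    contig = c("I", "I"), strand = c("+", "-"), pos = c(100L, 200L),
    sample_id = "S1", count = c(13L, 5L))
  cl <- cluster_sites(u)
  path <- withr::local_tempfile(fileext = ".bed")
  write_cpa_bed(cl, path)
  lines <- readLines(path)
  expect_identical(lines[1], paste("I", 99L, 100L, cl$sites$cluster_id[1],
                                   13L, "+", sep = "\t"))
  expect_identical(lines[2], paste("I", 199L, 200L, cl$sites$cluster_id[2],
                                   5L, "-", sep = "\t"))
  back <- read_cpa_bed(path)
  expect_identical(back[, .(contig, strand, pos, total)],
                   cl$sites[, .(contig, strand, pos = rep_pos, total)])
  # zero clusters give an empty file that reads back empty
  empty <- cluster_sites(u[0])
  write_cpa_bed(empty, path)
  expect_identical(nrow(read_cpa_bed(path)), 0L)
})
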