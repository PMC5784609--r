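test_that("motif counting is overlapping, alphabet-agnostic and degeneracy-aware", {
  brat <- motif_spec("UUGUU", "UUGUU")
  expect_identical(count_motif("UUGUUGUU", brat), 2L)   # overlapping starts
  expect_identical(count_motif("TTGTT", brat), 1L)      # T == U
  expect_identical(count_motif("UUG", brat), 0L)        # shorter than motif
  fbf <- motif_spec("FBF", "UGUAYW")                    # Y={C,T}, W={A,T}
  expect_identical(count_motif("TGTACA", fbf), 1L)
  expect_identical(count_motif("TGTATT", fbf), 1L)
  expect_identical(count_motif("TGTAGA", fbf), 0L)
  expect_error(motif_spec("bad", "UU"), "length >= 3")
})

test_that("counts agree with a regex-free positional scan on random inputs", {
  set.seed(19)
  pats <- c("UUGUU", "UGUAYW", "UGUAHWU", "AAN", "WWWW")
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1),
                      replace = TRUE), collapse = "")
    p <- sample(pats, 1)
    expect_identical(count_motif(s, motif_spec(p, p)),
                     oracle_motif_count(s, p))
  }
})

test_that("spliced transcript sequence joins exons and extends to the CPA", {
  # gene on +: exons [11,20] and [31,40], stop codon at 35, CPA at 50
  base <- strrep("C", 60)
  substr(base, 11, 20) <- "ACGTACGTAC"
  substr(base, 31, 40) <- "GGGTTTAAAC"
  substr(base, 41, 50) <- "TTGTTGTTGG"
  g <- Biostrings::DNAStringSet(c(I = base))
  genes <- data.frame(gene_id = "g1", biotype = "protein_coding",
                      contig = "I", strand = "+", stop_codon = 35L)
  exons <- data.frame(gene_id = "g1", contig = "I", strand = "+",
                      start = c(11L, 31L), end = c(20L, 40L))
  gm <- gene_models(genes, exons)
  sq <- transcript_sequence("g1", 50L, gm, g)
  expect_identical(sq$transcript,
                   paste0("ACGTACGTAC", "GGGTTTAAAC", "TTGTTGTTGG"))
  # stop at 35 is transcript position 15; UTR = bases 16..30
  expect_identical(sq$utr, paste0("TAAAC", "TTGTTGTTGG"))
  # junction-spanning motif: CPA inside exon 2 truncates the transcript
  sq2 <- transcript_sequence("g1", 33L, gm, g)
  expect_identical(sq2$transcript, paste0("ACGTACGTAC", "GGG"))
})

test_that("a motif spanning an exon junction is counted in spliced sequence", {
  # exon1 ends ...TTG, exon2 starts TT... -> UUGUU only exists spliced
  base <- strrep("C", 60)
  substr(base, 11, 15) <- "AATTG"
  substr(base, 26, 30) <- "TTAAA"
  g <- Biostrings::DNAStringSet(c(I = base))
  genes <- data.frame(gene_id = "g1", biotype = "protein_coding",
                      contig = "I", strand = "+", stop_codon = 12L)
  exons <- data.frame(gene_id = "g1", contig = "I", strand = "+",
                      start = c(11L, 26L), end = c(15L, 30L))
  gm <- gene_models(genes, exons)
  sq <- transcript_sequence("g1", 30L, gm, g)
  expect_identical(sq$transcript, "AATTGTTAAA")
  expect_identical(count_motif(sq$transcript, motif_spec("UUGUU", "UUGUU")),
                   1L)
  genomic <- get_seq(g, "I", 11L, 30L, "+")
  expect_identical(count_motif(genomic, motif_spec("UUGUU", "UUGUU")), 0L)
})

test_that("per-transcript tables separate UTR and whole-transcript counts", {
  # fib-1-like structure: 2 motifs in the CDS portion, 6 in the 3'UTR
  cds_part <- paste0("ATG", "TTGTT", "CCC", "TTGTT", "CCCTAA")
  utr_part <- paste0(strrep("TTGTTCC", 6), "G")
  base <- paste0(strrep("C", 10), cds_part, utr_part, strrep("C", 10))
  g <- Biostrings::DNAStringSet(c(I = base))
  stop_pos <- 10L + nchar(cds_part)
  cpa <- stop_pos + nchar(utr_part)
  genes <- data.frame(gene_id = "fib", biotype = "protein_coding",
                      contig = "I", strand = "+", stop_codon = stop_pos)
  exons <- data.frame(gene_id = "fib", contig = "I", strand = "+",
                      start = 11L, end = cpa)
  gm <- gene_models(genes, exons)
  iso <- data.table::data.table(gene_id = "fib", cluster_id = "c1",
                                rep_pos = cpa)
  tab <- per_transcript_motif_table(iso, gm, g,
                                    list(motif_spec("UUGUU", "UUGUU")))
  expect_identical(tab$n_utr, 6L)
  expect_identical(tab$n_transcript, 8L)
  expect_false(tab$missing_sequence)
})

test_that("motif density vs fold-change recovers monotone and null structure", {
  # distinct counts, strictly decreasing fold-change: perfect anticorrelation
  r1 <- motif_density_vs_foldchange(0:19, -(0:19), n_perm = 500, seed = 1)
  expect_equal(r1$rho, -1)
  expect_lt(r1$p_perm, 0.01)
  counts <- rep(0:3, each = 10)
  fc <- -counts + 0.001 * seq_along(counts)    # decreasing across buckets
  r <- motif_density_vs_foldchange(counts, fc, n_perm = 500, seed = 1)
  expect_lt(r$rho, -0.9)
  expect_lt(r$p_perm, 0.01)
  expect_identical(as.character(r$buckets$bucket), c("0", "1", "2", "3+"))
  expect_identical(r$buckets$n, rep(10L, 4))
  # permuted labels: small |rho|, non-significant
  set.seed(2)
  r0 <- motif_density_vs_foldchange(counts, sample(fc), n_perm = 500,
                                    seed = 1)
  expect_gt(r0$p_perm, 0.05)
  # degenerate input flagged
  rd <- motif_density_vs_foldchange(rep(0L, 20), rnorm(20), n_perm = 10,
                                    seed = 1)
  expect_true(is.na(rd$rho))
  expect_match(rd$warning, "undefined")
})
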