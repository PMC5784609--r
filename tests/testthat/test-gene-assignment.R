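site_row <- function(pos, strand = "+", contig = "I", id = "c1") {
  data.table::data.table(cluster_id = id, contig = contig, strand = strand,
                         rep_pos = pos)
}

test_that("exon overlap, upstream proximity and novel assignments follow the rules", {
  m <- fixture_models()
  # inside gA's terminal exon
  a <- assign_clusters(site_row(750L), m)
  expect_identical(a$assignment, "exon_overlap")
  expect_identical(a$gene_id, "gA")
  # 800 nt downstream of gA's last exon end (800), same strand
  a <- assign_clusters(site_row(1600L), m)
  expect_identical(a$assignment, "upstream_proximity")
  expect_identical(a$gene_id, "gA")
  expect_identical(a$assign_distance, 800L)
  # beyond the 1500 nt window
  a <- assign_clusters(site_row(2400L), m)
  expect_identical(a$assignment, "unassigned_novel")
  expect_true(is.na(a$gene_id))
  # minus-strand proximity: gB's 3'-most exon boundary is 4900
  a <- assign_clusters(site_row(4000L, strand = "-"), m)
  expect_identical(a$assignment, "upstream_proximity")
  expect_identical(a$gene_id, "gB")
  expect_identical(a$assign_distance, 900L)
})

test_that("assignment respects strand", {
  m <- fixture_models()
  # inside gA's exon but on the opposite strand; gB is >1500 nt away upstream
  a <- assign_clusters(site_row(750L, strand = "-"), m)
  expect_identical(a$assignment, "unassigned_novel")
})

test_that("overlap with exons of two genes is ambiguous, not assigned", {
  genes <- data.frame(gene_id = c("g1", "g2"), biotype = "protein_coding",
                      contig = "I", strand = "+", stop_codon = c(150L, 160L))
  exons <- data.frame(gene_id = c("g1", "g2"), contig = "I", strand = "+",
                      start = c(100L, 120L), end = c(200L, 220L))
  m <- gene_models(genes, exons)
  a <- assign_clusters(site_row(150L), m)
  expect_identical(a$assignment, "unassigned_ambiguous")
  expect_true(is.na(a$gene_id))
})

test_that("exon overlap wins over upstream proximity", {
  m <- fixture_models()
  # 450 overlaps gA's first exon even though no proximity would apply
  a <- assign_clusters(site_row(450L), m)
  expect_identical(a$assignment, "exon_overlap")
})

test_that("APA classification measures tandem 3'UTR lengths strand-aware", {
  r <- classify_and_measure(1000150L, "+", 1000000L, "protein_coding")
  expect_identical(r$apa_class, "tandem")
  expect_identical(r$utr_length, 150L)
  r <- classify_and_measure(4800L, "-", 5000L, "protein_coding")
  expect_identical(r$apa_class, "tandem")
  expect_identical(r$utr_length, 200L)
  r <- classify_and_measure(999000L, "+", 1000000L, "protein_coding")
  expect_identical(r$apa_class, "cds_internal")
  expect_true(is.na(r$utr_length))
  r <- classify_and_measure(500L, "+", NA_integer_, "ncRNA")
  expect_identical(r$apa_class, "ncRNA_end")
})

test_that("PAS scan reports the best-ranked hit at the documented offset", {
  s <- strrep("GC", 100)
  substr(s, 76, 81) <- "AATAAA"      # ends 19 nt upstream of CPA at 100
  g <- Biostrings::DNAStringSet(c(I = s))
  hit <- scan_pas(g, "I", "+", 100L)
  expect_identical(hit$pas_motif, "AAUAAA")
  expect_identical(hit$pas_rank, 1L)
  expect_identical(hit$pas_offset, 19L)
  # no listed motif in the window
  expect_true(is.na(scan_pas(g, "I", "+", 60L)$pas_motif))
})

test_that("motif rank beats proximity to the modal offset", {
  s <- strrep("GC", 100)
  substr(s, 70, 75) <- "AATAAA"      # canonical, ends 25 nt upstream
  substr(s, 76, 81) <- "AATATA"      # rank 5 variant, ends 19 nt upstream
  g <- Biostrings::DNAStringSet(c(I = s))
  hit <- scan_pas(g, "I", "+", 100L)
  expect_identical(hit$pas_motif, "AAUAAA")
  expect_identical(hit$pas_offset, 25L)
})

test_that("equal-rank hits prefer the offset closest to 19", {
  s <- strrep("GC", 100)
  substr(s, 66, 71) <- "AATAAA"      # offset 29 -> outside window [8,25]
  substr(s, 76, 81) <- "AATAAA"      # offset 19
  substr(s, 86, 91) <- "AATAAA"      # offset 9
  g <- Biostrings::DNAStringSet(c(I = s))
  hit <- scan_pas(g, "I", "+", 100L)
  expect_identical(hit$pas_offset, 19L)
})

test_that("PAS scan works on the minus strand and truncated windows", {
  s <- strrep("GC", 100)
  substr(s, 119, 124) <- "TTTATT"    # sense AAUAAA ending 19 nt upstream
  g <- Biostrings::DNAStringSet(c(I = s))
  hit <- scan_pas(g, "I", "-", 100L)
  expect_identical(hit$pas_motif, "AAUAAA")
  expect_identical(hit$pas_offset, 19L)
  # window truncated by the contig start scans the available portion
  expect_true(is.na(scan_pas(g, "I", "+", 20L)$pas_motif))
  s2 <- strrep("GC", 100)
  substr(s2, 1, 6) <- "AATAAA"       # ends 19 nt upstream of CPA at 25
  g2 <- Biostrings::DNAStringSet(c(I = s2))
  hit <- scan_pas(g2, "I", "+", 25L)
  expect_identical(hit$pas_offset, 19L)
})

test_that("isoform annotation indexes isoforms 5'->3' and usage sums to 1", {
  w <- fixture_world()
  sim <- simulate_sample(w, "S1", depth = 80, jitter = jitter_model(exact = TRUE),
                         seed = 3)
  sim2 <- simulate_sample(w, "S2", depth = 80, jitter = jitter_model(exact = TRUE),
                          seed = 4)
  u <- build_universe(tally_positions(sim$ends, sim2$ends), 2L)
  cl <- cluster_sites(u)
  ann <- annotate_isoforms(cl, w$models, w$genome, pipeline_config())
  # per-gene ranks are 1..k and proximal rank has the shortest UTR
  rk <- ann$isoforms[!is.na(gene_id),
                     .(ok = all(sort(isoform_rank) == seq_len(.N)),
                       prox = utr_length[which.min(isoform_rank)] ==
                         min(utr_length)), by = gene_id]
  expect_true(all(rk$ok))
  expect_true(all(rk$prox))
  tot <- ann$usage[, .(s = sum(fraction)), by = .(gene_id, sample_id)]
  expect_true(all(abs(tot$s - 1) < 1e-12))
})
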