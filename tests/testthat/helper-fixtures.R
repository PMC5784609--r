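# Small in-code fixtures shared across test files.

# a genome with known sequence content around fixed coordinates
fixture_genome <- function(len = 400L, seed = 11L) {
  set.seed(seed)
  seqs <- vapply(1:2, function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(.2, .3, .3, .2)), collapse = ""), character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, c("I", "II")))
}

# two well-separated genes, one per strand, with tandem site room downstream
fixture_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    biotype = c("protein_coding", "protein_coding"),
    contig = c("I", "I"),
    strand = c("+", "-"),
    stop_codon = c(700L, 5000L))
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    contig = "I",
    strand = c("+", "+", "-", "-"),
    start = c(400L, 600L, 5200L, 4900L),
    end = c(500L, 800L, 5400L, 5100L))
  gene_models(genes, exons)
}

# a tiny simulated world reused by integration-style tests
fixture_world <- function(n_genes = 12L, n_traps = 0L, seed = 5L,
                          contig_length = 60000L) {
  sg <- make_genome(n_contigs = 2L, contig_length = contig_length,
                    gc = 0.35, n_traps = n_traps, seed = seed)
  make_annotation(sg, n_genes = n_genes,
                  isoforms_per_gene = rep(1:3, length.out = n_genes),
                  seed = seed)
}
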