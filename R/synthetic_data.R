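#' Cleavage-jitter model
#'
#' Discrete symmetric distribution of the offset between a read's observed 3'
#' end and the true CPA site. The default puts 61% of the mass at the exact
#' site and >=90% within +/-5 nt: P(0)=0.61, P(+/-1)=0.08, P(+/-2)=0.05,
#' P(+/-3..5)=0.02 each, remaining 1% uniform on +/-6..12. The exact shape
#' beyond the two anchored constraints is a package assumption and is fully
#' configurable.
#'
#' @param p0 Probability of cleavage at the exact site.
#' @param probs Optional full probability vector over `offsets` (overrides
#'   the default shape).
#' @param offsets Offset support (default -12..12).
#' @param exact If TRUE, all mass at offset 0 (noise-free worlds).
#' @return List with `offsets` and `probs` (summing to 1).
#' @export
jitter_model <- function(p0 = 0.61, probs = NULL, offsets = -12:12,
                         exact = FALSE) {
  if (exact) return(list(offsets = 0L, probs = 1))
  if (is.null(probs)) {
    a <- abs(offsets)
    probs <- ifelse(a == 0, p0,
             ifelse(a == 1, 0.08,
             ifelse(a == 2, 0.05,
             ifelse(a <= 5, 0.02, NA))))
    rem <- 1 - sum(probs, na.rm = TRUE)
    probs[is.na(probs)] <- rem / sum(is.na(probs))
  }
  stopifnot(length(probs) == length(offsets), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-9)
  list(offsets = as.integer(offsets), probs = probs)
}

sample_bases <- function(n, gc, alphabet = c("A", "C", "G", "T")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(alphabet, n, replace = TRUE, prob = p)
}

break_homopolymer_runs <- function(seq_chr, min_run = 8L) {
  # interrupt accidental A/T runs that could mimic internal-priming tracts
  pat <- sprintf("[A]{%d,}|[T]{%d,}", min_run, min_run)
  repeat {
    m <- regexpr(pat, seq_chr)
    if (m == -1L) break
    base <- substr(seq_chr, m, m)
    mid <- m + 3L
    substr(seq_chr, mid, mid) <- if (base == "A") "C" else "G"
  }
  seq_chr
}

#' Simulate a genome with internal-priming traps
#'
#' Generates random contigs at the requested GC content, free of accidental
#' A/T homopolymer runs of 8+ nt, and injects `n_traps` A-homopolymer tracts
#' (10 nt, alternating strands) in the contig region reserved for intergenic
#' space, recording their positions. The 30 nt of sense sequence upstream of
#' each trap's would-be CPA base is rewritten without adenosines so no PAS
#' hexamer can rescue a trap (traps are A-rich and PAS-free by construction),
#' and trap CPA bases themselves start the A-run so the downstream A-rule
#' always fires on them.
#'
#' @param n_contigs Number of contigs; when >= 2 the last is named `"X"` so
#'   sex-chromosome scenarios can be programmed, the rest are Roman numerals.
#' @param contig_length Length of every contig (>= 10000 nt).
#' @param gc GC fraction.
#' @param n_traps Total number of traps across the genome.
#' @param seed RNG seed; identical seeds give byte-identical genomes.
#' @return Object of class `"sim_genome"`: list with `genome`
#'   (`DNAStringSet`), `traps` (data.table: contig, strand, pos of the CPA
#'   base = first A of the run), and the generating parameters.
#' @export
make_genome <- function(n_contigs = 2L, contig_length = 60000L, gc = 0.35,
                        n_traps = 0L, seed = 1L) {
  if (contig_length < 10000L) stop("contig_length must be >= 10000")
  set.seed(seed)
  cn <- if (n_contigs >= 2L)
    c(as.character(utils::as.roman(seq_len(n_contigs - 1L))), "X")
  else "I"
  seqs <- vapply(seq_len(n_contigs), function(i)
    break_homopolymer_runs(paste(sample_bases(contig_length, gc),
                                 collapse = "")),
    character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, cn))
  traps <- data.table::data.table(contig = character(), strand = character(),
                                  pos = integer())
  if (n_traps > 0L) {
    lo <- as.integer(ceiling(0.82 * contig_length))
    hi <- contig_length - 200L
    if (hi - lo < 200L * ceiling(n_traps / n_contigs))
      stop("trap placement impossible: intergenic region too small for ",
           n_traps, " traps")
    slots <- data.table::data.table(
      contig = cn[(seq_len(n_traps) - 1L) %% n_contigs + 1L])
    slots[, pos := lo + (seq_len(.N) - 1L) * 200L +
            sample.int(80L, .N, replace = TRUE), by = contig]
    slots[, strand := rep(c("+", "-"), length.out = .N)]
    for (i in seq_len(nrow(slots))) {
      p <- slots$pos[i]; ctg <- slots$contig[i]; st <- slots$strand[i]
      run_start <- if (st == "+") p else p - 9L
      genome <- set_seq(genome, ctg, run_start,
                        paste(rep("A", 10L), collapse = ""), st)
      up <- paste(sample(c("C", "G", "T"), 30L, replace = TRUE),
                  collapse = "")
      up_start <- if (st == "+") p - 30L else p + 1L
      genome <- set_seq(genome, ctg, up_start, up, st)
    }
    traps <- slots[, .(contig, strand, pos)]
  }
  structure(list(genome = genome, traps = traps, gc = gc,
                 contig_length = contig_length, seed = seed),
            class = "sim_genome")
}

#' Simulate annotation with programmed tandem CPA sites
#'
#' Lays genes on regular blocks (1-3 tandem CPA sites downstream of each
#' stop codon, the first inside the terminal exon, the rest within the
#' upstream-proximity assignment range), writes a PAS hexamer into the genome
#' ending `pas_offset` nt upstream of each true site, rewrites the remaining
#' upstream scan window and the 6 nt downstream of each site without
#' adenosines (a U/G-rich downstream element, which also keeps true sites
#' clear of the mispriming A-rule), and records everything as ground truth.
#' Inter-gene spacing exceeds the 1500 nt assignment window unless ambiguity
#' mode is requested.
#'
#' @param sim_genome A [make_genome()] result.
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Scalar or length-`n_genes` vector in 1..3.
#' @param pas_offset Distance from PAS end to CPA base (default 19).
#' @param block_size Gene-to-gene spacing in nt (default 3000).
#' @param allow_ambiguity Permit spacing that violates the 1500 nt
#'   separation guard (default FALSE -> error).
#' @param seed RNG seed.
#' @return Object of class `"sim_world"`: `genome` (with signals written),
#'   `models` ([gene_models()]), `cds` (CDS intervals for GFF export),
#'   `sites` (truth: gene_id, contig, strand, site_index, pos, utr_length,
#'   pas_motif, pas_offset), `usage_base` (per-gene default isoform usage,
#'   summing to 1), `expr` (per-gene relative expression), `traps`, `params`.
#' @export
make_annotation <- function(sim_genome, n_genes = 20L,
                            isoforms_per_gene = 2L, pas_offset = 19L,
                            block_size = 3000L, allow_ambiguity = FALSE,
                            seed = 1L) {
  stopifnot(inherits(sim_genome, "sim_genome"))
  set.seed(seed)
  footprint <- 1200L
  if (block_size - footprint <= 1500L && !allow_ambiguity)
    stop("inter-gene spacing ", block_size - footprint,
         " nt does not exceed the 1500 nt assignment window; ",
         "set allow_ambiguity = TRUE to force")
  k <- rep(as.integer(isoforms_per_gene), length.out = n_genes)
  if (any(k < 1L | k > 3L)) stop("isoforms_per_gene must be in 1..3")
  genome <- sim_genome$genome
  cn <- names(genome)
  L <- sim_genome$contig_length
  usable_hi <- as.integer(floor(0.8 * L)) - block_size
  per_contig <- (usable_hi - 1000L) %/% block_size
  if (per_contig * length(cn) < n_genes)
    stop("overcrowding: ", n_genes, " genes do not fit (capacity ",
         per_contig * length(cn), ")")
  site_rel <- c(60L, 230L, 380L)  # offsets from the stop codon
  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  cds <- vector("list", n_genes)
  sites <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ctg <- cn[(i - 1L) %% length(cn) + 1L]
    blk <- (i - 1L) %/% length(cn)
    b <- 1000L + blk * block_size
    st <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%03d", i)
    if (st == "+") {
      e1 <- c(b, b + 299L); e2 <- c(b + 400L, b + 760L)
      cds1 <- e1; cds2 <- c(b + 400L, b + 599L)
      stop_codon <- b + 599L
      pos <- stop_codon + site_rel[seq_len(k[i])]
    } else {
      mirror <- function(x) 2L * b + 1200L - x
      e1 <- sort(mirror(c(b, b + 299L))); e2 <- sort(mirror(c(b + 400L, b + 760L)))
      cds1 <- e1; cds2 <- sort(mirror(c(b + 400L, b + 599L)))
      stop_codon <- mirror(b + 599L)
      pos <- stop_codon - site_rel[seq_len(k[i])]
    }
    genes[[i]] <- data.table::data.table(
      gene_id = gid, biotype = "protein_coding", contig = ctg, strand = st,
      stop_codon = stop_codon)
    exons[[i]] <- data.table::data.table(
      gene_id = gid, contig = ctg, strand = st,
      start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
    cds[[i]] <- data.table::data.table(
      gene_id = gid, start = c(cds1[1], cds2[1]), end = c(cds1[2], cds2[2]))
    sites[[i]] <- data.table::data.table(
      gene_id = gid, contig = ctg, strand = st,
      site_index = seq_len(k[i]), pos = pos,
      utr_length = site_rel[seq_len(k[i])],
      pas_motif = "AAUAAA", pas_offset = pas_offset)
    for (p in pos) {
      # PAS-free upstream scan window in sense orientation, then the signal
      up <- paste(sample(c("C", "G", "T"), 30L, replace = TRUE),
                  collapse = "")
      substr(up, 31L - pas_offset - 5L, 31L - pas_offset) <- "AATAAA"
      up_start <- if (st == "+") p - 30L else p + 1L
      genome <- set_seq(genome, ctg, up_start, up, st)
      # U/G-rich downstream element: no adenosines near the cleavage base
      dse <- paste(sample(c("G", "T", "T", "C"), 6L, replace = TRUE),
                   collapse = "")
      dse_start <- if (st == "+") p + 1L else p - 6L
      genome <- set_seq(genome, ctg, dse_start, dse, st)
    }
  }
  sites <- data.table::rbindlist(sites)
  usage_base <- sites[, {
    n <- .N
    u <- switch(n, 1, c(0.7, 0.3), c(0.5, 0.3, 0.2))
    list(site_index = site_index, usage_frac = u)
  }, by = gene_id]
  models <- gene_models(data.table::rbindlist(genes),
                        data.table::rbindlist(exons))
  structure(list(genome = genome, models = models,
                 cds = data.table::rbindlist(cds), sites = sites,
                 usage_base = usage_base,
                 expr = data.table::data.table(
                   gene_id = sprintf("g%03d", seq_len(n_genes)),
                   expr_level = 1),
                 traps = sim_genome$traps,
                 params = list(seed = seed, pas_offset = pas_offset,
                               n_genes = n_genes, block_size = block_size)),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("sim_world:", nrow(x$models$genes), "genes,", nrow(x$sites),
      "true CPA sites,", nrow(x$traps), "mispriming traps\n")
  invisible(x)
}

#' Simulate one 3'-end library
#'
#' Per-gene read totals are Poisson with mean `depth * expr_level`; reads are
#' split across the gene's isoforms multinomially by the usage fractions;
#' each read's observed end is the true site plus a jitter offset drawn from
#' the jitter model (applied along the transcript direction). Mispriming
#' reads are emitted at trap positions at rate `depth * trap_rate` per trap,
#' without jitter.
#'
#' @param world A [make_annotation()] result.
#' @param sample_id Library name.
#' @param depth Expected reads per unit-expression gene.
#' @param usage Optional usage table overriding `world$usage_base`
#'   (`gene_id`, `site_index`, `usage_frac`).
#' @param expr Optional expression table overriding `world$expr`.
#' @param jitter A [jitter_model()].
#' @param trap_rate Expected trap reads as a fraction of `depth` (default
#'   0.5).
#' @param seed RNG seed.
#' @return List with `ends` (contig, strand, pos, sample_id, count), `truth`
#'   (realized reads per gene/isoform: gene_id, site_index, sample_id,
#'   true_pos, n_reads) and `trap_truth` (contig, strand, pos, n_reads).
#'   Zero depth yields an empty library with a warning.
#' @export
simulate_sample <- function(world, sample_id, depth = 100, usage = NULL,
                            expr = NULL, jitter = jitter_model(),
                            trap_rate = 0.5, seed = 1L) {
  stopifnot(inherits(world, "sim_world"))
  if (depth <= 0) {
    warning("depth 0: empty sample ", sample_id)
    empty <- data.table::data.table(contig = character(),
                                    strand = character(), pos = integer(),
                                    sample_id = character(),
                                    count = integer())
    return(list(ends = empty, truth = empty[0], trap_truth = empty[0]))
  }
  set.seed(seed)
  u <- if (is.null(usage)) world$usage_base else
    data.table::as.data.table(usage)
  e <- if (is.null(expr)) world$expr else data.table::as.data.table(expr)
  tab <- merge(world$sites, u, by = c("gene_id", "site_index"))
  tab <- merge(tab, e, by = "gene_id")
  data.table::setorder(tab, gene_id, site_index)
  reads <- vector("list", length(unique(tab$gene_id)) + 1L)
  truth <- tab[, {
    n_g <- stats::rpois(1L, depth * expr_level[1])
    n_iso <- as.vector(stats::rmultinom(1L, n_g, usage_frac))
    list(site_index = site_index, contig = contig, strand = strand,
         true_pos = pos, n_reads = n_iso)
  }, by = gene_id]
  ends_list <- lapply(seq_len(nrow(truth)), function(i) {
    n <- truth$n_reads[i]
    if (n == 0L) return(NULL)
    off <- sample(jitter$offsets, n, replace = TRUE, prob = jitter$probs)
    p <- truth$true_pos[i] + if (truth$strand[i] == "+") off else -off
    data.table::data.table(contig = truth$contig[i],
                           strand = truth$strand[i], pos = p)
  })
  trap_truth <- data.table::copy(world$traps)
  if (nrow(trap_truth)) {
    trap_truth[, n_reads := stats::rpois(.N, depth * trap_rate)]
    ends_list <- c(ends_list, lapply(seq_len(nrow(trap_truth)), function(i) {
      n <- trap_truth$n_reads[i]
      if (n == 0L) return(NULL)
      data.table::data.table(contig = rep(trap_truth$contig[i], n),
                             strand = trap_truth$strand[i],
                             pos = trap_truth$pos[i])
    }))
  }
  ends <- data.table::rbindlist(ends_list)
  ends <- if (nrow(ends))
    ends[, .(count = .N), by = .(contig, strand, pos)][
      , sample_id := sample_id][order(contig, strand, pos)]
  else data.table::data.table(contig = character(), strand = character(),
                              pos = integer(), count = integer(),
                              sample_id = character())
  data.table::setcolorder(ends, c("contig", "strand", "pos", "sample_id",
                                  "count"))
  list(ends = ends,
       truth = truth[, .(gene_id, site_index, sample_id = sample_id,
                         contig, strand, true_pos, n_reads)],
       trap_truth = trap_truth)
}

#' Simulate a two-condition study
#'
#' Builds `n_per_condition` libraries for each of two conditions (A, B). A
#' programmed fraction of multi-isoform genes switches usage in condition B:
#' `switch_delta` of usage mass moves from the most proximal to the most
#' distal isoform. Genes on contig `"X"` can be programmed at a relative
#' expression ratio to test chromosome-profile recovery.
#'
#' @param world A [make_annotation()] result.
#' @param n_per_condition Libraries per condition (default 3).
#' @param depth Expected reads per gene per library (default 100).
#' @param switch_frac Fraction of multi-isoform genes programmed to switch
#'   (default 0).
#' @param switch_delta Usage mass moved proximal -> distal in condition B
#'   (default 0.4).
#' @param x_expr_ratio Relative expression of genes on contig `"X"`
#'   (default 1).
#' @param jitter A [jitter_model()].
#' @param trap_rate Trap read rate (default 0.5).
#' @param seed Master RNG seed; per-sample seeds are derived from it.
#' @return List with `ends` (all libraries), `truth` (per-sample realized
#'   counts), `conditions` (named vector sample -> A/B), `switched_genes`,
#'   `usage_b` (condition-B usage table) and `world`.
#' @export
simulate_study <- function(world, n_per_condition = 3L, depth = 100,
                           switch_frac = 0, switch_delta = 0.4,
                           x_expr_ratio = 1, jitter = jitter_model(),
                           trap_rate = 0.5, seed = 1L) {
  set.seed(seed)
  multi <- world$usage_base[, .N, by = gene_id][N > 1L, gene_id]
  n_sw <- round(switch_frac * length(multi))
  switched <- sort(sample(multi, n_sw))
  usage_b <- data.table::copy(world$usage_base)
  usage_b[gene_id %in% switched, usage_frac := {
    u <- usage_frac
    if (u[1] - switch_delta < 0.05)
      stop("switch_delta too large for base usage")
    u[1] <- u[1] - switch_delta
    u[length(u)] <- u[length(u)] + switch_delta
    u
  }, by = gene_id]
  expr <- data.table::copy(world$expr)
  if (x_expr_ratio != 1) {
    xg <- world$models$genes[contig == "X", gene_id]
    expr[gene_id %in% xg, expr_level := expr_level * x_expr_ratio]
  }
  samples <- c(paste0("A", seq_len(n_per_condition)),
               paste0("B", seq_len(n_per_condition)))
  conditions <- setNames(rep(c("A", "B"), each = n_per_condition), samples)
  seeds <- sample.int(.Machine$integer.max - 1L, length(samples))
  sims <- lapply(seq_along(samples), function(i) {
    simulate_sample(world, samples[i], depth = depth,
                    usage = if (conditions[i] == "B") usage_b else NULL,
                    expr = expr, jitter = jitter, trap_rate = trap_rate,
                    seed = seeds[i])
  })
  list(ends = data.table::rbindlist(lapply(sims, `[[`, "ends")),
       truth = data.table::rbindlist(lapply(sims, `[[`, "truth")),
       conditions = conditions, switched_genes = switched,
       usage_b = usage_b, world = world)
}

#' Write / read simulator end records (BED-like TSV)
#'
#' Columns: contig, pos-1, pos, sample, count, strand (0-based half-open
#' interval around the CPA base). Round-trips exactly.
#'
#' @param ends End-record data.table.
#' @param path Output path.
#' @return `path` invisibly (writer); end-record data.table (reader).
#' @export
write_end_records <- function(ends, path) {
  out <- ends[, .(contig, bed_start = pos - 1L, bed_end = pos,
                  sample_id, count, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_end_records
#' @export
read_end_records <- function(path) {
  b <- data.table::fread(path, header = FALSE,
                         col.names = c("contig", "bed_start", "bed_end",
                                       "sample_id", "count", "strand"))
  b[, .(contig, strand, pos = as.integer(bed_end),
        sample_id = as.character(sample_id), count = as.integer(count))]
}

#' Fabricate paired-end alignments (SAM) from end records
#'
#' Writes a minimal coordinate-unsorted SAM in which each end record becomes
#' `count` proper pairs whose Read 2 first sequenced base sits at the CPA
#' coordinate with the correct antisense mapping geometry, so the
#' end-extraction stage can be exercised without a real aligner.
#'
#' @param ends End records (one sample).
#' @param genome `DNAStringSet` (for header contig lengths).
#' @param path Output SAM path.
#' @param read_len Mate length (default 50).
#' @return `path`, invisibly.
#' @export
write_pairs_sam <- function(ends, genome, path, read_len = 50L) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome), unname(lens)))
  qn <- 0L
  for (i in seq_len(nrow(ends))) {
    e <- ends[i]
    L <- lens[[e$contig]]
    for (r in seq_len(e$count)) {
      qn <- qn + 1L
      name <- sprintf("rp%07d", qn)
      if (e$strand == "+") {
        r2_pos <- max(1L, e$pos - read_len + 1L)
        r2_cig <- sprintf("%dM", e$pos - r2_pos + 1L)
        r1_pos <- max(1L, e$pos - 150L)
        lines <- c(lines,
          sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t0\t*\t*",
                  name, e$contig, r1_pos, read_len, r2_pos),
          sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t0\t*\t*",
                  name, e$contig, r2_pos, r2_cig, r1_pos))
      } else {
        r2_end <- min(L, e$pos + read_len - 1L)
        r2_cig <- sprintf("%dM", r2_end - e$pos + 1L)
        r1_pos <- min(L - read_len + 1L, e$pos + 100L)
        lines <- c(lines,
          sprintf("%s\t163\t%s\t%d\t60\t%s\t=\t%d\t0\t*\t*",
                  name, e$contig, e$pos, r2_cig, r1_pos),
          sprintf("%s\t83\t%s\t%d\t60\t%dM\t=\t%d\t0\t*\t*",
                  name, e$contig, r1_pos, read_len, e$pos))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
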