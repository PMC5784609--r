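# Independent brute-force oracles. These deliberately re-derive each rule
# from scratch (re-scanning, enumeration) rather than sharing code with the
# package implementations they check.

# Greedy clustering oracle: repeatedly re-scan the whole unassigned table for
# the maximum count, applying the 3'-most tie rule and the lexical
# contig order, and absorb the +/-window neighbourhood.
oracle_cluster <- function(totals, window = 12L) {
  tot <- as.data.frame(totals)
  tot$assigned <- FALSE
  out <- list()
  while (any(!tot$assigned)) {
    cand <- tot[!tot$assigned, , drop = FALSE]
    cand <- cand[cand$total == max(cand$total), , drop = FALSE]
    threeprime <- ifelse(cand$strand == "+", -cand$pos, cand$pos)
    cand <- cand[order(cand$contig, cand$strand, threeprime), , drop = FALSE]
    seed <- cand[1, ]
    mem <- which(!tot$assigned & tot$contig == seed$contig &
                   tot$strand == seed$strand &
                   abs(tot$pos - seed$pos) <= window)
    out[[length(out) + 1L]] <- data.frame(
      contig = seed$contig, strand = seed$strand, rep_pos = seed$pos,
      pos = tot$pos[mem], count = tot$total[mem])
    tot$assigned[mem] <- TRUE
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$strand, res$rep_pos, res$pos), ]
}

# canonical member table from a cpa_clusters object for oracle comparison
cluster_membership <- function(cl) {
  m <- merge(as.data.frame(cl$members),
             as.data.frame(cl$sites[, c("cluster_id", "contig", "strand",
                                        "rep_pos")]), by = "cluster_id")
  m <- m[, c("contig", "strand", "rep_pos", "pos", "count")]
  m <- m[order(m$contig, m$strand, m$rep_pos, m$pos), ]
  rownames(m) <- NULL
  m
}

random_tally <- function(n_max = 50L) {
  n <- sample.int(n_max, 1L)
  data.table::data.table(
    contig = sample(c("I", "II"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    pos = sample.int(120L, n),
    sample_id = sample(c("S1", "S2"), n, replace = TRUE),
    count = sample.int(10L, n, replace = TRUE))[
      , .(count = sum(count)), by = .(contig, strand, pos, sample_id)]
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration of all tables
# with the observed margins, summing probabilities <= that of the observed
# table (with the conventional 1 + 1e-7 relative slack).
oracle_fisher2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0L, k - n):min(k, m)
  p <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Regex-free positional motif scan with explicit IUPAC expansion.
oracle_motif_count <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  seq <- chartr("Uu", "Tt", toupper(seq))
  pattern <- chartr("Uu", "Tt", toupper(pattern))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  if (length(s) < length(p)) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j - 1L] %in% iupac[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}
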