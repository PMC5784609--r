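#' Define a cis-regulatory motif
#'
#' Patterns are given in RNA or DNA alphabet (T and U are equivalent) and may
#' use IUPAC degeneracy codes (e.g. `UGUAYW`, `UGUAHWU`).
#'
#' @param name Motif name.
#' @param pattern Pattern of length >= 3 over IUPAC codes.
#' @return List of class `"motif_spec"` with `name` and `pattern` (DNA
#'   alphabet).
#' @export
#' @examples
#' motif_spec("brat", "UUGUU")
motif_spec <- function(name, pattern) {
  pattern <- toupper(rna_to_dna(pattern))
  if (nchar(pattern) < 3L) stop("motif pattern must have length >= 3")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern))
    stop("motif pattern must use IUPAC nucleotide codes")
  structure(list(name = name, pattern = pattern), class = "motif_spec")
}

#' Count motif occurrences in a sequence
#'
#' Counts all (possibly overlapping) match start positions of the motif in
#' the sense sequence; `UUGUUGUU` contains two `UUGUU` matches. T and U are
#' interchangeable; IUPAC degeneracy in the pattern is honoured while subject
#' letters are matched literally.
#'
#' @param seq Character vector of DNA/RNA sequences (sense orientation).
#' @param motif A [motif_spec()] (or a bare pattern string).
#' @return Integer vector of occurrence counts.
#' @export
#' @examples
#' count_motif("UUGUUGUU", motif_spec("brat", "UUGUU")) # 2
count_motif <- function(seq, motif) {
  if (is.character(motif)) motif <- motif_spec(motif, motif)
  pat <- Biostrings::DNAString(motif$pattern)
  vapply(rna_to_dna(toupper(seq)), function(s) {
    if (nchar(s) < length(pat)) return(0L)
    Biostrings::countPattern(pat, Biostrings::DNAString(s),
                             fixed = c(pattern = FALSE, subject = TRUE))
  }, integer(1), USE.NAMES = FALSE)
}

#' Spliced transcript and 3'UTR sequence for an isoform
#'
#' Concatenates the gene's exon sequences 5'->3', extends (or truncates) the
#' transcript to end at the CPA base, and returns both the full spliced
#' transcript and its 3'UTR portion (everything 3' of the stop codon). When
#' the CPA site lies downstream of the terminal exon, the genomic sequence
#' between the exon end and the CPA base is appended, so motifs spanning
#' exon-exon junctions are counted in spliced, not genomic, sequence.
#'
#' @param gene_id Gene identifier.
#' @param cpa CPA coordinate of the isoform.
#' @param models A [gene_models()] collection.
#' @param genome `DNAStringSet`.
#' @return List with `transcript` and `utr` character sequences (sense
#'   orientation; `utr` is `NA` for non-coding genes).
#' @export
transcript_sequence <- function(gene_id, cpa, models, genome) {
  g <- models$genes[models$genes$gene_id == gene_id]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  ex <- models$exons[models$exons$gene_id == gene_id][order(start)]
  plus <- g$strand == "+"
  # genomic-order exon blocks, then clip/extend at the 3' end
  if (plus) {
    last_end <- max(ex$end)
    if (cpa > last_end) {
      blocks <- rbind(ex[, .(start, end)],
                      data.table::data.table(start = last_end + 1L, end = cpa))
    } else {
      blocks <- ex[start <= cpa, .(start, end = pmin(end, cpa))]
    }
  } else {
    first_start <- min(ex$start)
    if (cpa < first_start) {
      blocks <- rbind(data.table::data.table(start = cpa,
                                             end = first_start - 1L),
                      ex[, .(start, end)])
    } else {
      blocks <- ex[end >= cpa, .(start = pmax(start, cpa), end)]
    }
  }
  seqs <- vapply(seq_len(nrow(blocks)), function(i)
    get_seq(genome, g$contig, blocks$start[i], blocks$end[i], "+"),
    character(1))
  tx <- paste(seqs, collapse = "")
  if (!plus)
    tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  if (g$biotype != "protein_coding" || is.na(g$stop_codon))
    return(list(transcript = tx, utr = NA_character_))
  # transcript coordinate of the stop codon via cumulative block widths
  widths <- blocks$end - blocks$start + 1L
  if (plus) {
    prior <- cumsum(c(0L, widths))[seq_len(nrow(blocks))]
    hit <- which(g$stop_codon >= blocks$start & g$stop_codon <= blocks$end)
    stop_tx <- prior[hit] + (g$stop_codon - blocks$start[hit] + 1L)
  } else {
    rb <- blocks[nrow(blocks):1]  # 5'->3' on minus strand
    rw <- rb$end - rb$start + 1L
    prior <- cumsum(c(0L, rw))[seq_len(nrow(rb))]
    hit <- which(g$stop_codon >= rb$start & g$stop_codon <= rb$end)
    stop_tx <- prior[hit] + (rb$end[hit] - g$stop_codon + 1L)
  }
  if (length(stop_tx) != 1L || stop_tx >= nchar(tx))
    return(list(transcript = tx, utr = ""))
  list(transcript = tx, utr = substring(tx, stop_tx + 1L))
}

#' Motif counts per isoform in 3'UTR and full transcript
#'
#' @param isoforms Isoform table ([annotate_isoforms()]); only rows with an
#'   assigned gene are used.
#' @param models A [gene_models()] collection.
#' @param genome `DNAStringSet`.
#' @param motifs List of [motif_spec()] objects.
#' @return data.table with one row per isoform x motif: counts in the called
#'   3'UTR (`n_utr`, NA for non-tandem isoforms) and in the spliced
#'   transcript ending at the CPA base (`n_transcript`). Rows with missing
#'   sequence are flagged.
#' @export
per_transcript_motif_table <- function(isoforms, models, genome, motifs) {
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  iso <- data.table::as.data.table(isoforms)[!is.na(gene_id)]
  out <- vector("list", nrow(iso))
  for (i in seq_len(nrow(iso))) {
    sq <- tryCatch(
      transcript_sequence(iso$gene_id[i], iso$rep_pos[i], models, genome),
      error = function(e) NULL)
    out[[i]] <- data.table::rbindlist(lapply(motifs, function(m) {
      data.table::data.table(
        gene_id = iso$gene_id[i], cluster_id = iso$cluster_id[i],
        motif = m$name,
        n_utr = if (is.null(sq) || is.na(sq$utr)) NA_integer_
                else count_motif(sq$utr, m),
        n_transcript = if (is.null(sq)) NA_integer_
                       else count_motif(sq$transcript, m),
        missing_sequence = is.null(sq))
    }))
  }
  data.table::rbindlist(out)
}

#' Relate 3'UTR motif density to expression fold-change
#'
#' Isoforms are bucketed by motif count (default 0 / 1 / 2 / 3+), per-bucket
#' median fold-changes are reported, and the association is quantified by the
#' Spearman rank correlation between motif count and fold-change with a
#' seeded permutation p-value.
#'
#' @param motif_counts Integer vector of per-isoform motif counts.
#' @param fold_changes Numeric vector of matching log2 fold-changes.
#' @param breaks Lower bin edges (default `c(0, 1, 2, 3)`; last bin is
#'   open-ended).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutation null.
#' @return List with `buckets` (data.table: bucket, n, median_fc), `rho`,
#'   `p_perm`, and `warning` (non-NULL when the correlation is undefined or
#'   the sample is small).
#' @export
motif_density_vs_foldchange <- function(motif_counts, fold_changes,
                                        breaks = c(0L, 1L, 2L, 3L),
                                        n_perm = 10000L, seed = 1L) {
  stopifnot(length(motif_counts) == length(fold_changes))
  labels <- c(as.character(breaks[-length(breaks)]),
              paste0(breaks[length(breaks)], "+"))
  bucket <- labels[findInterval(motif_counts, breaks)]
  bdt <- data.table::data.table(bucket = factor(bucket, labels),
                                fc = fold_changes)
  buckets <- bdt[, .(n = .N, median_fc = stats::median(fc)), by = bucket][
    order(bucket)]
  warn <- NULL
  if (length(motif_counts) < 10L)
    warn <- "fewer than 10 isoforms; correlation is unstable"
  if (stats::sd(motif_counts) == 0 || stats::sd(fold_changes) == 0) {
    return(list(buckets = buckets, rho = NA_real_, p_perm = NA_real_,
                warning = "correlation undefined: a variable is constant"))
  }
  rho <- stats::cor(motif_counts, fold_changes, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm,
                    stats::cor(motif_counts, sample(fold_changes),
                               method = "spearman"))
  p_perm <- (1 + sum(abs(perm) >= abs(rho))) / (1 + n_perm)
  list(buckets = buckets, rho = rho, p_perm = p_perm, warning = warn)
}
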