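#' Read paired-end alignments
#'
#' Loads proper read pairs from a SAM or BAM file (SAM files are converted to
#' BAM in a temporary directory). Only primary alignments of proper pairs with
#' both mates mapped are yielded; everything else is counted and skipped, and
#' the tally is attached as the `"skipped"` attribute and logged.
#'
#' @param path SAM or BAM file.
#' @param sample_id Library identifier attached to every pair.
#' @return data.table with one row per mate of each proper pair: `qname`,
#'   `sample_id`, `mate` (1 or 2), `contig`, `strand` (mapping strand),
#'   `start`, `end` (1-based closed reference span). Attribute `skipped`
#'   holds the number of skipped records.
#' @export
read_alignments <- function(path, sample_id) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    out <- data.table::data.table(
      qname = character(), sample_id = character(), mate = integer(),
      contig = character(), strand = character(),
      start = integer(), end = integer())
    data.table::setattr(out, "skipped", 0L)
    return(out)
  }
  flag <- b$flag
  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  mate_unmapped <- bitwAnd(flag, 8L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep <- paired & proper & !unmapped & !mate_unmapped & !secondary
  skipped <- sum(!keep)
  if (skipped) message("read_alignments: skipped ", skipped,
                       " non-proper/unmapped/secondary records in ", path)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
  out <- data.table::data.table(
    qname = b$qname[keep],
    sample_id = sample_id,
    mate = ifelse(bitwAnd(flag[keep], 128L) > 0L, 2L, 1L),
    contig = as.character(b$rname[keep]),
    strand = as.character(b$strand[keep]),
    start = b$pos[keep],
    end = b$pos[keep] + ref_w - 1L)
  # keep only complete pairs (both mates passed the flag filter)
  cnt <- out[, .N, by = qname]
  incomplete <- cnt[N != 2L, qname]
  if (length(incomplete)) {
    skipped <- skipped + nrow(out[qname %in% incomplete])
    out <- out[!qname %in% incomplete]
  }
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Extract transcript 3'-end records from aligned pairs
#'
#' The first sequenced base of Read 2 is the CPA site: Read 2 is primed at
#' the polyA junction and sequences upstream into the transcript, so it
#' aligns antisense to the transcript. A Read 2 mapped to the minus strand
#' therefore implies a plus-strand transcript whose CPA site is the 3'-most
#' (rightmost) aligned base; a plus-strand Read 2 implies a minus-strand
#' transcript with the CPA site at the leftmost aligned base.
#'
#' @param pairs data.table from [read_alignments()].
#' @param sample_id Optional override of the sample id column.
#' @return data.table of end records: `contig`, `strand` (transcript strand),
#'   `pos` (1-based CPA coordinate), `sample_id`, `count` (aggregated reads
#'   per position).
#' @export
extract_ends <- function(pairs, sample_id = NULL) {
  r2 <- pairs[mate == 2L]
  if (!is.null(sample_id)) r2[, sample_id := sample_id]
  ends <- r2[, .(
    contig,
    strand = ifelse(strand == "-", "+", "-"),
    pos = ifelse(strand == "-", end, start),
    sample_id)]
  ends[, .(count = .N), by = .(contig, strand, pos, sample_id)][
    order(contig, strand, pos)]
}

#' Combine per-sample end records into a position tally
#'
#' @param ... End-record data.tables (or a single list of them), each with
#'   columns `contig`, `strand`, `pos`, `sample_id`, `count`.
#' @return Long data.table keyed by (contig, strand, pos, sample_id) with
#'   summed counts.
#' @export
tally_positions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  tal <- data.table::rbindlist(parts, use.names = TRUE)
  tal[, .(count = sum(count)), by = .(contig, strand, pos, sample_id)][
    order(contig, strand, pos, sample_id)]
}

#' Build the multi-sample CPA position universe
#'
#' A position (contig, strand, coordinate) enters the universe only if it is
#' supported by at least one read in at least `min_samples_support` libraries;
#' counts of retained positions are kept in full (summed over all libraries
#' that observed them). Everything else is removed.
#'
#' @param tally Long tally from [tally_positions()] over every library in the
#'   run.
#' @param min_samples_support Minimum number of supporting libraries
#'   (default 2).
#' @return Long data.table of retained positions with per-sample counts.
#'   Attributes `n_removed_positions` and `n_removed_reads` report what was
#'   filtered.
#' @export
build_universe <- function(tally, min_samples_support = 2L) {
  n_lib <- length(unique(tally$sample_id))
  if (n_lib < min_samples_support)
    stop("run has ", n_lib, " libraries but min_samples_support = ",
         min_samples_support, "; cannot build a multi-sample universe")
  supp <- tally[count > 0L, .(n_samples = .N), by = .(contig, strand, pos)]
  keep <- supp[n_samples >= min_samples_support, .(contig, strand, pos)]
  out <- tally[keep, on = c("contig", "strand", "pos")]
  removed <- tally[!keep, on = c("contig", "strand", "pos")]
  data.table::setattr(out, "n_removed_positions",
                      nrow(unique(removed[, .(contig, strand, pos)])))
  data.table::setattr(out, "n_removed_reads", sum(removed$count))
  out[]
}
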