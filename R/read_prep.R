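#' Read paired FASTQ files into a read-pair table
#'
#' @param r1_path,r2_path FASTQ files for Read 1 and Read 2 (same order).
#' @return data.table with `id`, `read1`, `qual1`, `read2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files differ in read count")
  data.table::data.table(
    id = sub("\\s.*$", "", names(r1)),
    read1 = as.character(r1),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    read2 = as.character(r2),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write a read-pair table as paired FASTQ
#'
#' @param pairs data.table as produced by [read_fastq_pairs()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  fq <- function(seqs, quals, ids, path) {
    quals <- substr(quals, 1L, nchar(seqs))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  }
  fq(pairs$read1, pairs$qual1, pairs$id, r1_path)
  fq(pairs$read2, pairs$qual2, pairs$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Demultiplex read pairs by the Read 1 barcode
#'
#' The sample barcode is the first `barcode_len` bases of Read 1. Each pair is
#' routed to exactly one sample, or to the `"undetermined"` bin when its
#' barcode is not in the map (default exact matching; `max_mismatch = 1`
#' allows rescue of single-mismatch barcodes provided the match is unique).
#' The barcode is trimmed from routed Read 1 sequences and qualities.
#'
#' @param pairs Read-pair table ([read_fastq_pairs()]).
#' @param barcode_map Named character vector, barcode -> sample id.
#' @param barcode_len Barcode length (default 6).
#' @param max_mismatch 0 (exact, default) or 1.
#' @return List of read-pair tables, one per sample plus `undetermined`
#'   (always present, possibly empty). Attribute `report` is a data.table of
#'   per-bin pair counts.
#' @export
demultiplex <- function(pairs, barcode_map, barcode_len = 6L,
                        max_mismatch = 0L) {
  bcs <- names(barcode_map)
  if (is.null(bcs) || any(!nzchar(bcs)))
    stop("barcode_map must be a named vector barcode -> sample")
  if (any(nchar(bcs) != barcode_len))
    stop("all barcodes must have length ", barcode_len)
  if (anyDuplicated(bcs))
    stop("barcode collision in barcode_map")
  if (anyDuplicated(barcode_map))
    stop("two barcodes map to the same sample: ",
         barcode_map[duplicated(barcode_map)][1])
  obs <- substr(pairs$read1, 1L, barcode_len)
  hit <- barcode_map[obs]
  if (max_mismatch >= 1L) {
    miss <- which(is.na(hit))
    if (length(miss)) {
      bc_mat <- do.call(rbind, strsplit(bcs, ""))
      for (i in miss) {
        o <- strsplit(obs[i], "")[[1]]
        d <- rowSums(bc_mat != matrix(o, nrow = length(bcs),
                                      ncol = barcode_len, byrow = TRUE))
        cand <- which(d <= 1L)
        if (length(cand) == 1L) hit[i] <- barcode_map[[cand]]
      }
    }
  }
  bins <- c(sort(unique(unname(barcode_map))), "undetermined")
  out <- lapply(bins, function(b) {
    idx <- if (b == "undetermined") which(is.na(hit)) else which(hit == b)
    sub <- pairs[idx]
    if (b != "undetermined" && nrow(sub)) {
      sub[, read1 := substring(read1, barcode_len + 1L)]
      sub[, qual1 := substring(qual1, barcode_len + 1L)]
    }
    sub
  })
  names(out) <- bins
  rep <- data.table::data.table(
    sample_id = bins, pairs = vapply(out, nrow, integer(1)))
  data.table::setattr(out, "report", rep)
  out
}

#' Drop read pairs with a short mate
#'
#' Pairs where either mate is shorter than `min_read_len` nucleotides are
#' excluded (strictly shorter: a 50 nt mate passes the default filter).
#'
#' @param pairs Read-pair table.
#' @param min_read_len Minimum retained mate length (default 50).
#' @return Filtered table; attribute `n_dropped` holds the drop tally.
#' @export
length_filter <- function(pairs, min_read_len = 50L) {
  keep <- nchar(pairs$read1) >= min_read_len &
    nchar(pairs$read2) >= min_read_len
  out <- pairs[keep]
  if (any(!keep)) message("length_filter: dropped ", sum(!keep),
                          " pairs with a mate < ", min_read_len, " nt")
  data.table::setattr(out, "n_dropped", sum(!keep))
  out[]
}

#' Trim leading thymidine stretches from Read 2
#'
#' Removes the maximal run of T at the start of each sequence (mis-anchored
#' oligo-dT leaves residual polyA-tail complement at the Read 2 start).
#' Idempotent.
#'
#' @param seq Character vector of sequences over {A,C,G,T,N}.
#' @return List with `seq` (trimmed sequences) and `n_trimmed` (run lengths).
#' @export
#' @examples
#' trim_leading_T("TTTTACGT") # "ACGT", 4 removed
trim_leading_T <- function(seq) {
  m <- regmatches(seq, regexpr("^T*", seq))
  n <- nchar(m)
  list(seq = substring(seq, n + 1L), n_trimmed = n)
}

#' Truncate sequences for remapping
#'
#' Shortens sequences to their first `len` nucleotides (removes occasional
#' palindromic artifacts at read ends); shorter sequences pass unchanged.
#'
#' @param seq Character vector.
#' @param len Maximum retained length (default 50).
#' @return Character vector of truncated sequences.
#' @export
truncate_for_remap <- function(seq, len = 50L) {
  substr(seq, 1L, len)
}

#' Alignment identity filter
#'
#' Identity is defined at the alignment stage as
#' `1 - edit_distance / aligned_length`; reads at or below the cutoff are
#' excluded (the cutoff itself is excluded, i.e. identity must be strictly
#' greater than `max_excluded_identity`).
#'
#' @param edit_distance Integer vector of edit distances (e.g. `NM` tags).
#' @param aligned_length Aligned lengths.
#' @param max_excluded_identity Reads with identity <= this value are dropped
#'   (default 0.95).
#' @return Logical vector, `TRUE` for retained reads.
#' @export
identity_filter <- function(edit_distance, aligned_length,
                            max_excluded_identity = 0.95) {
  identity <- 1 - edit_distance / aligned_length
  identity > max_excluded_identity
}
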