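#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique contig names.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names in ", path)
  genome
}

#' Write a genome FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

check_contig <- function(genome, contig) {
  if (!contig %in% names(genome))
    stop("contig '", contig, "' not present in genome")
}

#' Extract genomic sequence, strand-aware
#'
#' Coordinates are 1-based fully closed. On the minus strand the
#' reverse-complemented (sense) sequence is returned. Out-of-range queries are
#' rejected, never silently truncated; use [get_window()] where clipping to
#' contig bounds is the intended behaviour.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param contig Contig name.
#' @param start,end 1-based closed interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar, sense-orientation sequence.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(I = "ACGTACGT"))
#' get_seq(g, "I", 1, 4, "+") # "ACGT"
#' get_seq(g, "I", 1, 4, "-") # "ACGT" reverse-complemented
get_seq <- function(genome, contig, start, end, strand = "+") {
  check_contig(genome, contig)
  len <- Biostrings::width(genome[contig])
  if (start < 1L || end > len || start > end)
    stop("out-of-range query ", contig, ":", start, "-", end,
         " (contig length ", len, ")")
  s <- Biostrings::subseq(genome[[contig]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract a genomic window clipped to contig bounds
#'
#' Like [get_seq()] but the requested interval is intersected with the contig;
#' the number of bases clipped on each side is reported so callers can decide
#' how to treat unavailable sequence.
#'
#' @inheritParams get_seq
#' @return List with `seq` (sense orientation, possibly shorter than
#'   requested), `clipped_start` and `clipped_end` (bases lost at the
#'   requested interval's low/high genomic end).
#' @export
get_window <- function(genome, contig, start, end, strand = "+") {
  check_contig(genome, contig)
  len <- Biostrings::width(genome[contig])
  start <- as.integer(start)
  end <- as.integer(end)
  lo <- max(start, 1L)
  hi <- min(end, len)
  if (lo > hi)
    return(list(seq = "", clipped_start = end - start + 1L, clipped_end = 0L))
  list(seq = get_seq(genome, contig, lo, hi, strand),
       clipped_start = lo - start,
       clipped_end = end - hi)
}

#' Replace genomic sequence in place (simulator support)
#'
#' Writes `replacement` (given in sense orientation for `strand`) over the
#' 1-based closed interval.
#'
#' @inheritParams get_seq
#' @param replacement Character scalar; reverse-complemented before insertion
#'   when `strand == "-"`.
#' @return Modified `DNAStringSet`.
#' @keywords internal
set_seq <- function(genome, contig, start, replacement, strand = "+") {
  check_contig(genome, contig)
  s <- Biostrings::DNAString(replacement)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  end <- start + length(s) - 1L
  len <- Biostrings::width(genome[contig])
  if (start < 1L || end > len)
    stop("replacement out of range on ", contig)
  x <- genome[[contig]]
  genome[[contig]] <- c(Biostrings::subseq(x, 1L, start - 1L), s,
                        if (end < len) Biostrings::subseq(x, end + 1L, len)
                        else Biostrings::DNAString(""))
  genome
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)
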