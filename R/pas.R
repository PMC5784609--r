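#' Scan for a polyadenylation signal upstream of a CPA site
#'
#' Searches the sense-strand sequence for each ranked PAS hexamer whose last
#' base falls within `pas_window` (default 8--25) nt upstream of the CPA base.
#' The offset of a hit is the distance from the motif's last base to the CPA
#' base. Among all hits the one with the best (lowest) motif rank is reported;
#' among equal-rank hits, the one whose offset is closest to the modal offset
#' of 19 nt; remaining ties go to the 3'-most hit (smallest offset). A window
#' truncated by the contig start is scanned over its available portion.
#'
#' @param genome `DNAStringSet`.
#' @param contig,strand,cpa Site coordinates (1-based CPA base, transcript
#'   strand).
#' @param config A [pipeline_config()].
#' @return data.table row (`pas_motif` in RNA alphabet, `pas_rank`,
#'   `pas_offset`) or a row of NAs when no listed motif is in the window.
#' @export
scan_pas <- function(genome, contig, strand, cpa, config = pipeline_config()) {
  lo_off <- config$pas_window[1]
  hi_off <- config$pas_window[2]
  # motif end at offset o occupies sense positions [o+5, o] upstream of cpa;
  # fetch the sense region covering motif starts at hi_off+5 .. ends at lo_off
  if (strand == "+") {
    w <- get_window(genome, contig, cpa - hi_off - 5L, cpa - lo_off, "+")
  } else {
    w <- get_window(genome, contig, cpa + lo_off, cpa + hi_off + 5L, "-")
  }
  none <- data.table::data.table(pas_motif = NA_character_,
                                 pas_rank = NA_integer_,
                                 pas_offset = NA_integer_)
  s <- w$seq
  if (nchar(s) < 6L) return(none)
  # sense-window index i ends a hexamer at offset hi_off + 1 - (i + clip - 1)
  clip <- if (strand == "+") w$clipped_start else w$clipped_end
  hits <- list()
  for (r in seq_along(config$pas_motifs)) {
    motif <- rna_to_dna(config$pas_motifs[r])
    # matchPattern reports overlapping occurrences, unlike fixed-string regex
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
    if (length(m) == 0L) next
    ends_idx <- Biostrings::end(m)
    offs <- hi_off + 5L + 1L - (ends_idx + clip)
    offs <- offs[offs >= lo_off & offs <= hi_off]
    if (length(offs))
      hits[[length(hits) + 1L]] <- data.table::data.table(
        pas_motif = config$pas_motifs[r], pas_rank = r, pas_offset = offs)
  }
  if (!length(hits)) return(none)
  h <- data.table::rbindlist(hits)
  h <- h[order(pas_rank, abs(pas_offset - 19L), pas_offset)]
  h[1]
}

#' Vectorized PAS annotation over a site table
#'
#' @param sites data.table with `contig`, `strand` and a CPA coordinate column
#'   (`rep_pos` or `pos`).
#' @param genome `DNAStringSet`.
#' @param config A [pipeline_config()].
#' @return `sites` with `pas_motif`, `pas_rank`, `pas_offset` columns added.
#' @export
annotate_pas <- function(sites, genome, config = pipeline_config()) {
  pos_col <- if ("rep_pos" %in% names(sites)) "rep_pos" else "pos"
  ann <- data.table::rbindlist(lapply(seq_len(nrow(sites)), function(i) {
    scan_pas(genome, sites$contig[i], sites$strand[i],
             sites[[pos_col]][i], config)
  }))
  cbind(sites, ann)
}
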