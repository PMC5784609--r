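#' Filter CPA clusters caused by internal oligo-dT mispriming
#'
#' Oligo-dT priming on a genomically templated A-rich tract produces a
#' spurious 3' end whose downstream genomic sequence mimics a polyA tail. For
#' each cluster the sense-strand window of `mispriming_downstream_window`
#' (default 5) bases beginning at the representative CPA base is inspected.
#' The A-rule fires when the first base is A and at least `mispriming_min_A`
#' (default 4) of the window bases are A. Clusters with the A-rule satisfied
#' and no PAS hexamer in the upstream scan window are removed as mispriming
#' artifacts; clusters with the A-rule satisfied but a PAS hit are flagged as
#' potential true positives, kept in a side set, and excluded from the final
#' site collection. Bases beyond the contig end are treated as non-A.
#'
#' @param clusters A `cpa_clusters` object.
#' @param genome `DNAStringSet` covering all cluster contigs.
#' @param config A [pipeline_config()].
#' @return List with `final` (retained `cpa_clusters`), `flagged`
#'   (PAS-positive A-rich `cpa_clusters`, the side set) and `verdicts`
#'   (data.table: cluster_id, status, downstream_seq, pas_motif, pas_rank,
#'   pas_offset).
#' @export
apply_mispriming_filter <- function(clusters, genome,
                                    config = pipeline_config()) {
  s <- clusters$sites
  missing <- setdiff(unique(s$contig), names(genome))
  if (length(missing))
    stop("genome lacks contig(s): ", paste(missing, collapse = ", "))
  wlen <- config$mispriming_downstream_window
  down <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    w <- if (s$strand[i] == "+")
      get_window(genome, s$contig[i], s$rep_pos[i],
                 s$rep_pos[i] + wlen - 1L, "+")
    else
      get_window(genome, s$contig[i], s$rep_pos[i] - wlen + 1L,
                 s$rep_pos[i], "-")
    if (w$clipped_start > 0L || w$clipped_end > 0L)
      message("mispriming filter: window of ", s$cluster_id[i],
              " extends past contig end; missing bases treated as non-A")
    down[i] <- w$seq
  }
  first_a <- substr(down, 1L, 1L) == "A"
  n_a <- nchar(gsub("[^A]", "", down))
  a_rule <- first_a & n_a >= config$mispriming_min_A
  pas <- annotate_pas(s[, .(cluster_id, contig, strand, rep_pos)],
                      genome, config)
  verdicts <- data.table::data.table(
    cluster_id = s$cluster_id,
    status = ifelse(!a_rule, "retained",
                    ifelse(is.na(pas$pas_motif), "removed_mispriming",
                           "flagged_pas_positive")),
    downstream_seq = down,
    pas_motif = pas$pas_motif,
    pas_rank = pas$pas_rank,
    pas_offset = pas$pas_offset)
  tab <- table(factor(verdicts$status,
                      c("retained", "removed_mispriming",
                        "flagged_pas_positive")))
  message("mispriming filter: ", tab[["retained"]], " retained, ",
          tab[["removed_mispriming"]], " removed, ",
          tab[["flagged_pas_positive"]], " flagged PAS-positive")
  list(final = filter_clusters(clusters,
                               verdicts[status == "retained", cluster_id]),
       flagged = filter_clusters(clusters,
                                 verdicts[status == "flagged_pas_positive",
                                          cluster_id]),
       verdicts = verdicts)
}
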