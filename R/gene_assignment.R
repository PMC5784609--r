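#' Assign CPA clusters to genes
#'
#' A cluster whose CPA base overlaps the exons of exactly one same-strand gene
#' is assigned by `exon_overlap`; overlap with exons of more than one gene is
#' ambiguous and the cluster is left unassigned (`unassigned_ambiguous`).
#' Without exon overlap, the cluster is assigned by `upstream_proximity` to
#' the gene whose nearest same-strand exon 3' boundary lies 5' of the CPA base
#' within `max_upstream_assign` nt (the gene is upstream of the site); ties at
#' equal distance go to the lexically first gene id. Otherwise the cluster is
#' `unassigned_novel`. Exon-overlap assignment is never overridden by
#' proximity, and a cluster is never assigned to an opposite-strand gene.
#'
#' @param sites data.table of representative sites (columns `cluster_id`,
#'   `contig`, `strand`, `rep_pos`), e.g. `clusters$sites`.
#' @param models A [gene_models()] collection.
#' @param max_upstream_assign Maximum upstream distance in nt (default 1500).
#' @return data.table: `cluster_id`, `contig`, `strand`, `rep_pos`,
#'   `gene_id` (NA when unassigned), `assignment`, `assign_distance` (0 for
#'   exon overlap, exon-end distance for proximity).
#' @export
assign_clusters <- function(sites, models, max_upstream_assign = 1500L) {
  ex <- models$exons
  ex_gr <- GenomicRanges::GRanges(ex$contig,
                                  IRanges::IRanges(ex$start, ex$end),
                                  strand = ex$strand)
  site_gr <- GenomicRanges::GRanges(sites$contig,
                                    IRanges::IRanges(sites$rep_pos,
                                                     sites$rep_pos),
                                    strand = sites$strand)
  ov <- GenomicRanges::findOverlaps(site_gr, ex_gr)
  ov_dt <- data.table::data.table(
    site = S4Vectors::queryHits(ov),
    gene_id = ex$gene_id[S4Vectors::subjectHits(ov)])
  ov_dt <- unique(ov_dt)
  genes_per_site <- ov_dt[, .(n_genes = .N,
                              gene_id = gene_id[1]), by = site]
  out <- data.table::data.table(
    cluster_id = sites$cluster_id, contig = sites$contig,
    strand = sites$strand, rep_pos = sites$rep_pos,
    gene_id = NA_character_, assignment = "unassigned_novel",
    assign_distance = NA_integer_)
  if (nrow(genes_per_site)) {
    uniq <- genes_per_site[n_genes == 1L]
    out[uniq$site, `:=`(gene_id = uniq$gene_id, assignment = "exon_overlap",
                        assign_distance = 0L)]
    amb <- genes_per_site[n_genes > 1L]
    out[amb$site, assignment := "unassigned_ambiguous"]
  }
  # proximity: nearest same-strand exon 3' boundary upstream of the site
  todo <- which(out$assignment == "unassigned_novel")
  if (length(todo)) {
    ex3 <- ex[, .(gene_id, contig, strand,
                  exon_end = ifelse(strand == "+", end, start))]
    for (i in todo) {
      cand <- ex3[contig == out$contig[i] & strand == out$strand[i]]
      d <- if (out$strand[i] == "+") out$rep_pos[i] - cand$exon_end
           else cand$exon_end - out$rep_pos[i]
      ok <- which(d > 0L & d <= max_upstream_assign)
      if (length(ok)) {
        best <- ok[order(d[ok], cand$gene_id[ok])][1]
        out[i, `:=`(gene_id = cand$gene_id[best],
                    assignment = "upstream_proximity",
                    assign_distance = as.integer(d[best]))]
      }
    }
  }
  out[]
}

#' Classify an assigned CPA site and measure its 3'UTR
#'
#' For protein-coding genes, a CPA site strictly 3' of the gene's 3'-most stop
#' codon (strand-aware) is tandem APA; its 3'UTR length is the number of
#' genomic bases from the first base 3' of the stop codon through the CPA base
#' inclusive (introns within the UTR are not subtracted). A site at or 5' of
#' the stop codon is CDS-internal and has no UTR length. Sites on non-coding
#' genes are classed `ncRNA_end`.
#'
#' @param cpa CPA coordinate (1-based).
#' @param strand Transcript strand.
#' @param stop_codon Genomic coordinate of the gene's 3'-most stop-codon base
#'   (NA for non-coding genes).
#' @param biotype Gene biotype.
#' @return List with `apa_class` (`tandem`/`cds_internal`/`ncRNA_end`) and
#'   `utr_length` (NA unless tandem).
#' @export
#' @examples
#' classify_and_measure(1000150, "+", 1000000, "protein_coding") # tandem, 150
classify_and_measure <- function(cpa, strand, stop_codon, biotype) {
  if (biotype != "protein_coding" || is.na(stop_codon))
    return(list(apa_class = "ncRNA_end", utr_length = NA_integer_))
  d <- if (strand == "+") cpa - stop_codon else stop_codon - cpa
  if (d > 0L) list(apa_class = "tandem", utr_length = as.integer(d))
  else list(apa_class = "cds_internal", utr_length = NA_integer_)
}

#' Build the annotated 3'UTR isoform table
#'
#' Chains gene assignment, APA classification, UTR measurement and PAS
#' annotation over a filtered cluster collection, then derives per-sample
#' usage. Isoforms of each gene are indexed 5'->3' (`isoform_rank` 1 =
#' most proximal) so proximal/distal labels are well defined downstream.
#'
#' @param clusters A `cpa_clusters` object (post mispriming filter).
#' @param models A [gene_models()] collection.
#' @param genome `DNAStringSet`.
#' @param config A [pipeline_config()].
#' @return List with `isoforms` (one row per cluster: assignment, class, UTR
#'   length, PAS annotation, isoform_rank within gene) and `usage` (long
#'   table: gene_id, cluster_id, sample_id, count, fraction; fractions sum to
#'   1 per expressed gene and sample).
#' @export
annotate_isoforms <- function(clusters, models, genome,
                              config = pipeline_config()) {
  asn <- assign_clusters(clusters$sites, models, config$max_upstream_assign)
  asn <- merge(asn, models$genes[, .(gene_id, biotype, stop_codon)],
               by = "gene_id", all.x = TRUE, sort = FALSE)
  cls <- lapply(seq_len(nrow(asn)), function(i) {
    if (is.na(asn$gene_id[i]))
      return(list(apa_class = NA_character_, utr_length = NA_integer_))
    classify_and_measure(asn$rep_pos[i], asn$strand[i],
                         asn$stop_codon[i], asn$biotype[i])
  })
  asn[, apa_class := vapply(cls, `[[`, character(1), "apa_class")]
  asn[, utr_length := vapply(cls, `[[`, integer(1), "utr_length")]
  iso <- annotate_pas(asn, genome, config)
  # 5'->3' isoform index within each assigned gene
  iso[, isoform_rank := NA_integer_]
  iso[!is.na(gene_id),
      isoform_rank := as.integer(ifelse(strand == "+",
                                        rank(rep_pos), rank(-rep_pos))),
      by = gene_id]
  data.table::setcolorder(iso, c("cluster_id", "gene_id", "contig", "strand",
                                 "rep_pos", "assignment", "apa_class",
                                 "utr_length", "isoform_rank"))
  usage <- merge(clusters$counts,
                 iso[!is.na(gene_id), .(cluster_id, gene_id)],
                 by = "cluster_id")
  usage[, fraction := count / sum(count), by = .(gene_id, sample_id)]
  list(isoforms = iso[order(cluster_id)],
       usage = usage[order(gene_id, cluster_id, sample_id),
                     .(gene_id, cluster_id, sample_id, count, fraction)])
}
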