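#' Major isoform per gene and sample
#'
#' The isoform with the highest read count; ties are broken 3'-most (the most
#' distal isoform), consistent with the cluster-level tie rule.
#'
#' @param usage Long usage table with `isoform_rank` available through
#'   `isoforms`, or columns `gene_id`, `cluster_id`, `sample_id`, `count`.
#' @param isoforms Isoform table from [annotate_isoforms()] carrying
#'   `isoform_rank` (1 = most proximal).
#' @return data.table: `gene_id`, `sample_id`, `cluster_id` of the major
#'   isoform (genes with zero total in a sample are absent).
#' @export
major_isoform <- function(usage, isoforms) {
  u <- merge(data.table::as.data.table(usage),
             isoforms[, .(cluster_id, isoform_rank)], by = "cluster_id")
  u <- u[count > 0L]
  u[order(-count, -isoform_rank),
    .(cluster_id = cluster_id[1]), by = .(gene_id, sample_id)][
      order(gene_id, sample_id)]
}

# two-sided Fisher probability-mass p-value for table [[a, b], [c, d]]
fisher_p2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))$p.value
}

#' Test per-isoform differential usage between two conditions
#'
#' For every gene with at least two retained isoforms and a per-condition
#' total of at least `min_test_reads`, each isoform is compared to the
#' collective usage of all other isoforms: the 2x2 table
#' `[isoform count, others' sum] x [condition A, condition B]` is evaluated
#' with a two-sided exact hypergeometric (Fisher) test summing the
#' probabilities of all tables at most as probable as the observed one.
#' p-values are collected over all isoforms genome-wide and adjusted by
#' Benjamini-Hochberg. Replicates are pooled per condition. Genes with a
#' zero or sub-threshold total in either condition are skipped and logged.
#'
#' @param counts data.table with columns `gene_id`, `cluster_id`, `n_a`,
#'   `n_b` (pooled isoform counts in conditions A and B); see
#'   [pool_condition_counts()].
#' @param isoforms Optional isoform table providing `isoform_rank` for
#'   direction labels.
#' @param fdr_threshold Significance threshold on q (default 0.05).
#' @param min_test_reads Minimum per-condition gene total (default 20).
#' @return data.table of class-augmented switch results: usage fractions in
#'   both conditions, p, BH q, `significant`, and `direction`
#'   (`proximal_shift`/`distal_shift` in condition B relative to A, from the
#'   gene's 5'->3' isoform ordering) when ranks are available.
#' @export
test_switch <- function(counts, isoforms = NULL, fdr_threshold = 0.05,
                        min_test_reads = 20L) {
  d <- data.table::as.data.table(counts)
  stopifnot(all(c("gene_id", "cluster_id", "n_a", "n_b") %in% names(d)))
  d[, `:=`(tot_a = sum(n_a), tot_b = sum(n_b)), by = gene_id]
  skip <- unique(d[tot_a < min_test_reads | tot_b < min_test_reads, gene_id])
  n_iso <- d[, .N, by = gene_id]
  skip <- union(skip, n_iso[N < 2L, gene_id])
  if (length(skip))
    message("test_switch: skipped ", length(skip),
            " gene(s) with <2 isoforms or insufficient per-condition reads")
  t <- d[!gene_id %in% skip]
  if (nrow(t) == 0L) return(t[, .(gene_id, cluster_id)])
  t[, p_value := mapply(fisher_p2, n_a, tot_a - n_a, n_b, tot_b - n_b)]
  t[, q_value := stats::p.adjust(p_value, method = "BH")]
  t[, `:=`(frac_a = n_a / tot_a, frac_b = n_b / tot_b)]
  t[, significant := q_value < fdr_threshold]
  if (!is.null(isoforms)) {
    t <- merge(t, isoforms[, .(cluster_id, isoform_rank)],
               by = "cluster_id", sort = FALSE)
    # gaining usage in B on an isoform more proximal than the gene's centre
    # of ordering is a proximal shift, and conversely
    t[, direction := {
      centred <- isoform_rank - mean(isoform_rank)
      ifelse((frac_b - frac_a) * centred < 0, "proximal_shift",
             ifelse((frac_b - frac_a) * centred > 0, "distal_shift",
                    NA_character_))
    }, by = gene_id]
  }
  data.table::setorder(t, gene_id, cluster_id)
  t[, .SD, .SDcols = setdiff(names(t), c("tot_a", "tot_b"))]
}

#' Pool per-sample isoform counts into two conditions
#'
#' @param usage Long usage table (`gene_id`, `cluster_id`, `sample_id`,
#'   `count`).
#' @param conditions Named vector sample_id -> condition label (exactly two
#'   distinct labels; the lexically first is condition A).
#' @return data.table `gene_id`, `cluster_id`, `n_a`, `n_b`.
#' @export
pool_condition_counts <- function(usage, conditions) {
  u <- data.table::as.data.table(usage)
  lab <- sort(unique(unname(conditions)))
  if (length(lab) != 2L) stop("need exactly two condition labels, got ",
                              length(lab))
  u[, condition := conditions[sample_id]]
  pooled <- u[, .(n = sum(count)), by = .(gene_id, cluster_id, condition)]
  wide <- data.table::dcast(pooled, gene_id + cluster_id ~ condition,
                            value.var = "n", fill = 0L)
  data.table::setnames(wide, lab, c("n_a", "n_b"))
  wide[]
}

#' Per-gene switch catalog
#'
#' Summarizes [test_switch()] output: a gene enters the catalog when any of
#' its isoforms is significant; a "major switch" additionally requires that
#' the usage-dominant isoform differs between the two conditions. Direction
#' is labelled from the gene's 5'->3' isoform ordering: a major isoform of
#' lower rank in condition B than in A is a proximal shift in B.
#'
#' @param results [test_switch()] output (with `isoform_rank`).
#' @param fdr_threshold Threshold on q (default 0.05).
#' @return List with `catalog` (per-gene table: major isoform per condition,
#'   major_switch flag, direction) and `summary` (counts of significant
#'   genes, major switches, and shifts by direction).
#' @export
switch_catalog <- function(results, fdr_threshold = 0.05) {
  r <- data.table::as.data.table(results)
  sig_genes <- unique(r[q_value < fdr_threshold, gene_id])
  if (length(sig_genes) == 0L) {
    empty <- data.table::data.table(
      gene_id = character(), major_a = character(), major_b = character(),
      major_switch = logical(), min_q = numeric(), direction = character())
    return(list(catalog = empty,
                summary = data.table::data.table(
                  n_significant_genes = 0L, n_major_switches = 0L,
                  n_proximal_shift = 0L, n_distal_shift = 0L)))
  }
  cat_dt <- r[gene_id %in% sig_genes, {
    ma <- cluster_id[order(-frac_a, -isoform_rank)][1]
    mb <- cluster_id[order(-frac_b, -isoform_rank)][1]
    ra <- isoform_rank[cluster_id == ma]
    rb <- isoform_rank[cluster_id == mb]
    list(major_a = ma, major_b = mb, major_switch = ma != mb,
         min_q = min(q_value),
         direction = if (ma == mb) NA_character_
                     else if (rb < ra) "proximal_shift" else "distal_shift")
  }, by = gene_id]
  summary <- data.table::data.table(
    n_significant_genes = length(sig_genes),
    n_major_switches = sum(cat_dt$major_switch),
    n_proximal_shift = sum(cat_dt$direction == "proximal_shift", na.rm = TRUE),
    n_distal_shift = sum(cat_dt$direction == "distal_shift", na.rm = TRUE))
  list(catalog = cat_dt[order(gene_id)], summary = summary)
}

#' 3'UTR length-distribution statistics
#'
#' Per-sample median and quartiles of 3'UTR length over expressed tandem
#' isoforms, with configurable exclusions: a gene exclusion list (e.g. gene
#' families dominating the library) and/or removal of the most highly
#' expressed isoforms (those above the `1 - exclude_top_frac` expression
#' quantile within the sample).
#'
#' @param usage Long usage table restricted to the retained isoform set.
#' @param isoforms Isoform table with `utr_length` and `apa_class`.
#' @param exclude_genes Character vector of gene ids to drop (default none).
#' @param exclude_top_frac Fraction of top-expressed isoforms to drop per
#'   sample (default 0).
#' @return data.table per sample: `n`, `median`, `q25`, `q75` of UTR length.
#'   Samples with an empty set after exclusion appear with `n = 0` and NA
#'   statistics.
#' @export
utr_length_stats <- function(usage, isoforms, exclude_genes = character(),
                             exclude_top_frac = 0) {
  u <- merge(data.table::as.data.table(usage),
             isoforms[apa_class == "tandem",
                      .(cluster_id, utr_length)], by = "cluster_id")
  u <- u[count > 0L & !gene_id %in% exclude_genes]
  samples <- sort(unique(u$sample_id))
  data.table::rbindlist(lapply(samples, function(s) {
    x <- u[sample_id == s]
    if (exclude_top_frac > 0 && nrow(x)) {
      cut <- stats::quantile(x$count, 1 - exclude_top_frac, type = 1L)
      x <- x[count <= cut]
    }
    if (nrow(x) == 0L)
      return(data.table::data.table(sample_id = s, n = 0L,
                                    median = NA_real_, q25 = NA_real_,
                                    q75 = NA_real_))
    q <- stats::quantile(x$utr_length, c(.25, .5, .75))
    data.table::data.table(sample_id = s, n = nrow(x),
                           median = unname(q[2]), q25 = unname(q[1]),
                           q75 = unname(q[3]))
  }))
}
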