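#' Build gene- and isoform-level count matrices
#'
#' @param usage Long usage table from [annotate_isoforms()] (`gene_id`,
#'   `cluster_id`, `sample_id`, `count`).
#' @return List of integer matrices `gene` (genes x samples) and `isoform`
#'   (isoforms x samples, rownames `gene_id:cluster_id`). Each gene row equals
#'   the sum of its isoform rows.
#' @export
count_matrices <- function(usage) {
  samples <- sort(unique(usage$sample_id))
  to_mat <- function(dt, key) {
    wide <- data.table::dcast(dt, stats::as.formula(paste(key, "~ sample_id")),
                              value.var = "count", fill = 0L)
    m <- as.matrix(wide[, -1, with = FALSE])
    rownames(m) <- wide[[key]]
    m[, samples, drop = FALSE]
  }
  gene <- to_mat(usage[, .(count = sum(count)), by = .(gene_id, sample_id)],
                 "gene_id")
  iso_dt <- usage[, .(iso = paste0(gene_id, ":", cluster_id),
                      sample_id, count)]
  iso <- to_mat(iso_dt[, .(count = sum(count)), by = .(iso, sample_id)], "iso")
  list(gene = gene, isoform = iso)
}

#' Median-of-ratios library size factors
#'
#' The size factor of library j is the median over qualifying genes g of
#' `count[g, j] / geometric mean over libraries of count[g, ]`, computed with
#' the DESeq2 size-factor calculation. Only rows with nonzero counts in every
#' library qualify; with none, set `pseudo_reference = TRUE` to build the
#' geometric-mean reference over positive counts only.
#'
#' @param mat Non-negative count matrix, genes x libraries.
#' @param pseudo_reference Fall back to a positive-count geometric-mean
#'   reference when no row is all-positive (default FALSE).
#' @return Named numeric vector of positive per-library factors.
#' @export
#' @examples
#' m <- cbind(A = c(10, 20), B = c(20, 40))
#' size_factors(m) # c(1/sqrt(2), sqrt(2))
size_factors <- function(mat, pseudo_reference = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two libraries")
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in every library; rerun with ",
           "pseudo_reference = TRUE to use a positive-count reference")
    lg <- log(mat)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    geo[!is.finite(geo) | rowSums(mat > 0) == 0L] <- 0
    return(DESeq2::estimateSizeFactorsForMatrix(mat, geoMeans = geo))
  }
  DESeq2::estimateSizeFactorsForMatrix(mat)
}

#' Filter low-abundance 3'UTR isoforms
#'
#' Within each sample an isoform is retained iff its count is at least
#' `min_isoform_fraction` of its gene's total in that sample; the gene's
#' maximal isoform in a sample is always retained (so an expressed gene never
#' loses all isoforms). The reported cross-sample set is the union of the
#' per-sample retained sets. Idempotent.
#'
#' @param usage Long usage table (`gene_id`, `cluster_id`, `sample_id`,
#'   `count`).
#' @param min_isoform_fraction Threshold fraction (default 0.05).
#' @return List with `usage` (rows retained in their sample, fractions
#'   recomputed), `retained` (per-sample logical table) and `kept_isoforms`
#'   (union set data.table of gene_id, cluster_id).
#' @export
filter_low_abundance_isoforms <- function(usage, min_isoform_fraction = 0.05) {
  u <- data.table::copy(data.table::as.data.table(usage))
  u[, total := sum(count), by = .(gene_id, sample_id)]
  u[, retained := total > 0L &
      (count >= min_isoform_fraction * total | count == max(count)) &
      count > 0L,
    by = .(gene_id, sample_id)]
  kept <- unique(u[retained == TRUE, .(gene_id, cluster_id)])
  filtered <- u[retained == TRUE][, total := NULL][, retained := NULL]
  filtered[, fraction := count / sum(count), by = .(gene_id, sample_id)]
  list(usage = filtered[],
       retained = u[, .(gene_id, cluster_id, sample_id, count, retained)],
       kept_isoforms = kept[order(gene_id, cluster_id)])
}

#' Normalized expression and pairwise log2 fold-changes
#'
#' @param mat Raw count matrix (genes x libraries).
#' @param factors Size factors from [size_factors()].
#' @param pseudocount Added to both normalized values before the log ratio
#'   (default 1).
#' @return List with `normalized` (matrix `raw / factor`) and `log2fc(a, b)`,
#'   a function returning per-gene `log2((norm_a + pc) / (norm_b + pc))`.
#' @export
expression_table <- function(mat, factors, pseudocount = 1) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(factors))
  norm <- sweep(mat, 2L, factors, "/")
  list(normalized = norm,
       log2fc = function(a, b) {
         log2((norm[, a] + pseudocount) / (norm[, b] + pseudocount))
       })
}

#' Per-chromosome expression profile
#'
#' Mean and median normalized expression per contig and library over
#' expressed genes, plus the X:autosome ratio of means. A library with no
#' expressed X-linked gene gets ratio 0 with an explicit flag.
#'
#' @param norm Normalized gene matrix (genes x libraries).
#' @param models A [gene_models()] collection (gene -> contig map). Genes on
#'   contigs absent from the annotation are excluded with a warning.
#' @param x_contig Name of the X chromosome contig (default `"X"`).
#' @param min_expr Expression floor defining an expressed gene (default 1
#'   normalized count).
#' @return List with `profile` (data.table: contig, sample_id, n_genes,
#'   mean_expr, median_expr) and `x_autosome` (data.table: sample_id, ratio,
#'   zero_x flag).
#' @export
chromosome_profile <- function(norm, models, x_contig = "X", min_expr = 1) {
  map <- models$genes[, .(gene_id, contig)]
  unknown <- setdiff(rownames(norm), map$gene_id)
  if (length(unknown)) {
    warning(length(unknown), " gene(s) absent from annotation excluded ",
            "from chromosome profile")
    norm <- norm[rownames(norm) %in% map$gene_id, , drop = FALSE]
  }
  long <- data.table::data.table(
    gene_id = rep(rownames(norm), ncol(norm)),
    sample_id = rep(colnames(norm), each = nrow(norm)),
    expr = as.vector(norm))
  long <- merge(long, map, by = "gene_id")
  expressed <- long[expr >= min_expr]
  profile <- expressed[, .(n_genes = .N, mean_expr = mean(expr),
                           median_expr = stats::median(expr)),
                       by = .(contig, sample_id)][order(contig, sample_id)]
  xa <- data.table::rbindlist(lapply(sort(unique(long$sample_id)),
                                     function(s) {
    x_mean <- if (nrow(expressed[sample_id == s & contig == x_contig]))
      expressed[sample_id == s & contig == x_contig, mean(expr)] else 0
    a_mean <- if (nrow(expressed[sample_id == s & contig != x_contig]))
      expressed[sample_id == s & contig != x_contig, mean(expr)] else NA_real_
    data.table::data.table(sample_id = s,
                           ratio = if (x_mean == 0) 0 else x_mean / a_mean,
                           zero_x = x_mean == 0)
  }))
  list(profile = profile, x_autosome = xa)
}
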