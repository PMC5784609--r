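#' Greedy abundance-ranked clustering of 3'-end positions
#'
#' Positions in the universe are processed in descending order of summed read
#' count. The unassigned position with the highest count seeds a cluster and
#' absorbs every unassigned position within `+/- window` nt on the same contig
#' and strand; absorbed positions can never seed later clusters. Ties are
#' broken 3'-most: on the plus strand the higher coordinate wins, on the minus
#' strand the lower coordinate. When equally supported positions are more than
#' a window apart, the 3'-most is processed first within each contig/strand,
#' contigs in lexical order, so the procedure is a total order and the result
#' is independent of input row order.
#'
#' @param universe Long position tally from [build_universe()] (columns
#'   `contig`, `strand`, `pos`, `sample_id`, `count`).
#' @param window Half-width of the clustering window in nt (default 12).
#' @return Object of class `"cpa_clusters"`: list of data.tables `sites`
#'   (cluster_id, contig, strand, rep_pos, n_members, total), `members`
#'   (cluster_id, pos, count) and `counts` (cluster_id, sample_id, count).
#' @export
#' @examples
#' u <- data.table::data.table(contig = "I", strand = "+",
#'   pos = c(100L, 105L, 113L), sample_id = "S1", count = c(10L, 3L, 2L))
#' cl <- cluster_sites(u)
#' cl$sites$rep_pos # 100 and 113: |113 - 100| = 13 exceeds the +/-12 window
cluster_sites <- function(universe, window = 12L) {
  totals <- universe[, .(total = sum(count)), by = .(contig, strand, pos)]
  # total processing order: count desc, contig lexical, 3'-most first
  totals[, rank_5p := ifelse(strand == "+", -pos, pos)]
  data.table::setorder(totals, -total, contig, strand, rank_5p)
  groups <- split(totals, by = c("contig", "strand"), sorted = TRUE)
  member_list <- lapply(groups, function(g) {
    n <- nrow(g)
    assigned <- logical(n)
    ord <- order(-g$total, g$rank_5p)
    res <- vector("list", n)
    k <- 0L
    for (i in ord) {
      if (assigned[i]) next
      members <- which(!assigned & abs(g$pos - g$pos[i]) <= window)
      assigned[members] <- TRUE
      k <- k + 1L
      res[[k]] <- data.table::data.table(
        contig = g$contig[1], strand = g$strand[1],
        rep_pos = g$pos[i], pos = g$pos[members], count = g$total[members])
    }
    data.table::rbindlist(res[seq_len(k)])
  })
  mem <- data.table::rbindlist(member_list)
  if (nrow(mem) == 0L) {
    empty <- list(
      sites = data.table::data.table(cluster_id = character(),
        contig = character(), strand = character(), rep_pos = integer(),
        n_members = integer(), total = integer()),
      members = data.table::data.table(cluster_id = character(),
        pos = integer(), count = integer()),
      counts = data.table::data.table(cluster_id = character(),
        sample_id = character(), count = integer()))
    return(structure(empty, class = "cpa_clusters"))
  }
  sites <- mem[, .(n_members = .N, total = sum(count)),
               by = .(contig, strand, rep_pos)]
  data.table::setorder(sites, contig, rep_pos, strand)
  sites[, cluster_id := sprintf("CPA%06d", seq_len(.N))]
  data.table::setcolorder(sites, c("cluster_id", "contig", "strand",
                                   "rep_pos", "n_members", "total"))
  mem <- merge(mem, sites[, .(contig, strand, rep_pos, cluster_id)],
               by = c("contig", "strand", "rep_pos"))
  counts <- merge(universe,
                  mem[, .(contig, strand, pos, cluster_id)],
                  by = c("contig", "strand", "pos"))
  counts <- counts[, .(count = sum(count)), by = .(cluster_id, sample_id)]
  structure(list(sites = sites[],
                 members = mem[order(cluster_id, pos),
                               .(cluster_id, pos, count)],
                 counts = counts[order(cluster_id, sample_id)]),
            class = "cpa_clusters")
}

#' @export
print.cpa_clusters <- function(x, ...) {
  cat("cpa_clusters:", nrow(x$sites), "representative sites,",
      nrow(x$members), "member positions,",
      sum(x$sites$total), "reads\n")
  invisible(x)
}

#' Subset a cluster collection by cluster id
#'
#' @param clusters A `cpa_clusters` object.
#' @param keep_ids Cluster ids to retain.
#' @return A `cpa_clusters` object restricted to `keep_ids`.
#' @export
filter_clusters <- function(clusters, keep_ids) {
  structure(list(sites = clusters$sites[cluster_id %in% keep_ids],
                 members = clusters$members[cluster_id %in% keep_ids],
                 counts = clusters$counts[cluster_id %in% keep_ids]),
            class = "cpa_clusters")
}

#' Write representative CPA sites as BED6
#'
#' BED is 0-based half-open; each representative site becomes a 1-nt interval
#' ending at the CPA base. Name is the cluster id, score the total read
#' support.
#'
#' @param clusters A `cpa_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly. On a write failure any partial file is removed.
#' @export
write_cpa_bed <- function(clusters, path) {
  s <- clusters$sites
  ok <- FALSE
  on.exit(if (!ok && file.exists(path)) unlink(path))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE, after = FALSE)
  if (nrow(s))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       s$contig, s$rep_pos - 1L, s$rep_pos,
                       s$cluster_id, s$total, s$strand), con)
  ok <- TRUE
  invisible(path)
}

#' Read a BED6 file of representative CPA sites
#'
#' Inverse of [write_cpa_bed()]: converts the 0-based half-open 1-nt interval
#' back to the 1-based CPA coordinate.
#'
#' @param path BED6 file.
#' @return data.table with `contig`, `strand`, `pos`, `cluster_id`, `total`.
#' @export
read_cpa_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.table::data.table(contig = character(), strand = character(),
                                  pos = integer(), cluster_id = character(),
                                  total = integer()))
  b <- data.table::fread(path, header = FALSE,
                         col.names = c("contig", "bed_start", "bed_end",
                                       "cluster_id", "total", "strand"))
  if (any(b$bed_end - b$bed_start != 1L))
    stop("expected 1-nt CPA intervals in ", path)
  b[, .(contig, strand, pos = as.integer(bed_end), cluster_id, total)]
}
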