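#' Construct a gene-model collection
#'
#' Internal container used across the pipeline: one row per gene plus a merged
#' exon table. Coordinates are 1-based fully closed and strand-aware. Exons
#' are merged (non-overlapping) and sorted 5'->3' on the gene's strand. For
#' protein-coding genes the 3'-most stop-codon coordinate is the CDS boundary
#' nearest the gene's 3' end: the maximum CDS end on `+`, the minimum CDS
#' start on `-`.
#'
#' @param genes data.frame with columns `gene_id`, `biotype`
#'   (`protein_coding`/`ncRNA`/`other`), `contig`, `strand`, `stop_codon`
#'   (NA for non-coding).
#' @param exons data.frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end`.
#' @return Object of class `"gene_models"`: list with data.tables `genes` and
#'   `exons`.
#' @export
gene_models <- function(genes, exons) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  stopifnot(all(c("gene_id", "biotype", "contig", "strand", "stop_codon") %in%
                  names(genes)),
            all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(exons)))
  if (anyDuplicated(genes$gene_id))
    stop("gene ids must be unique")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon with unknown gene id: ",
         setdiff(exons$gene_id, genes$gene_id)[1])
  # merge overlapping/adjacent exons per gene
  exons <- exons[order(gene_id, start)]
  merged <- exons[, {
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    list(contig = contig[1], strand = strand[1],
         start = IRanges::start(ir), end = IRanges::end(ir))
  }, by = gene_id]
  coding <- genes[biotype == "protein_coding"]
  if (nrow(coding)) {
    if (anyNA(coding$stop_codon))
      stop("protein_coding gene without stop-codon coordinate")
    bad <- coding[!vapply(seq_len(nrow(coding)), function(i) {
      e <- merged[gene_id == coding$gene_id[i]]
      any(coding$stop_codon[i] >= e$start & coding$stop_codon[i] <= e$end)
    }, logical(1))]
    if (nrow(bad))
      stop("stop codon outside exons for gene ", bad$gene_id[1])
  }
  # 5'->3' order on the gene's strand
  merged <- merged[order(gene_id, start)]
  minus <- merged$strand == "-"
  merged <- rbind(merged[!minus], merged[minus][order(gene_id, -start)])
  structure(list(genes = genes[order(gene_id)], exons = merged),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons),
      "merged exons on", length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

resolve_gff_gene_ids <- function(gr) {
  m <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(m)) as.character(m$gene_id)
         else rep(NA_character_, length(gr))
  # GFF3: follow Parent -> ID chains up to the gene feature
  if ("ID" %in% names(m) && "Parent" %in% names(m)) {
    id2idx <- setNames(seq_along(gr), as.character(m$ID))
    parent_of <- vapply(seq_along(gr), function(i) {
      p <- m$Parent[[i]]
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
    resolve_one <- function(i) {
      cur <- i
      for (step in 1:10) {
        if (!is.na(ids[cur]) && nzchar(ids[cur])) return(ids[cur])
        ty <- as.character(m$type[cur])
        if (identical(ty, "gene")) return(as.character(m$ID[cur]))
        p <- parent_of[cur]
        if (is.na(p) || !p %in% names(id2idx)) {
          # top of chain: use its ID if any
          return(if (!is.na(m$ID[cur])) as.character(m$ID[cur])
                 else NA_character_)
        }
        cur <- id2idx[[p]]
      }
      NA_character_
    }
    need <- which(is.na(ids) | !nzchar(ids))
    ids[need] <- vapply(need, resolve_one, character(1))
  }
  ids
}

#' Read gene annotation (GFF3 or GTF)
#'
#' Parses exon and CDS features into a [gene_models()] collection. The gene
#' identifier of a feature is resolved in the order `gene_id` attribute, then
#' the feature's own `ID`, then the `Parent` chain up to the `gene` feature,
#' so both GTF and GFF3 dialects are accepted. Biotype is taken from a
#' `biotype`/`gene_biotype` attribute when present, otherwise inferred:
#' genes with CDS features are `protein_coding`, others `ncRNA`.
#'
#' @param path GFF3 or GTF file.
#' @return A `gene_models` object.
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  # light syntactic pre-scan so malformed lines are reported with line numbers
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", raw))
  nfields <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfields != 9L))
    stop("malformed annotation line ", body[which(nfields != 9L)[1]],
         " in ", path, " (expected 9 tab-separated fields)")
  gr <- rtracklayer::import(path, format = fmt)
  type <- as.character(S4Vectors::mcols(gr)$type)
  ids <- resolve_gff_gene_ids(gr)
  use <- type %in% c("exon", "CDS")
  if (!any(use)) stop("no exon or CDS features in ", path)
  if (anyNA(ids[use]))
    stop("feature without resolvable gene id (", type[which(use & is.na(ids))[1]],
         " feature #", which(use & is.na(ids))[1], ") in ", path)
  feat <- data.table::data.table(
    gene_id = ids[use],
    type = type[use],
    contig = as.character(GenomicRanges::seqnames(gr))[use],
    strand = as.character(GenomicRanges::strand(gr))[use],
    start = GenomicRanges::start(gr)[use],
    end = GenomicRanges::end(gr)[use])
  if (any(!feat$strand %in% c("+", "-")))
    stop("exon/CDS feature without strand in ", path)
  ex <- feat[type == "exon"]
  cds <- feat[type == "CDS"]
  if (nrow(cds) && !all(cds$gene_id %in% ex$gene_id))
    stop("CDS without parent gene exons: ",
         setdiff(cds$gene_id, ex$gene_id)[1])
  # biotype from attributes where present
  m <- S4Vectors::mcols(gr)
  bt_attr <- NULL
  for (nm in c("gene_biotype", "biotype")) {
    if (nm %in% names(m)) { bt_attr <- as.character(m[[nm]]); break }
  }
  gene_rows <- ex[, .(contig = contig[1], strand = strand[1]), by = gene_id]
  stop_tab <- cds[, .(stop_codon = if (strand[1] == "+") max(end)
                      else min(start)), by = gene_id]
  gene_rows <- merge(gene_rows, stop_tab, by = "gene_id", all.x = TRUE)
  gene_rows[, biotype := ifelse(is.na(stop_codon), "ncRNA", "protein_coding")]
  if (!is.null(bt_attr)) {
    known <- data.table::data.table(gene_id = ids, biotype_attr = bt_attr)
    known <- unique(known[!is.na(biotype_attr) & gene_id %in% gene_rows$gene_id])
    if (nrow(known)) {
      gene_rows <- merge(gene_rows, known, by = "gene_id", all.x = TRUE)
      gene_rows[!is.na(biotype_attr), biotype := biotype_attr]
      gene_rows[, biotype_attr := NULL]
    }
  }
  gene_models(gene_rows[, .(gene_id, biotype, contig, strand, stop_codon)],
              ex[, .(gene_id, contig, strand, start, end)])
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` (or `ncRNA`), `exon` and `CDS` features; the inverse
#' of [read_annotation()] for simulator-produced annotations.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @param cds A data.frame (`gene_id`, `start`, `end`) of CDS intervals; when
#'   `NULL`, a single CDS spanning from the gene's first exon to the stop
#'   codon is emitted for coding genes.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(models, path, cds = NULL) {
  stopifnot(inherits(models, "gene_models"))
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i]
    ex <- models$exons[gene_id == g$gene_id][order(start)]
    gstart <- min(ex$start); gend <- max(ex$end)
    ty <- if (g$biotype == "protein_coding") "mRNA" else "ncRNA"
    lines <- c(lines,
      sprintf("%s\tapascan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
              g$contig, gstart, gend, g$strand, g$gene_id, g$biotype),
      sprintf("%s\tapascan\t%s\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$contig, ty, gstart, gend, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tapascan\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              g$contig, ex$start, ex$end, g$strand, g$gene_id))
    if (g$biotype == "protein_coding") {
      ci <- if (!is.null(cds)) data.table::as.data.table(cds)[gene_id == g$gene_id]
            else data.table::data.table(
              start = if (g$strand == "+") gstart else g$stop_codon,
              end = if (g$strand == "+") g$stop_codon else gend)
      lines <- c(lines,
        sprintf("%s\tapascan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s.t1",
                g$contig, ci$start, ci$end, g$strand, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
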