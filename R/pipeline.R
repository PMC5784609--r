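#' Write a stage TSV with a one-line schema header
#'
#' Every intermediate table carries a `# apascan_tsv v1 <stage>` header line
#' so stages are independently runnable and schema mismatches are caught.
#'
#' @param dt data.table to write.
#' @param path Output path.
#' @param stage Stage name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(dt, path, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# apascan_tsv v1 ", stage), con)
  suppressWarnings(utils::write.table(dt, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_stage_tsv
#' @param expect_stage Stage name the caller requires; a mismatch is a
#'   versioned-format error.
#' @export
read_stage_tsv <- function(path, expect_stage = NULL) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# apascan_tsv v1 ", hdr))
    stop("not an apascan v1 stage TSV: ", path)
  stage <- sub("^# apascan_tsv v1 ", "", hdr)
  if (!is.null(expect_stage) && stage != expect_stage)
    stop("stage TSV mismatch in ", path, ": found '", stage,
         "', expected '", expect_stage, "'")
  data.table::fread(path, skip = 1L, header = TRUE, sep = "\t")
}

#' Validate a run manifest
#'
#' @param manifest data.frame with `sample_id`, `path`, `condition`.
#' @return The manifest as a data.table, or an error before any work starts.
#' @export
validate_manifest <- function(manifest) {
  m <- data.table::as.data.table(manifest)
  need <- c("sample_id", "path", "condition")
  if (!all(need %in% names(m)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample ids in manifest")
  missing <- m$path[!file.exists(m$path)]
  if (length(missing))
    stop("manifest input path(s) do not exist: ",
         paste(missing, collapse = ", "))
  m
}

read_sample_ends <- function(path, sample_id) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    extract_ends(read_alignments(path, sample_id))
  } else {
    e <- read_end_records(path)
    e[, sample_id := sample_id]
    e[]
  }
}

#' Run the full 3'-end analysis pipeline
#'
#' Stage order: end extraction -> multi-sample site universe -> greedy CPA
#' clustering -> mispriming filter -> gene assignment, 3'UTR classification
#' and PAS annotation -> count matrices and size-factor normalization ->
#' low-abundance isoform filter -> differential isoform-usage test (when the
#' manifest has two conditions) -> 3'UTR length and motif reports. Every
#' stage writes a schema-tagged TSV under `out_dir` and its row counts are
#' logged to `run_report.tsv`; a rerun with the same inputs, config and seed
#' is identical.
#'
#' @param manifest data.frame (`sample_id`, `path`, `condition`); paths are
#'   SAM/BAM alignments or BED-like end-record files.
#' @param genome `DNAStringSet` or FASTA path.
#' @param models [gene_models()] or GFF3/GTF path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param motifs Optional list of [motif_spec()] for the motif report.
#' @return Invisibly, a list with all stage results (`universe`, `clusters`,
#'   `filter`, `isoforms`, `usage`, `matrices`, `size_factors`,
#'   `filtered_usage`, `switch` or NULL, `utr_stats`, `report`).
#' @export
run_pipeline <- function(manifest, genome, models,
                         config = pipeline_config(), out_dir,
                         motifs = list(motif_spec("UUGUU", "UUGUU"))) {
  m <- validate_manifest(manifest)
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(models)) models <- read_annotation(models)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(config_log_lines(config), file.path(out_dir, "config.log"))
  report <- list()
  note <- function(stage, n) {
    report[[stage]] <<- n
    message("[", stage, "] ", n, " rows")
  }

  ends <- tally_positions(lapply(seq_len(nrow(m)), function(i)
    read_sample_ends(m$path[i], m$sample_id[i])))
  note("ends", nrow(ends))
  universe <- build_universe(ends, config$min_samples_support)
  note("universe", nrow(unique(universe[, .(contig, strand, pos)])))
  write_stage_tsv(universe, file.path(out_dir, "universe.tsv"), "universe")

  clusters <- cluster_sites(universe, config$cluster_window)
  note("clusters", nrow(clusters$sites))
  write_stage_tsv(clusters$sites, file.path(out_dir, "clusters.tsv"),
                  "clusters")
  write_stage_tsv(clusters$counts, file.path(out_dir, "cluster_counts.tsv"),
                  "cluster_counts")

  filt <- apply_mispriming_filter(clusters, genome, config)
  note("retained_sites", nrow(filt$final$sites))
  write_stage_tsv(filt$verdicts,
                  file.path(out_dir, "mispriming_verdicts.tsv"),
                  "mispriming_verdicts")
  write_cpa_bed(filt$final, file.path(out_dir, "cpa_sites.bed"))
  write_cpa_bed(filt$flagged, file.path(out_dir, "flagged_pas_positive.bed"))

  ann <- annotate_isoforms(filt$final, models, genome, config)
  note("isoforms", nrow(ann$isoforms))
  write_stage_tsv(ann$isoforms, file.path(out_dir, "isoforms.tsv"),
                  "isoforms")

  mats <- count_matrices(ann$usage)
  sf <- size_factors(mats$gene, pseudo_reference = TRUE)
  write_stage_tsv(data.table::data.table(sample_id = names(sf),
                                         size_factor = sf),
                  file.path(out_dir, "size_factors.tsv"), "size_factors")
  expr <- expression_table(mats$gene, sf, config$pseudocount)
  write_stage_tsv(data.table::data.table(gene_id = rownames(mats$gene),
                                         mats$gene),
                  file.path(out_dir, "gene_counts.tsv"), "gene_counts")
  write_stage_tsv(data.table::data.table(gene_id = rownames(expr$normalized),
                                         expr$normalized),
                  file.path(out_dir, "normalized_counts.tsv"),
                  "normalized_counts")

  fl <- filter_low_abundance_isoforms(ann$usage, config$min_isoform_fraction)
  note("retained_isoform_sample_pairs", nrow(fl$usage))
  write_stage_tsv(fl$usage, file.path(out_dir, "usage.tsv"), "usage")

  conditions <- setNames(m$condition, m$sample_id)
  switch_res <- NULL
  if (length(unique(m$condition)) == 2L) {
    pooled <- pool_condition_counts(fl$usage, conditions)
    switch_res <- test_switch(pooled, ann$isoforms, config$fdr_threshold,
                              config$min_test_reads)
    note("switch_tests", nrow(switch_res))
    write_stage_tsv(switch_res, file.path(out_dir, "switch_results.tsv"),
                    "switch_results")
    cat_res <- switch_catalog(switch_res, config$fdr_threshold)
    write_stage_tsv(cat_res$catalog, file.path(out_dir, "switch_catalog.tsv"),
                    "switch_catalog")
  } else {
    message("single condition in manifest: isoform switch test skipped")
    report[["switch_tests"]] <- NA_integer_
  }

  utr_stats <- utr_length_stats(fl$usage, ann$isoforms)
  write_stage_tsv(utr_stats, file.path(out_dir, "utr_lengths.tsv"),
                  "utr_lengths")
  motif_tab <- per_transcript_motif_table(
    ann$isoforms[apa_class == "tandem"], models, genome, motifs)
  note("motif_rows", nrow(motif_tab))
  write_stage_tsv(motif_tab, file.path(out_dir, "motif_counts.tsv"),
                  "motif_counts")

  rep_dt <- data.table::data.table(stage = names(report),
                                   rows = unlist(report))
  write_stage_tsv(rep_dt, file.path(out_dir, "run_report.tsv"), "run_report")
  invisible(list(universe = universe, clusters = clusters, filter = filt,
                 isoforms = ann$isoforms, usage = ann$usage,
                 matrices = mats, size_factors = sf, expression = expr,
                 filtered_usage = fl$usage, switch = switch_res,
                 utr_stats = utr_stats, motif_counts = motif_tab,
                 report = rep_dt))
}
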