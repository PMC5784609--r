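#' Default ranked polyadenylation-signal hexamers
#'
#' A ranked list of 15 PAS hexamers with the canonical `AAUAAA` first,
#' followed by common single-base variants observed in nematode and mammalian
#' 3'-end surveys. The precise composition and order of the non-canonical
#' variants is a package default, not a measured quantity; both are
#' configurable through [pipeline_config()].
#'
#' @return Character vector of 15 hexamers in RNA alphabet, ranked from
#'   strongest (canonical) to weakest.
#' @export
#' @examples
#' default_pas_motifs()[1] # canonical signal
default_pas_motifs <- function() {
  c("AAUAAA", "AUUAAA", "UAUAAA", "AAUACA", "AAUAUA",
    "AAUGAA", "GAUAAA", "AAUAGA", "CAUAAA", "AGUAAA",
    "ACUAAA", "AAUAAU", "UUUAAA", "AAGAAA", "AAUAAG")
}

#' Pipeline configuration
#'
#' Builds and validates the single configuration object consumed by every
#' stage. All numeric rules of the pipeline live here: the +/-12 nt clustering
#' window, the >=2-sample site universe rule, the 1500 nt upstream gene
#' assignment limit, the 5% low-abundance isoform filter, the 8--25 nt PAS
#' scan window, the mispriming A-rule, and the FDR threshold for differential
#' isoform usage.
#'
#' @param cluster_window Half-width in nt of the clustering window around the
#'   most-supported position (default 12).
#' @param min_samples_support Minimum number of libraries a position must be
#'   seen in to enter the site universe (default 2).
#' @param max_upstream_assign Maximum distance in nt from a CPA site to the
#'   nearest upstream same-strand exon end for gene assignment (default 1500).
#' @param min_isoform_fraction Minimum within-sample fraction of a gene's
#'   clustered reads an isoform must carry to be retained (default 0.05).
#' @param pas_window Closed interval, in nt upstream of the CPA base, within
#'   which the last base of a PAS hexamer must fall (default `c(8, 25)`).
#' @param pas_motifs Ranked PAS hexamers, canonical first
#'   (default [default_pas_motifs()]).
#' @param mispriming_downstream_window Number of genomic bases inspected from
#'   the CPA base downstream for the A-rule (default 5).
#' @param mispriming_min_A Minimum number of adenosines among those bases for
#'   the A-rule to fire; the first base must additionally be A (default 4).
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param min_read_len Minimum mate length in nt retained by the length
#'   filter (default 50; shorter mates are dropped).
#' @param barcode_len Sample barcode length at the start of Read 1 (default 6).
#' @param min_test_reads Minimum per-condition gene total required before the
#'   isoform switch test is attempted (default 20).
#' @param pseudocount Pseudocount used for log2 fold-changes (default 1).
#' @param rng_seed Integer seed used by every randomized operation.
#' @return A validated list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(rng_seed = 1)
#' cfg$cluster_window
pipeline_config <- function(cluster_window = 12L,
                            min_samples_support = 2L,
                            max_upstream_assign = 1500L,
                            min_isoform_fraction = 0.05,
                            pas_window = c(8L, 25L),
                            pas_motifs = default_pas_motifs(),
                            mispriming_downstream_window = 5L,
                            mispriming_min_A = 4L,
                            fdr_threshold = 0.05,
                            min_read_len = 50L,
                            barcode_len = 6L,
                            min_test_reads = 20L,
                            pseudocount = 1,
                            rng_seed = 1L) {
  cfg <- list(
    cluster_window = as.integer(cluster_window),
    min_samples_support = as.integer(min_samples_support),
    max_upstream_assign = as.integer(max_upstream_assign),
    min_isoform_fraction = as.numeric(min_isoform_fraction),
    pas_window = as.integer(pas_window),
    pas_motifs = toupper(as.character(pas_motifs)),
    mispriming_downstream_window = as.integer(mispriming_downstream_window),
    mispriming_min_A = as.integer(mispriming_min_A),
    fdr_threshold = as.numeric(fdr_threshold),
    min_read_len = as.integer(min_read_len),
    barcode_len = as.integer(barcode_len),
    min_test_reads = as.integer(min_test_reads),
    pseudocount = as.numeric(pseudocount),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos_int <- c("cluster_window", "min_samples_support", "max_upstream_assign",
               "mispriming_downstream_window", "mispriming_min_A",
               "min_read_len", "barcode_len", "min_test_reads")
  for (p in pos_int) {
    v <- cfg[[p]]
    if (length(v) != 1L || is.na(v) || v <= 0L)
      stop("config parameter '", p, "' must be a single strictly positive integer")
  }
  for (p in c("min_isoform_fraction", "fdr_threshold")) {
    v <- cfg[[p]]
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop("config parameter '", p, "' must lie in (0, 1)")
  }
  if (length(cfg$pas_window) != 2L || any(is.na(cfg$pas_window)) ||
      cfg$pas_window[1] < 1L || cfg$pas_window[2] < cfg$pas_window[1])
    stop("pas_window must be a closed interval [lo, hi] with lo >= 1")
  if (length(cfg$pas_motifs) < 1L ||
      !all(grepl("^[ACGU]{6}$", cfg$pas_motifs)))
    stop("pas_motifs must be RNA hexamers over {A,C,G,U}")
  if (anyDuplicated(cfg$pas_motifs))
    stop("pas_motifs must be unique")
  if (cfg$mispriming_min_A > cfg$mispriming_downstream_window)
    stop("mispriming_min_A cannot exceed mispriming_downstream_window")
  if (length(cfg$rng_seed) != 1L || is.na(cfg$rng_seed))
    stop("rng_seed must be a single integer")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("3'-end pipeline configuration:\n")
  for (line in config_log_lines(x)) cat(" ", line, "\n")
  invisible(x)
}

#' Echo every configuration parameter as log lines
#'
#' Used at run start so a run log records the exact numeric rules applied.
#'
#' @param cfg A [pipeline_config()] object.
#' @return Character vector, one `key = value` line per parameter.
#' @export
config_log_lines <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  vapply(names(cfg), function(n) {
    paste0(n, " = ", paste(cfg[[n]], collapse = ","))
  }, character(1))
}

#' Read a `key = value` configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored. Values
#' for `pas_window` and `pas_motifs` are comma separated. Unknown keys are an
#' error. Keys not present keep their [pipeline_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- pipeline_config()
  args <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (no '='): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    args[[key]] <- if (key == "pas_motifs") parts else
      if (key %in% c("min_isoform_fraction", "fdr_threshold", "pseudocount"))
        as.numeric(parts) else as.integer(parts)
  }
  do.call(pipeline_config, args)
}
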