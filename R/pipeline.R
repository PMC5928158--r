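# End-to-end orchestration: read -> linearize -> resolve -> threshold ->
# intra-normalize -> scaled-quantile -> pool -> differential map -> flags ->
# segments -> test -> deduplicate -> single-gene -> summaries, with a
# structured per-stage record-count log.

#' Run the integrated differential-map pipeline
#'
#' Takes raw expression samples from both pools, normalizes and integrates
#' them and produces the differential transcriptome map with segment calls.
#' The quantile reference is built jointly over both pools; per-locus
#' flagging and segment scoring use the log2 A/B ratio so the over- and
#' under-expression tails are symmetric.
#'
#' @param samples_a,samples_b lists of [expr_sample()] for pools A
#'   (trisomic) and B (euploid).
#' @param platforms named list of [platform()] objects (names =
#'   platform ids).
#' @param annotation a [genome_annotation()].
#' @param config a [map_config()].
#' @param n_quantile_points scaled-quantile grid resolution.
#' @param threshold_factor non-positive-value threshold factor.
#' @param run_segments run segment tagging/testing (and dedup).
#' @param run_single_gene run the 25 kb single-gene mode.
#' @return list: `comparison` (locus map), `pool_a`, `pool_b`, `flags`,
#'   `segments` (all tagged/tested windows), `called` (deduplicated calls),
#'   `single_gene`, `chromosome_summary`, `reference`, `log` (stage
#'   record-count table).
#' @export
run_pipeline <- function(samples_a, samples_b, platforms, annotation,
                         config = map_config(), n_quantile_points = 1001,
                         threshold_factor = 0.95, run_segments = TRUE,
                         run_single_gene = TRUE) {
  if (length(samples_a) == 0) stop_stage("input", "pool A manifest is empty")
  if (length(samples_b) == 0) stop_stage("input", "pool B manifest is empty")
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                          n_out = n_out,
                                          stringsAsFactors = FALSE)
  }
  prep <- function(samples, pool_name) {
    lapply(samples, function(s) {
      lin <- linearize(s)
      plat <- platforms[[lin$platform_id]]
      if (is.null(plat)) {
        stop_stage("resolve", sprintf("sample '%s': unknown platform '%s'",
                                      s$sample_id, s$platform_id))
      }
      rec <- resolve_probes(lin, plat, annotation)
      normalize_sample(rec, threshold_factor)
    })
  }
  norm_a <- prep(samples_a, "A")
  norm_b <- prep(samples_b, "B")
  n_probes <- sum(vapply(c(samples_a, samples_b),
                         function(s) length(s$values), integer(1)))
  n_records <- sum(vapply(c(norm_a, norm_b),
                          function(s) nrow(s$records), integer(1)))
  note("resolve_and_normalize", n_probes, n_records)

  ref <- build_quantile_reference(c(norm_a, norm_b), n_quantile_points)
  norm_a <- lapply(norm_a, scaled_quantile_normalize, ref = ref)
  norm_b <- lapply(norm_b, scaled_quantile_normalize, ref = ref)
  note("scaled_quantile", n_records, n_records)

  pool_a <- pool_loci(norm_a, config$min_samples_per_locus)
  pool_b <- pool_loci(norm_b, config$min_samples_per_locus)
  note("pool_loci", n_records, nrow(pool_a) + nrow(pool_b))

  comparison <- differential_map(pool_a, pool_b)
  note("differential_map", nrow(pool_a) + nrow(pool_b), nrow(comparison))

  values <- stats::setNames(log2(comparison$ratio), comparison$symbol)
  flags <- flag_extreme_loci(values, config$extreme_percentile)
  note("flag_extreme_loci", length(values), flags$K_over + flags$K_under)

  segments <- NULL
  called <- NULL
  if (run_segments) {
    segments <- build_segments(annotation, comparison$symbol, config,
                               drop_empty = FALSE)
    segments <- tag_and_test_segments(segments, flags, values, config)
    called <- deduplicate_segments(segments)
    note("segments", nrow(segments), nrow(called))
  }
  single_gene <- NULL
  if (run_single_gene) {
    single_gene <- single_gene_mode(values, annotation, config)
    note("single_gene_mode", length(values), nrow(single_gene))
  }
  chromosome_summary <- chromosome_mean_ratio(comparison, annotation)
  note("chromosome_summary", nrow(comparison), nrow(chromosome_summary))

  list(comparison = comparison, pool_a = pool_a, pool_b = pool_b,
       flags = flags, segments = segments, called = called,
       single_gene = single_gene, chromosome_summary = chromosome_summary,
       reference = ref, log = do.call(rbind, log))
}

#' Run the pipeline from a dataset directory
#'
#' Reads a `manifest.tsv` (columns `sample_id`, `file`, `platform_id`,
#' `condition`, `scale`), the per-platform `platform_<id>.tsv` annotations
#' and `annotation.tsv` from `dir` -- the layout written by
#' [write_synthetic_dataset()] -- and runs [run_pipeline()].
#'
#' @param dir dataset directory.
#' @param ... passed to [run_pipeline()].
#' @return A [run_pipeline()] result.
#' @export
run_pipeline_from_dir <- function(dir, ...) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  annotation <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  platform_ids <- unique(manifest$platform_id)
  platforms <- stats::setNames(lapply(platform_ids, function(pid) {
    read_platform_annotation(file.path(dir, paste0("platform_", pid, ".tsv")),
                             pid)
  }), platform_ids)
  read_one <- function(i) {
    read_expression_table(file.path(dir, manifest$file[i]),
                          scale = manifest$scale[i],
                          condition = manifest$condition[i],
                          platform_id = manifest$platform_id[i],
                          sample_id = manifest$sample_id[i])
  }
  idx_a <- which(manifest$condition == "A_trisomic")
  idx_b <- which(manifest$condition == "B_euploid")
  run_pipeline(lapply(idx_a, read_one), lapply(idx_b, read_one),
               platforms, annotation, ...)
}

#' Write a pipeline result bundle
#'
#' Writes the five standard outputs: per-locus map TSV, segment TSV, called
#' segments as BED5, per-chromosome summary TSV and the stage log, all with
#' deterministic formatting.
#'
#' @param result a [run_pipeline()] result.
#' @param annotation the [genome_annotation()] used for the run.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_map_bundle <- function(result, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(locus_map = file.path(dir, "locus_map.tsv"),
             segments = file.path(dir, "segments.tsv"),
             called_bed = file.path(dir, "called_segments.bed"),
             chromosomes = file.path(dir, "chromosome_summary.tsv"),
             log = file.path(dir, "run_log.tsv"))
  write_locus_map(result$comparison, annotation, paths[["locus_map"]])
  segs <- result$segments
  if (is.null(segs)) {
    segs <- data.frame(chromosome = character(0), start = numeric(0),
                       end = numeric(0), n_genes = integer(0))
  } else {
    segs <- segs[segs$n_genes > 0, , drop = FALSE]
    segs$loci <- vapply(segs$loci, paste, character(1), collapse = ",")
  }
  write_tsv(segs, paths[["segments"]])
  called <- result$called
  if (is.null(called)) {
    called <- data.frame(chromosome = character(0), start = numeric(0),
                         end = numeric(0), call = character(0),
                         q_over = numeric(0), q_under = numeric(0))
  }
  write_segment_bed(called, paths[["called_bed"]])
  write_tsv(result$chromosome_summary, paths[["chromosomes"]])
  write_tsv(result$log, paths[["log"]])
  invisible(paths)
}
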