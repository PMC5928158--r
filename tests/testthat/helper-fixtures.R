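# Shared fixtures: everything is built in code at test time.

tmp_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal annotation: loci evenly spaced on one or more chromosomes.
toy_annotation <- function(symbols, chromosome = "1", spacing = 50000,
                           width = 1000, chrom_len = NULL) {
  start <- seq_along(symbols) * spacing
  ann <- data.frame(symbol = symbols, chromosome = chromosome,
                    start = start, end = start + width - 1,
                    biotype = "known_gene", stringsAsFactors = FALSE)
  lens <- if (is.null(chrom_len)) NULL else
    stats::setNames(chrom_len, unique(chromosome))
  genome_annotation(ann, lens)
}

toy_platform <- function(probe_map, platform_id = "P") {
  platform(platform_id, probe_map, enforce_size = FALSE)
}

# A per-sample record set as produced by resolve_probes()/normalize_sample().
mock_records <- function(sample_id, symbols, values,
                         condition = "A_trisomic") {
  structure(list(sample_id = sample_id, platform_id = "P",
                 condition = condition, tissue = "",
                 records = data.frame(symbol = symbols, value = values,
                                      stringsAsFactors = FALSE),
                 dropped = c(missing = 0L, unmapped = 0L, unannotated = 0L)),
            class = c("normalized_sample", "locus_records"))
}

# Small synthetic configuration for fast pipeline-level tests.
small_synth_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         chromosomes = c("1", "2", "21"),
         genes_per_chromosome = c(150L, 120L, 60L),
         chromosome_lengths = c(7e7, 6e7, 2.5e7),
         samples_per_pool = 6L),
    list(...))
  do.call(synthetic_config, args)
}
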