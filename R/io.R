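# Reading and writing tabular inputs/outputs, probe-to-symbol resolution,
# linearization and platform inclusion rules.

PLATFORM_MIN_FEATURES <- 5000L
PLATFORM_MAX_FEATURES <- 60000L

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")
VALID_SCALES <- c("linear", "ln", "log2")
VALID_CONDITIONS <- c("A_trisomic", "B_euploid")
VALID_BIOTYPES <- c("known_gene", "est_cluster")

#' Construct a genome annotation
#'
#' A genome annotation holds the gene loci (official symbols or EST-cluster
#' identifiers) with 1-based inclusive genomic coordinates, plus per
#' chromosome lengths. Every downstream map is positioned on it.
#'
#' @param loci data.frame with columns `symbol`, `chromosome`, `start`,
#'   `end`, `biotype` (`"known_gene"` or `"est_cluster"`).
#' @param chromosome_lengths named numeric vector of chromosome lengths in
#'   bp. Defaults to the per-chromosome maximum `end` observed in `loci`.
#' @return A `genome_annotation`: the validated loci data.frame, sorted by
#'   chromosome and start, with the lengths stored in
#'   `attr(, "chromosome_lengths")`.
#' @export
genome_annotation <- function(loci, chromosome_lengths = NULL) {
  required <- c("symbol", "chromosome", "start", "end", "biotype")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  loci <- as.data.frame(loci)[required]
  loci$symbol <- as.character(loci$symbol)
  loci$chromosome <- as.character(loci$chromosome)
  loci$start <- as.numeric(loci$start)
  loci$end <- as.numeric(loci$end)
  loci$biotype <- as.character(loci$biotype)
  if (anyDuplicated(loci$symbol)) {
    stop("duplicate locus symbol(s): ",
         paste(unique(loci$symbol[duplicated(loci$symbol)]), collapse = ", "))
  }
  if (any(loci$start < 1)) stop("locus start coordinates must be >= 1")
  if (any(loci$start > loci$end)) stop("locus start must not exceed end")
  bad_bt <- setdiff(unique(loci$biotype), VALID_BIOTYPES)
  if (length(bad_bt) > 0) stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- tapply(loci$end, loci$chromosome, max)
    chromosome_lengths <- stats::setNames(as.numeric(chromosome_lengths),
                                          names(chromosome_lengths))
  }
  over <- loci$end > chromosome_lengths[loci$chromosome]
  if (any(is.na(over))) {
    stop("chromosome length missing for: ",
         paste(unique(loci$chromosome[is.na(over)]), collapse = ", "))
  }
  if (any(over)) {
    stop("locus extends beyond its chromosome length: ",
         paste(utils::head(loci$symbol[over], 5), collapse = ", "))
  }
  loci <- loci[order(loci$chromosome, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  structure(loci,
            chromosome_lengths = chromosome_lengths,
            class = c("genome_annotation", "data.frame"))
}

#' Read a gene annotation table
#'
#' Tab-delimited with header columns `symbol`, `chromosome`, `start`, `end`,
#' `biotype`; coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @inheritParams genome_annotation
#' @return A [genome_annotation()].
#' @export
read_gene_annotation <- function(path, chromosome_lengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_annotation(df, chromosome_lengths = chromosome_lengths)
}

#' Construct a platform description
#'
#' A platform maps probe identifiers to gene symbols. Platforms probing an
#' atypical number of features (fewer than 5,000 or more than 60,000) are
#' rejected at load: such arrays (boutique panels, tiling/exon designs) are
#' outside the integration's assumptions.
#'
#' @param platform_id platform label.
#' @param probe_map named character vector, probe id -> gene symbol; `NA`
#'   entries denote probes with no symbol assignment (control/filler probes),
#'   which are dropped with a logged count at resolution time.
#' @param feature_count number of features on the array; defaults to
#'   `length(probe_map)`.
#' @param enforce_size enforce the 5,000-60,000 feature inclusion rule
#'   (default `TRUE`; disable only for toy examples).
#' @return A `platform` object.
#' @export
platform <- function(platform_id, probe_map,
                     feature_count = length(probe_map),
                     enforce_size = TRUE) {
  if (is.null(names(probe_map)) || anyDuplicated(names(probe_map))) {
    stop("probe_map must be uniquely named by probe id")
  }
  feature_count <- as.integer(feature_count)
  if (enforce_size &&
      (feature_count < PLATFORM_MIN_FEATURES ||
       feature_count > PLATFORM_MAX_FEATURES)) {
    stop(sprintf(
      "platform '%s' rejected: %d features outside the accepted range [%d, %d]",
      platform_id, feature_count, PLATFORM_MIN_FEATURES, PLATFORM_MAX_FEATURES))
  }
  structure(list(platform_id = as.character(platform_id),
                 probe_map = probe_map,
                 feature_count = feature_count),
            class = "platform")
}

#' Read a platform annotation table
#'
#' Tab-delimited, columns `probe_id` and `gene_symbol` (blank symbol =
#' unassigned probe).
#'
#' @param path file path.
#' @param platform_id platform label.
#' @inheritParams platform
#' @return A [platform()].
#' @export
read_platform_annotation <- function(path, platform_id, enforce_size = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    stop("platform annotation must have columns probe_id, gene_symbol")
  }
  sym <- df$gene_symbol
  sym[!nzchar(sym) | is.na(sym)] <- NA_character_
  platform(platform_id, stats::setNames(sym, df$probe_id),
           enforce_size = enforce_size)
}

#' Construct an expression sample
#'
#' @param sample_id sample label.
#' @param platform_id platform the sample was measured on.
#' @param condition `"A_trisomic"` or `"B_euploid"`.
#' @param values named numeric vector, probe id -> intensity.
#' @param scale declared scale of `values`: `"linear"`, `"ln"` or `"log2"`.
#' @param tissue free-text tissue/cell-type label.
#' @param gender `"M"`, `"F"` or `"unknown"`.
#' @param n_missing count of probes whose value was absent in the source
#'   table (omitted, not imputed).
#' @return An `expr_sample` object.
#' @export
expr_sample <- function(sample_id, platform_id, condition, values,
                        scale = "linear", tissue = "", gender = "unknown",
                        n_missing = 0L) {
  condition <- match.arg(condition, VALID_CONDITIONS)
  scale <- match.arg(scale, VALID_SCALES)
  gender <- match.arg(gender, c("M", "F", "unknown"))
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("sample values must be uniquely named by probe id")
  }
  structure(list(sample_id = as.character(sample_id),
                 platform_id = as.character(platform_id),
                 condition = condition,
                 tissue = as.character(tissue),
                 gender = gender,
                 scale = scale,
                 values = values,
                 n_missing = as.integer(n_missing)),
            class = "expr_sample")
}

#' Read a two-column expression table
#'
#' Tab-delimited `probe_id <TAB> value`. A header row is auto-detected (a
#' first line whose second field is non-numeric). Probes with a missing or
#' blank value are omitted with a logged count: an absent value means the
#' probe was not measured, not that expression is zero. Malformed lines and
#' duplicate probe ids are errors.
#'
#' @param path file path.
#' @param scale declared scale of the stored values.
#' @param condition pool membership, `"A_trisomic"` or `"B_euploid"`.
#' @param platform_id platform label.
#' @param sample_id sample label; defaults to the file name without
#'   extension.
#' @param tissue,gender sample metadata.
#' @return An [expr_sample()] with the declared scale and the omission count
#'   in `$n_missing`.
#' @export
read_expression_table <- function(path, scale, condition, platform_id,
                                  sample_id = NULL, tissue = "",
                                  gender = "unknown") {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  start_at <- 1L
  if (length(lines) > 0) {
    first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 2 && nzchar(first[2]) &&
        is.na(suppressWarnings(as.numeric(first[2])))) {
      start_at <- 2L  # header row
    }
  }
  body <- lines[seq(from = start_at, length.out = length(lines) - start_at + 1L)]
  lineno <- seq_along(body) + start_at - 1L
  has_tab <- grepl("\t", body, fixed = TRUE)
  f1 <- sub("\t.*$", "", body)
  f2 <- ifelse(has_tab, sub("^[^\t]*\t", "", body), "")
  bad <- !has_tab | grepl("\t", f2, fixed = TRUE) | !nzchar(f1)
  if (any(bad)) {
    stop(sprintf("malformed line %d in '%s': expected 'probe<TAB>value'",
                 lineno[which(bad)[1]], path))
  }
  raw <- trimws(f2)
  missing <- !nzchar(raw) | toupper(raw) %in% c("NA", "NULL")
  v <- suppressWarnings(as.numeric(raw))
  nonnum <- !missing & is.na(v)
  if (any(nonnum)) {
    i <- which(nonnum)[1]
    stop(sprintf("malformed line %d in '%s': non-numeric value '%s'",
                 lineno[i], path, raw[i]))
  }
  probes <- f1[!missing]
  vals <- v[!missing]
  n_missing <- sum(missing)
  if (anyDuplicated(probes)) {
    stop(sprintf("duplicate probe id(s) in '%s': %s", path,
                 paste(unique(probes[duplicated(probes)]), collapse = ", ")))
  }
  expr_sample(sample_id, platform_id, condition,
              stats::setNames(vals, probes), scale = scale,
              tissue = tissue, gender = gender, n_missing = n_missing)
}

#' Linearize a log-scaled sample
#'
#' Expression tables may store linear intensities, natural-log or binary-log
#' values; all downstream arithmetic assumes linear scale. `ln` values are
#' exponentiated, `log2` values raised to powers of two, linear values are
#' returned unchanged.
#'
#' @param sample an [expr_sample()].
#' @return The sample with `scale = "linear"`.
#' @export
linearize <- function(sample) {
  stopifnot(inherits(sample, "expr_sample"))
  sample$values <- linearize_values(sample$values, sample$scale)
  sample$scale <- "linear"
  sample
}

#' @rdname linearize
#' @param values numeric vector.
#' @param scale `"linear"`, `"ln"` or `"log2"`.
#' @export
linearize_values <- function(values, scale) {
  scale <- match.arg(scale, VALID_SCALES)
  switch(scale,
         linear = values,
         ln = exp(values),
         log2 = 2^values)
}

#' Resolve probes to gene loci
#'
#' Converts a linearized sample's probe-level values into (gene symbol,
#' value) records via the platform's probe map, keeping one record per probe
#' (multiple probes per symbol are collapsed later, at pooling). Probes with
#' no symbol assignment, and probes whose symbol is absent from the genome
#' annotation, are dropped with separate logged counts, so that
#' `records + unmapped + unannotated + missing = feature_count`.
#'
#' @param sample a linearized [expr_sample()].
#' @param plat the sample's [platform()].
#' @param annotation a [genome_annotation()].
#' @return A `locus_records` object: sample metadata plus `$records`
#'   (data.frame `symbol`, `value`) and `$dropped` (named counts `missing`,
#'   `unmapped`, `unannotated`).
#' @export
resolve_probes <- function(sample, plat, annotation) {
  stopifnot(inherits(sample, "expr_sample"), inherits(plat, "platform"),
            inherits(annotation, "genome_annotation"))
  if (!identical(sample$platform_id, plat$platform_id)) {
    stop(sprintf("sample '%s' declares platform '%s' but platform '%s' given",
                 sample$sample_id, sample$platform_id, plat$platform_id))
  }
  if (sample$scale != "linear") {
    stop("sample must be linearized before probe resolution; see linearize()")
  }
  unknown <- setdiff(names(sample$values), names(plat$probe_map))
  if (length(unknown) > 0) {
    stop(sprintf("sample '%s' contains probe(s) absent from platform '%s': %s",
                 sample$sample_id, plat$platform_id,
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  symbols <- plat$probe_map[names(sample$values)]
  unmapped <- is.na(symbols)
  annotated <- symbols %in% annotation$symbol
  keep <- !unmapped & annotated
  structure(list(sample_id = sample$sample_id,
                 platform_id = sample$platform_id,
                 condition = sample$condition,
                 tissue = sample$tissue,
                 records = data.frame(symbol = unname(symbols[keep]),
                                      value = unname(sample$values[keep]),
                                      stringsAsFactors = FALSE),
                 dropped = c(missing = sample$n_missing,
                             unmapped = sum(unmapped),
                             unannotated = sum(!unmapped & !annotated))),
            class = "locus_records")
}

#' Write called segments as BED5
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the exported start is `start - 1` and the end is unchanged. The name
#' column carries the call direction and the score column is `-log10(q)`.
#'
#' @param segments segment data.frame (see [tag_and_test_segments()]),
#'   usually the called subset.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(segments) > 0) {
    q <- ifelse(segments$call == "over", segments$q_over, segments$q_under)
    score <- ifelse(is.na(q), 0, -log10(pmax(q, 1e-300)))
    lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                     segments$chromosome,
                     as.integer(segments$start) - 1L,
                     as.integer(segments$end),
                     segments$call,
                     sprintf("%.6g", score))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a per-locus comparison map as TSV
#'
#' Mirrors the supplementary-table shape of published transcriptome maps:
#' symbol, position, per-pool consensus means and sample counts, A/B ratio,
#' dosage band and ratio percentile.
#'
#' @param comparison output of [differential_map()].
#' @param annotation a [genome_annotation()] supplying coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_locus_map <- function(comparison, annotation, path) {
  ann <- as.data.frame(annotation)
  m <- merge(comparison, ann[, c("symbol", "chromosome", "start", "end")],
             by = "symbol", all.x = TRUE, sort = FALSE)
  m <- m[order(m$chromosome, m$start), c("symbol", "chromosome", "start",
                                         "end", "meanA", "nA_samples",
                                         "meanB", "nB_samples", "ratio",
                                         "band", "percentile")]
  write_tsv(m, path)
  invisible(path)
}

# Deterministic TSV writer (fixed numeric formatting, no quoting).
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- sprintf("%.10g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
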