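# Per-locus pooling of normalized samples, A/B differential maps, dosage
# band classification and gene-list export.

#' Dosage-model constants
#'
#' The simplest gene-dosage model for a trisomy predicts a 3:2 (1.5)
#' trisomic/euploid expression ratio for triplicated genes, and 2:3 (0.67)
#' for genes inhibited downstream. To absorb natural expression variability
#' the working bands are widened to >= 1.30 (over), 0.77-1.29 (neutral,
#' "close to 1") and <= 0.76 (under).
#'
#' @format Named numeric vector with elements `expected_over` (1.5),
#'   `expected_under` (0.67), `band_over` (1.30), `band_under` (0.76).
#' @export
dosage_model <- c(expected_over = 1.5, expected_under = 0.67,
                  band_over = 1.30, band_under = 0.76)

#' Classify A/B ratios into dosage bands
#'
#' Band boundaries are defined at two decimal places (the precision at which
#' the bands 1.29 vs 1.30 are adjacent), so the ratio is rounded half-up to
#' 2 d.p. before comparison: 1.295 classifies as over.
#'
#' @param ratio positive numeric vector of A/B expression ratios.
#' @return Character vector: `"over"` (>= 1.30), `"neutral"` (0.77-1.29) or
#'   `"under"` (<= 0.76).
#' @export
classify_dosage_band <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("ratios must be positive and finite")
  }
  r2 <- round_half_up(ratio, 2)
  ifelse(r2 >= dosage_model[["band_over"]], "over",
         ifelse(r2 <= dosage_model[["band_under"]], "under", "neutral"))
}

#' Pool normalized samples into per-locus consensus values
#'
#' The consensus value of a locus in one pool is the plain arithmetic mean
#' of all (probe, sample) records available for it -- records are weighted
#' equally, not samples, so a sample contributing three probes for a gene
#' contributes three records. Loci measured in fewer than `min_samples`
#' distinct biological samples are excluded from the map (too few samples
#' for a trustworthy consensus). Each retained locus gets the percentile of
#' its mean within the map (mean rank for ties).
#'
#' @param samples list of `normalized_sample` objects from one pool.
#' @param min_samples minimum distinct biological samples per locus
#'   (default 3).
#' @return data.frame (`locus_summary`) with columns `symbol`,
#'   `mean_value`, `n_values`, `n_samples`, `percentile`; excluded loci are
#'   recorded in `attr(, "excluded")`.
#' @export
pool_loci <- function(samples, min_samples = 3) {
  if (length(samples) == 0) stop("no samples to pool")
  if (min_samples < 1) stop("min_samples must be >= 1")
  sym <- unlist(lapply(samples, function(s) s$records$symbol),
                use.names = FALSE)
  val <- unlist(lapply(samples, function(s) s$records$value),
                use.names = FALSE)
  sid <- rep(vapply(samples, function(s) s$sample_id, character(1)),
             vapply(samples, function(s) nrow(s$records), integer(1)))
  if (length(sym) == 0) stop("no records to pool")
  f <- factor(sym)
  sums <- rowsum(val, f)
  n_values <- as.integer(table(f))
  pair_first <- !duplicated(paste(sid, sym, sep = "\r"))
  n_samples <- as.integer(table(factor(sym[pair_first], levels = levels(f))))
  out <- data.frame(symbol = levels(f),
                    mean_value = as.numeric(sums) / n_values,
                    n_values = n_values,
                    n_samples = n_samples,
                    stringsAsFactors = FALSE)
  keep <- out$n_samples >= min_samples
  excluded <- out[!keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    out$percentile <- 100 * rank(out$mean_value, ties.method = "average") /
      nrow(out)
  } else {
    out$percentile <- numeric(0)
  }
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("locus_summary", "data.frame"))
}

#' Differential A/B comparison map
#'
#' Compares two pooled maps locus-wise: only loci with a consensus value in
#' both pools are comparable. The per-locus ratio is `meanA / meanB`, banded
#' by [classify_dosage_band()]; `percentile` ranks each locus's ratio within
#' the comparison map.
#'
#' @param poolA,poolB [pool_loci()] results for the trisomic (A) and euploid
#'   (B) pools.
#' @return data.frame (`locus_comparison`) with columns `symbol`, `meanA`,
#'   `nA_values`, `nA_samples`, `meanB`, `nB_values`, `nB_samples`, `ratio`,
#'   `band`, `percentile`.
#' @export
differential_map <- function(poolA, poolB) {
  m <- merge(as.data.frame(poolA)[c("symbol", "mean_value", "n_values",
                                    "n_samples")],
             as.data.frame(poolB)[c("symbol", "mean_value", "n_values",
                                    "n_samples")],
             by = "symbol", suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no loci shared between the two pools")
  out <- data.frame(symbol = m$symbol,
                    meanA = m$mean_value_a,
                    nA_values = m$n_values_a,
                    nA_samples = m$n_samples_a,
                    meanB = m$mean_value_b,
                    nB_values = m$n_values_b,
                    nB_samples = m$n_samples_b,
                    stringsAsFactors = FALSE)
  out$ratio <- out$meanA / out$meanB
  out$band <- classify_dosage_band(out$ratio)
  out$percentile <- 100 * rank(out$ratio, ties.method = "average") / nrow(out)
  rownames(out) <- NULL
  structure(out, class = c("locus_comparison", "data.frame"))
}

#' Export over-/under-expressed gene lists
#'
#' Collects the symbols in the `over` and `under` dosage bands, optionally
#' excluding EST clusters (uncharacterized loci are kept in the maps but are
#' not useful inputs for functional-enrichment services). Lists are
#' optionally written one symbol per line.
#'
#' @param comparison a [differential_map()] result.
#' @param annotation a [genome_annotation()] (required when
#'   `exclude_est = TRUE`, to identify EST clusters).
#' @param exclude_est drop `est_cluster` loci (default `TRUE`).
#' @param dir if non-`NULL`, write `over_expressed.txt` and
#'   `under_expressed.txt` into this directory.
#' @return `list(over = , under = )` of symbol vectors.
#' @export
export_band_gene_lists <- function(comparison, annotation = NULL,
                                   exclude_est = TRUE, dir = NULL) {
  over <- comparison$symbol[comparison$band == "over"]
  under <- comparison$symbol[comparison$band == "under"]
  if (exclude_est) {
    if (is.null(annotation)) {
      stop("annotation required to exclude EST clusters")
    }
    est <- annotation$symbol[annotation$biotype == "est_cluster"]
    over <- setdiff(over, est)
    under <- setdiff(under, est)
  }
  res <- list(over = over, under = under)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(over, file.path(dir, "over_expressed.txt"))
    writeLines(under, file.path(dir, "under_expressed.txt"))
  }
  res
}

#' Per-chromosome mean expression ratio
#'
#' For each chromosome, the ratio of the pool means over all its comparable
#' loci: `mean(meanA) / mean(meanB)`. In a trisomy this summary is expected
#' to rank the trisomic chromosome first, since its genes are selectively
#' over-expressed while other chromosomes stay near 1.
#'
#' @param comparison a [differential_map()] result.
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `chromosome`, `n_loci`, `meanA`, `meanB`,
#'   `ratio`, `rank` (1 = highest ratio), ordered by rank. Chromosomes with
#'   no comparable loci are omitted.
#' @export
chromosome_mean_ratio <- function(comparison, annotation) {
  if (nrow(comparison) == 0) stop("empty comparison map")
  chr <- annotation$chromosome[match(comparison$symbol, annotation$symbol)]
  if (anyNA(chr)) {
    stop("comparison contains loci absent from the annotation")
  }
  f <- factor(chr)
  ma <- tapply(comparison$meanA, f, mean)
  mb <- tapply(comparison$meanB, f, mean)
  out <- data.frame(chromosome = levels(f),
                    n_loci = as.integer(table(f)),
                    meanA = as.numeric(ma),
                    meanB = as.numeric(mb),
                    stringsAsFactors = FALSE)
  out$ratio <- out$meanA / out$meanB
  out$rank <- rank(-out$ratio, ties.method = "min")
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
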