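# Sliding-window "Map" mode: tile fixed-width windows along each
# chromosome, flag extreme loci, tag candidate over-/under-expressed
# segments, test them against the hypergeometric null of random
# colocalization, FDR-correct, deduplicate overlapping calls, and the 25 kb
# single-gene mode.

#' Map-mode configuration
#'
#' Defaults follow the established transcriptome-mapping parameters: 500 kb
#' windows shifted by 250 kb (each locus falls in two windows), extreme loci
#' and extreme segments both defined by the 2.5th/97.5th percentiles, at
#' least 3 extreme genes per candidate segment, FDR threshold q < 0.05, and
#' a 25 kb / minimum-1-gene single-gene mode.
#'
#' @param window_size window width in bp.
#' @param shift window offset in bp (must not exceed `window_size`).
#' @param extreme_percentile tail percentile (percent) defining extreme loci
#'   and extreme segment values.
#' @param min_extreme_genes minimum flagged genes for a candidate segment.
#' @param q_threshold FDR threshold for a call.
#' @param single_gene_window window width for single-gene mode, bp.
#' @param single_gene_min minimum flagged genes in single-gene mode.
#' @param min_samples_per_locus minimum biological samples per retained
#'   locus (applied at pooling).
#' @return A validated `map_config` list.
#' @export
map_config <- function(window_size = 500000, shift = 250000,
                       extreme_percentile = 2.5, min_extreme_genes = 3,
                       q_threshold = 0.05, single_gene_window = 25000,
                       single_gene_min = 1, min_samples_per_locus = 3) {
  if (shift > window_size) stop("shift must not exceed window_size")
  if (shift < 1) stop("shift must be positive")
  if (extreme_percentile <= 0 || extreme_percentile >= 50) {
    stop("extreme_percentile must lie in (0, 50)")
  }
  if (q_threshold <= 0 || q_threshold >= 1) {
    stop("q_threshold must lie in (0, 1)")
  }
  if (min_extreme_genes < 1 || single_gene_min < 1) {
    stop("minimum extreme-gene counts must be >= 1")
  }
  structure(list(window_size = window_size, shift = shift,
                 extreme_percentile = extreme_percentile,
                 min_extreme_genes = as.integer(min_extreme_genes),
                 q_threshold = q_threshold,
                 single_gene_window = single_gene_window,
                 single_gene_min = as.integer(single_gene_min),
                 min_samples_per_locus = as.integer(min_samples_per_locus)),
            class = "map_config")
}

#' Tile genomic windows and assign loci
#'
#' Windows start at 1, 1 + shift, 1 + 2 shift, ... on every chromosome and
#' span `window_size` bp (clipped at the chromosome end). A locus belongs to
#' a window iff its start coordinate lies inside the window; membership by
#' gene start (not full span) counts each locus the same number of times
#' regardless of gene length -- with default parameters, exactly twice
#' except near chromosome ends.
#'
#' @param annotation a [genome_annotation()].
#' @param loci character vector of retained locus symbols (or a data.frame
#'   with a `symbol` column).
#' @param config a [map_config()].
#' @param drop_empty drop windows containing no loci (they can never be
#'   tagged; default `FALSE` keeps the full tiling).
#' @return data.frame with columns `chromosome`, `start`, `end`, `n_genes`
#'   and list-column `loci` (member symbols).
#' @export
build_segments <- function(annotation, loci, config = map_config(),
                           drop_empty = FALSE) {
  if (is.data.frame(loci)) loci <- loci$symbol
  w <- config$window_size
  s <- config$shift
  lens <- attr(annotation, "chromosome_lengths")
  ann <- as.data.frame(annotation)
  ann <- ann[ann$symbol %in% loci, , drop = FALSE]
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    chr <- names(lens)[ci]
    L <- lens[[ci]]
    n_win <- floor((L - 1) / s) + 1
    gs <- ann$start[ann$chromosome == chr]
    gsym <- ann$symbol[ann$chromosome == chr]
    # window index i (0-based) covers [1 + i*s, i*s + w]; gene start g is
    # inside iff ceil((g - w)/s) <= i <= floor((g - 1)/s)
    members <- rep(list(character(0)), n_win)
    if (length(gs) > 0) {
      hi <- floor((gs - 1) / s)
      lo <- pmax(0, ceiling((gs - w) / s))
      reps <- hi - lo + 1
      widx <- unlist(mapply(seq.int, lo, hi, SIMPLIFY = FALSE)) + 1
      msym <- rep(gsym, reps)
      got <- split(msym, widx)
      members[as.integer(names(got))] <- got
    }
    starts <- 1 + (seq_len(n_win) - 1) * s
    df <- data.frame(chromosome = chr, start = starts,
                     end = pmin(starts + w - 1, L),
                     stringsAsFactors = FALSE)
    df$n_genes <- lengths(members)
    df$loci <- I(members)
    if (drop_empty) df <- df[df$n_genes > 0, , drop = FALSE]
    out[[ci]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Inclusive extreme-tail membership with a tie rule: the tie group sitting
# exactly at the percentile threshold joins only if that keeps the tail at
# or below its nominal size; otherwise the whole group is excluded. A
# constant map therefore flags nothing.
tail_members <- function(values, threshold, cap, upper) {
  strict <- if (upper) values > threshold else values < threshold
  at <- values == threshold
  if (any(at) && sum(strict) + sum(at) <= cap) strict <- strict | at
  names(values)[strict]
}

#' Flag loci in the extreme expression tails
#'
#' Flags loci whose value lies at or beyond the `(100 - p)`th / `p`th
#' percentile of the map's per-locus values (linear-interpolation
#' percentiles). In differential maps the per-locus value is the log A/B
#' ratio, so the two tails are symmetric around no-change.
#'
#' @param values named numeric vector, locus symbol -> value.
#' @param extreme_percentile tail size in percent (default 2.5).
#' @return A `flag_set`: `$over_set`, `$under_set` (symbol vectors), `$N`
#'   (total loci), `$K_over`, `$K_under` (tail sizes), and the thresholds.
#' @export
flag_extreme_loci <- function(values, extreme_percentile = 2.5) {
  if (is.null(names(values))) stop("values must be named by locus symbol")
  N <- length(values)
  p <- extreme_percentile / 100
  hi <- stats::quantile(values, 1 - p, type = 7, names = FALSE)
  lo <- stats::quantile(values, p, type = 7, names = FALSE)
  cap <- ceiling(N * p)
  over <- tail_members(values, hi, cap, upper = TRUE)
  under <- tail_members(values, lo, cap, upper = FALSE)
  clash <- intersect(over, under)  # degenerate tiny/constant maps only
  over <- setdiff(over, clash)
  under <- setdiff(under, clash)
  structure(list(over_set = over, under_set = under, N = N,
                 K_over = length(over), K_under = length(under),
                 threshold_over = hi, threshold_under = lo),
            class = "flag_set")
}

#' Hypergeometric colocalization p-value
#'
#' Probability that at least `k` of a segment's `n` genes are flagged when
#' `K` of the `N` genes genome-wide are flagged and gene placement is
#' random: the upper tail P(X >= k) for X ~ Hypergeometric(N, K, n).
#'
#' @param k flagged genes in the segment.
#' @param n genes in the segment.
#' @param K flagged genes genome-wide.
#' @param N genes genome-wide.
#' @return Upper-tail probability in (0, 1]. Vectorized over `k`, `n`.
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  if (any(K > N) || any(n > N)) stop("require n <= N and K <= N")
  if (any(k < 0) || any(k > pmin(n, K))) {
    stop("require 0 <= k <= min(n, K)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Tag candidate segments and test their significance
#'
#' A segment's value is the mean of its member loci's values. It is tagged
#' as a candidate in one direction if (a) it contains at least
#' `min_extreme_genes` loci flagged in that direction and (b) its own value
#' lies in the corresponding extreme tail of all non-empty segments' values.
#' Candidates are then tested: hypergeometric p for the flagged-gene count,
#' Benjamini-Hochberg correction across the candidates of each direction,
#' and a call where q falls below `q_threshold`. Tagging precedes testing:
#' only segments that look extreme by descriptive statistics are submitted
#' to the significance test.
#'
#' @param segments a [build_segments()] result.
#' @param flags a [flag_extreme_loci()] result over the same locus values.
#' @param values the named per-locus values used for flagging.
#' @param config a [map_config()].
#' @return `segments` with added columns `segment_value`, `k_over`,
#'   `k_under`, `p_over`, `p_under`, `q_over`, `q_under`, `call`
#'   (`"over"`/`"under"`/`"none"`).
#' @export
tag_and_test_segments <- function(segments, flags, values,
                                  config = map_config()) {
  stopifnot(inherits(flags, "flag_set"))
  p <- config$extreme_percentile / 100
  segments$segment_value <- vapply(segments$loci, function(g) {
    if (length(g) == 0) NA_real_ else mean(values[g])
  }, numeric(1))
  over_set <- flags$over_set
  under_set <- flags$under_set
  segments$k_over <- vapply(segments$loci,
                            function(g) sum(g %in% over_set), integer(1))
  segments$k_under <- vapply(segments$loci,
                             function(g) sum(g %in% under_set), integer(1))
  nonempty <- !is.na(segments$segment_value)
  sv <- segments$segment_value[nonempty]
  hi <- stats::quantile(sv, 1 - p, type = 7, names = FALSE)
  lo <- stats::quantile(sv, p, type = 7, names = FALSE)
  cand_over <- nonempty & segments$k_over >= config$min_extreme_genes &
    segments$segment_value >= hi
  cand_under <- nonempty & segments$k_under >= config$min_extreme_genes &
    segments$segment_value <= lo
  segments$p_over <- NA_real_
  segments$p_under <- NA_real_
  segments$q_over <- NA_real_
  segments$q_under <- NA_real_
  if (any(cand_over)) {
    segments$p_over[cand_over] <- hypergeometric_pvalue(
      segments$k_over[cand_over], segments$n_genes[cand_over],
      flags$K_over, flags$N)
    segments$q_over[cand_over] <- stats::p.adjust(
      segments$p_over[cand_over], method = "BH")
  }
  if (any(cand_under)) {
    segments$p_under[cand_under] <- hypergeometric_pvalue(
      segments$k_under[cand_under], segments$n_genes[cand_under],
      flags$K_under, flags$N)
    segments$q_under[cand_under] <- stats::p.adjust(
      segments$p_under[cand_under], method = "BH")
  }
  call_over <- !is.na(segments$q_over) & segments$q_over < config$q_threshold
  call_under <- !is.na(segments$q_under) &
    segments$q_under < config$q_threshold
  segments$call <- ifelse(call_over, "over",
                          ifelse(call_under, "under", "none"))
  segments
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Deduplicate overlapping same-direction calls
#'
#' Adjacent windows covering one expression hotspot are called together;
#' chains of consecutive same-direction called segments whose gene sets
#' overlap by Jaccard > 0.5 are collapsed to the single most extreme segment
#' (largest value for over, smallest for under; ties broken by smaller q,
#' then leftmost start).
#'
#' @param segments a tagged/tested segment data.frame (only rows with
#'   `call != "none"` are considered).
#' @return The deduplicated called segments, sorted by chromosome and start.
#' @export
deduplicate_segments <- function(segments) {
  called <- segments[segments$call != "none", , drop = FALSE]
  if (nrow(called) == 0) return(called)
  called <- called[order(called$chromosome, called$start), , drop = FALSE]
  keep_rows <- logical(0)
  pick <- function(block) {
    dir <- block$call[1]
    val <- block$segment_value
    q <- if (dir == "over") block$q_over else block$q_under
    score <- if (dir == "over") val else -val
    best <- order(-score, q, block$start)[1]
    block[best, , drop = FALSE]
  }
  out <- list()
  for (dir in unique(called$call)) {
    sub <- called[called$call == dir, , drop = FALSE]
    for (chr in unique(sub$chromosome)) {
      blk <- sub[sub$chromosome == chr, , drop = FALSE]
      chain_id <- integer(nrow(blk))
      cid <- 1L
      chain_id[1] <- cid
      if (nrow(blk) > 1) {
        for (i in 2:nrow(blk)) {
          if (jaccard(blk$loci[[i - 1]], blk$loci[[i]]) <= 0.5) cid <- cid + 1L
          chain_id[i] <- cid
        }
      }
      for (g in split(seq_len(nrow(blk)), chain_id)) {
        out[[length(out) + 1]] <- pick(blk[g, , drop = FALSE])
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Single-gene significance mode
#'
#' Re-runs the map machinery with a 25 kb window (shift = half window) and a
#' minimum of one flagged gene per window. Because 25 kb is well below the
#' mean human protein-coding gene length, a called window almost always
#' contains a single gene, whose significance it reports. When a window
#' holds several genes, the call is attributed to its flagged gene only if
#' that gene's |value| strictly prevails over every other member's.
#'
#' @param values named per-locus values (log ratios for differential maps).
#' @param annotation a [genome_annotation()].
#' @param config a [map_config()]; `single_gene_window` and
#'   `single_gene_min` override the map-mode window and gene minimum.
#' @return data.frame of attributed genes: `symbol`, `chromosome`,
#'   `direction`, `q`, `window_start`, `window_end` (best window per gene).
#' @export
single_gene_mode <- function(values, annotation, config = map_config()) {
  cfg <- config
  cfg$window_size <- config$single_gene_window
  cfg$shift <- max(1, floor(config$single_gene_window / 2))
  cfg$min_extreme_genes <- config$single_gene_min
  flags <- flag_extreme_loci(values, cfg$extreme_percentile)
  segs <- build_segments(annotation, names(values), cfg, drop_empty = TRUE)
  segs <- tag_and_test_segments(segs, flags, values, cfg)
  called <- segs[segs$call != "none", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(called))) {
    g <- called$loci[[i]]
    dir <- called$call[i]
    flagged <- intersect(g, if (dir == "over") flags$over_set else
      flags$under_set)
    if (length(flagged) == 0) next
    if (length(g) > 1) {
      # attribution requires the flagged gene to dominate the window
      mag <- abs(values[g])
      top <- names(mag)[mag == max(mag)]
      flagged <- if (length(top) == 1 && top %in% flagged) top else character(0)
    }
    q <- if (dir == "over") called$q_over[i] else called$q_under[i]
    for (sym in flagged) {
      rows[[length(rows) + 1]] <- data.frame(
        symbol = sym,
        chromosome = called$chromosome[i],
        direction = dir, q = q,
        window_start = called$start[i], window_end = called$end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(symbol = character(0), chromosome = character(0),
                      direction = character(0), q = numeric(0),
                      window_start = numeric(0), window_end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  # a gene can be called in both windows covering it: keep its best window
  res <- res[order(res$symbol, res$q, res$window_start), , drop = FALSE]
  res <- res[!duplicated(res$symbol), , drop = FALSE]
  res <- res[order(res$chromosome, res$window_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
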