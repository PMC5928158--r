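# Ground-truthed synthetic multi-platform expression datasets. The
# generator emulates what the integration pipeline assumes about real
# trisomic microarray pools: a designated trisomic chromosome at mean 3:2
# dosage with a fraction of dosage-escaping genes, trans-acting effects on
# other chromosomes, optional planted over-/under-expressed segments,
# several platforms of different feature counts covering overlapping gene
# subsets with smooth intensity-dependent bias, multiplicative lognormal
# noise, and values emitted in linear, ln or log2 format per platform.

#' Synthetic dataset configuration
#'
#' Defaults describe a desk-scale genome: six chromosomes with the trisomic
#' one deliberately smallest (120 of 1,800 loci, ~7%, mirroring the small
#' genomic fraction a real trisomic chromosome represents), three platforms
#' within the accepted 5,000-60,000 feature range whose probe sets cover
#' 90/70/50% of genes with 1-3 probes each plus unassigned filler probes,
#' power-law intensity bias per platform, mixed emission formats, 10
#' samples per pool and lognormal noise sigma 0.2.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param chromosomes chromosome labels.
#' @param genes_per_chromosome integer vector, one count per chromosome.
#' @param chromosome_lengths numeric vector of lengths in bp.
#' @param trisomic_chromosome label of the trisomic chromosome.
#' @param dosage_factor mean trisomic/euploid ratio for dosage-sensitive
#'   trisomic genes (default 1.5, the 3:2 expectation).
#' @param escape_fraction fraction of trisomic-chromosome genes escaping
#'   dosage (ratio 1; default 0.3).
#' @param trans_over,trans_under counts of non-trisomic genes placed at
#'   ratio 1.5 / 0.67 (downstream trans-effects).
#' @param planted_segments optional data.frame `chromosome`, `start`,
#'   `n_genes`, `ratio` (and optional `width`, default 500000): extra
#'   gene-dense windows whose members all carry `ratio`.
#' @param platforms list of platform descriptors: `platform_id`,
#'   `feature_count`, `coverage`, `bias_gamma`, `log_format`.
#' @param samples_per_pool biological samples per pool (platforms assigned
#'   round-robin).
#' @param noise_sigma lognormal sigma of per-record multiplicative noise.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline expression (between-gene sigma 1).
#' @param gene_length_meanlog,gene_length_sdlog lognormal gene-length
#'   parameters (median 20 kb).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             chromosomes = c("1", "2", "3", "4", "5", "21"),
                             genes_per_chromosome = c(400L, 380L, 350L,
                                                      300L, 250L, 120L),
                             chromosome_lengths = c(2.2e8, 1.9e8, 1.8e8,
                                                    1.5e8, 1.3e8, 4.5e7),
                             trisomic_chromosome = "21",
                             dosage_factor = 1.5,
                             escape_fraction = 0.3,
                             trans_over = 25L, trans_under = 25L,
                             planted_segments = NULL,
                             platforms = list(
                               list(platform_id = "PLT1",
                                    feature_count = 6000L, coverage = 0.9,
                                    bias_gamma = 0.85, log_format = "linear"),
                               list(platform_id = "PLT2",
                                    feature_count = 5500L, coverage = 0.7,
                                    bias_gamma = 1.15, log_format = "log2"),
                               list(platform_id = "PLT3",
                                    feature_count = 5000L, coverage = 0.5,
                                    bias_gamma = 1.0, log_format = "ln")),
                             samples_per_pool = 10L,
                             noise_sigma = 0.2,
                             baseline_meanlog = log(100),
                             baseline_sdlog = 1,
                             gene_length_meanlog = log(20000),
                             gene_length_sdlog = 0.8) {
  stopifnot(length(chromosomes) == length(genes_per_chromosome),
            length(chromosomes) == length(chromosome_lengths))
  if (!trisomic_chromosome %in% chromosomes) {
    stop("trisomic_chromosome must be one of the configured chromosomes")
  }
  if (escape_fraction < 0 || escape_fraction > 1) {
    stop("escape_fraction must lie in [0, 1]")
  }
  if (dosage_factor <= 0) stop("dosage_factor must be positive")
  for (p in platforms) {
    if (p$feature_count < PLATFORM_MIN_FEATURES ||
        p$feature_count > PLATFORM_MAX_FEATURES) {
      stop(sprintf("platform '%s': feature_count outside [%d, %d]",
                   p$platform_id, PLATFORM_MIN_FEATURES,
                   PLATFORM_MAX_FEATURES))
    }
    match.arg(p$log_format, VALID_SCALES)
  }
  if (!is.null(planted_segments)) {
    planted_segments <- as.data.frame(planted_segments)
    if (is.null(planted_segments$width)) planted_segments$width <- 500000
    stopifnot(all(c("chromosome", "start", "n_genes", "ratio") %in%
                    names(planted_segments)))
    if (!all(planted_segments$chromosome %in% chromosomes)) {
      stop("planted segment on unknown chromosome")
    }
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 chromosome_lengths = chromosome_lengths,
                 trisomic_chromosome = trisomic_chromosome,
                 dosage_factor = dosage_factor,
                 escape_fraction = escape_fraction,
                 trans_over = as.integer(trans_over),
                 trans_under = as.integer(trans_under),
                 planted_segments = planted_segments,
                 platforms = platforms,
                 samples_per_pool = as.integer(samples_per_pool),
                 noise_sigma = noise_sigma,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog),
            class = "synthetic_config")
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes at seeded positions: each chromosome is
#' divided into equal slots, one gene per slot at a uniform offset, with
#' lognormal lengths (median 20 kb, within the realistic range for human
#' protein-coding genes). Planted segments displace background genes in
#' their window and receive `n_genes` evenly spaced member genes. About 15%
#' of background loci are labelled EST clusters.
#'
#' @param config a [synthetic_config()].
#' @return A [genome_annotation()] with planted-segment truth stored in
#'   `attr(, "planted_segments")` and `attr(, "planted_genes")`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    rows <- list()
    for (ci in seq_along(config$chromosomes)) {
      chr <- config$chromosomes[ci]
      n <- config$genes_per_chromosome[ci]
      L <- config$chromosome_lengths[ci]
      slot <- floor(L / n)
      if (slot < 1000) {
        stop(sprintf("chromosome %s: %d genes do not fit in %g bp", chr, n, L))
      }
      len <- round(stats::rlnorm(n, config$gene_length_meanlog,
                                 config$gene_length_sdlog))
      len <- pmax(200, pmin(len, floor(0.8 * slot)))
      offset <- floor(stats::runif(n) * (slot - len))
      start <- (seq_len(n) - 1) * slot + 1 + offset
      est <- stats::runif(n) < 0.15
      rows[[ci]] <- data.frame(
        symbol = sprintf("G%s_%04d", chr, seq_len(n)),
        chromosome = chr, start = start, end = start + len - 1,
        biotype = ifelse(est, "est_cluster", "known_gene"),
        stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    planted_genes <- data.frame(symbol = character(0),
                                segment_id = integer(0),
                                stringsAsFactors = FALSE)
    ps <- config$planted_segments
    if (!is.null(ps) && nrow(ps) > 0) {
      for (si in seq_len(nrow(ps))) {
        chr <- ps$chromosome[si]
        s0 <- ps$start[si]
        wd <- ps$width[si]
        k <- ps$n_genes[si]
        e0 <- s0 + wd - 1
        if (e0 > config$chromosome_lengths[match(chr, config$chromosomes)]) {
          stop(sprintf("planted segment %d exceeds chromosome %s", si, chr))
        }
        clash <- ann$chromosome == chr & ann$end >= s0 & ann$start <= e0
        ann <- ann[!clash, , drop = FALSE]
        pitch <- floor(wd / k)
        glen <- min(10000, pitch - 100)
        gstart <- s0 + (seq_len(k) - 1) * pitch
        sym <- sprintf("SEG%02d_%02d", si, seq_len(k))
        ann <- rbind(ann, data.frame(symbol = sym, chromosome = chr,
                                     start = gstart, end = gstart + glen - 1,
                                     biotype = "known_gene",
                                     stringsAsFactors = FALSE))
        planted_genes <- rbind(planted_genes,
                               data.frame(symbol = sym, segment_id = si,
                                          stringsAsFactors = FALSE))
      }
      ps$end <- ps$start + ps$width - 1
      ps$segment_id <- seq_len(nrow(ps))
      ps$direction <- ifelse(ps$ratio >= 1, "over", "under")
    }
    out <- genome_annotation(
      ann, stats::setNames(config$chromosome_lengths, config$chromosomes))
    attr(out, "planted_segments") <- ps
    attr(out, "planted_genes") <- planted_genes
    out
  })
}

platform_bias <- function(x, gamma) {
  # smooth monotone intensity-dependent distortion, anchored at 100 so the
  # overall scale stays comparable across platforms
  x^gamma * 100^(1 - gamma)
}

#' Simulate trisomic and euploid sample pools
#'
#' Draws per-gene lognormal baselines, applies the per-gene true ratio to
#' the trisomic pool mean, builds the configured platforms (seeded gene
#' subsets with 1-3 probes per covered gene plus unassigned filler probes up
#' to the declared feature count), and emits per-sample probe values: pool
#' mean x lognormal noise x platform bias, in the platform's declared
#' format. Platforms are assigned to samples round-robin within each pool.
#'
#' @param config a [synthetic_config()].
#' @param annotation the matching [generate_annotation()] result.
#' @return list with `samples_a`, `samples_b` (lists of [expr_sample()]),
#'   `platforms` (named list of [platform()]), `truth` (a `synthetic_truth`:
#'   per-gene `$genes` with `true_ratio` and class flags, plus
#'   `$planted_segments`), and `annotation`.
#' @export
simulate_pools <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "genome_annotation"))
  ann <- as.data.frame(annotation)
  nG <- nrow(ann)
  planted_genes <- attr(annotation, "planted_genes") %||%
    data.frame(symbol = character(0), segment_id = integer(0))
  ps <- attr(annotation, "planted_segments")
  with_seed(config$seed + 1L, {
    true_ratio <- rep(1, nG)
    gene_class <- rep("background", nG)
    is_planted <- ann$symbol %in% planted_genes$symbol
    if (any(is_planted)) {
      sid <- planted_genes$segment_id[match(ann$symbol[is_planted],
                                            planted_genes$symbol)]
      true_ratio[is_planted] <- ps$ratio[sid]
      gene_class[is_planted] <- "planted"
    }
    tri <- ann$chromosome == config$trisomic_chromosome & !is_planted
    true_ratio[tri] <- config$dosage_factor
    gene_class[tri] <- "trisomic_dosage"
    n_esc <- round(config$escape_fraction * sum(tri))
    if (n_esc > 0) {
      esc <- sample(which(tri), n_esc)
      true_ratio[esc] <- 1
      gene_class[esc] <- "escaping"
    }
    eligible <- which(gene_class == "background")
    if (config$trans_over > 0) {
      to <- sample(eligible, min(config$trans_over, length(eligible)))
      true_ratio[to] <- 1.5
      gene_class[to] <- "trans_over"
      eligible <- setdiff(eligible, to)
    }
    if (config$trans_under > 0) {
      tu <- sample(eligible, min(config$trans_under, length(eligible)))
      true_ratio[tu] <- 0.67
      gene_class[tu] <- "trans_under"
    }
    baseline <- stats::rlnorm(nG, config$baseline_meanlog,
                              config$baseline_sdlog)
    mean_b <- baseline
    mean_a <- baseline * true_ratio

    platforms <- list()
    probe_gene_idx <- list()
    for (j in seq_along(config$platforms)) {
      pd <- config$platforms[[j]]
      covered <- which(stats::runif(nG) < pd$coverage)
      n_probes <- sample(1:3, length(covered), replace = TRUE)
      gene_idx <- rep(covered, n_probes)
      n_mapped <- length(gene_idx)
      n_filler <- pd$feature_count - n_mapped
      if (n_filler < 0) {
        stop(sprintf("platform '%s': %d mapped probes exceed feature_count %d",
                     pd$platform_id, n_mapped, pd$feature_count))
      }
      ids <- sprintf("%s_p%06d", pd$platform_id, seq_len(pd$feature_count))
      probe_map <- stats::setNames(
        c(ann$symbol[gene_idx], rep(NA_character_, n_filler)), ids)
      platforms[[pd$platform_id]] <- platform(pd$platform_id, probe_map)
      probe_gene_idx[[pd$platform_id]] <-
        c(gene_idx, rep(NA_integer_, n_filler))
    }

    make_sample <- function(pool, i) {
      j <- (i - 1) %% length(config$platforms) + 1
      pd <- config$platforms[[j]]
      gidx <- probe_gene_idx[[pd$platform_id]]
      mapped <- !is.na(gidx)
      mu <- numeric(length(gidx))
      mu[mapped] <- if (pool == "A") mean_a[gidx[mapped]] else
        mean_b[gidx[mapped]]
      mu[!mapped] <- stats::rlnorm(sum(!mapped), config$baseline_meanlog,
                                   config$baseline_sdlog)
      v <- mu * stats::rlnorm(length(mu), 0, config$noise_sigma)
      v <- platform_bias(v, pd$bias_gamma)
      emitted <- switch(pd$log_format,
                        linear = v, ln = log(v), log2 = log2(v))
      expr_sample(sprintf("%s%02d", pool, i), pd$platform_id,
                  if (pool == "A") "A_trisomic" else "B_euploid",
                  stats::setNames(emitted, names(platforms[[
                    pd$platform_id]]$probe_map)),
                  scale = pd$log_format)
    }
    samples_a <- lapply(seq_len(config$samples_per_pool),
                        function(i) make_sample("A", i))
    samples_b <- lapply(seq_len(config$samples_per_pool),
                        function(i) make_sample("B", i))
    truth <- structure(
      list(genes = data.frame(symbol = ann$symbol,
                              chromosome = ann$chromosome,
                              true_ratio = true_ratio,
                              class = gene_class,
                              stringsAsFactors = FALSE),
           planted_segments = ps,
           config = config),
      class = "synthetic_truth")
    list(samples_a = samples_a, samples_b = samples_b,
         platforms = platforms, truth = truth, annotation = annotation)
  })
}

#' Write a simulated dataset as plain-text tables
#'
#' Emits exactly the formats the readers consume: one two-column expression
#' TSV per sample, one platform annotation TSV per platform, the gene
#' annotation TSV, a sample manifest and the per-gene truth table. Output is
#' byte-identical for identical configurations.
#'
#' @param sim a [simulate_pools()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (s in c(sim$samples_a, sim$samples_b)) {
    f <- file.path(dir, paste0(s$sample_id, ".tsv"))
    writeLines(c("probe_id\tvalue",
                 sprintf("%s\t%.12g", names(s$values), s$values)), f)
    manifest[[length(manifest) + 1]] <- data.frame(
      sample_id = s$sample_id, file = basename(f),
      platform_id = s$platform_id, condition = s$condition,
      scale = s$scale, stringsAsFactors = FALSE)
  }
  for (p in sim$platforms) {
    sym <- p$probe_map
    sym[is.na(sym)] <- ""
    writeLines(c("probe_id\tgene_symbol",
                 sprintf("%s\t%s", names(p$probe_map), sym)),
               file.path(dir, paste0("platform_", p$platform_id, ".tsv")))
  }
  ann <- as.data.frame(sim$annotation)
  writeLines(c("symbol\tchromosome\tstart\tend\tbiotype",
               sprintf("%s\t%s\t%d\t%d\t%s", ann$symbol, ann$chromosome,
                       as.integer(ann$start), as.integer(ann$end),
                       ann$biotype)),
             file.path(dir, "annotation.tsv"))
  tg <- sim$truth$genes
  writeLines(c("symbol\tchromosome\ttrue_ratio\tclass",
               sprintf("%s\t%s\t%.12g\t%s", tg$symbol, tg$chromosome,
                       tg$true_ratio, tg$class)),
             file.path(dir, "truth_genes.tsv"))
  mf <- do.call(rbind, manifest)
  writeLines(c("sample_id\tfile\tplatform_id\tcondition\tscale",
               sprintf("%s\t%s\t%s\t%s\t%s", mf$sample_id, mf$file,
                       mf$platform_id, mf$condition, mf$scale)),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Score a pipeline run against the generator's ground truth
#'
#' Segment-level recovery is direction-matched: a planted segment counts as
#' recovered if at least one called segment of the same direction overlaps
#' it by >= 1 bp; precision is the fraction of calls (in directions that
#' were planted) overlapping a planted segment, `NA` when there are no such
#' calls. Per-gene ratio accuracy is summarized as the RMSE of
#' `log2(estimated/true)` per gene class.
#'
#' @param truth the `synthetic_truth` from [simulate_pools()].
#' @param result a [run_pipeline()] result on the same dataset.
#' @return list: `sensitivity`, `precision`, `n_planted`, `n_calls`,
#'   `false_calls`, and `ratio_rmse` (data.frame `class`, `n`,
#'   `rmse_log2`).
#' @export
truth_report <- function(truth, result) {
  stopifnot(inherits(truth, "synthetic_truth"))
  comparison <- result$comparison
  if (!all(comparison$symbol %in% truth$genes$symbol)) {
    stop("comparison contains loci unknown to the truth (mismatched annotation)")
  }
  ps <- truth$planted_segments
  called <- result$called
  if (is.null(ps) || nrow(ps) == 0) {
    sens <- NA_real_
    prec <- NA_real_
    n_calls <- if (is.null(called)) 0L else nrow(called)
    false_calls <- n_calls
  } else {
    dirs <- unique(ps$direction)
    calls <- called[called$call %in% dirs, , drop = FALSE]
    overlaps <- function(seg, call_df) {
      any(call_df$chromosome == seg$chromosome &
            call_df$call == seg$direction &
            call_df$end >= seg$start & call_df$start <= seg$end)
    }
    hit <- vapply(seq_len(nrow(ps)), function(i) {
      overlaps(ps[i, ], calls)
    }, logical(1))
    sens <- mean(hit)
    n_calls <- nrow(calls)
    if (n_calls == 0) {
      prec <- NA_real_
      false_calls <- 0L
    } else {
      call_hit <- vapply(seq_len(n_calls), function(i) {
        any(ps$chromosome == calls$chromosome[i] &
              ps$direction == calls$call[i] &
              ps$end >= calls$start[i] & ps$start <= calls$end[i])
      }, logical(1))
      prec <- mean(call_hit)
      false_calls <- sum(!call_hit)
    }
  }
  m <- merge(comparison[, c("symbol", "ratio")],
             truth$genes[, c("symbol", "true_ratio", "class")],
             by = "symbol")
  err <- log2(m$ratio / m$true_ratio)
  rmse <- stats::aggregate(err ~ class, data = data.frame(err = err,
                                                          class = m$class),
                           FUN = function(e) sqrt(mean(e^2)))
  names(rmse)[2] <- "rmse_log2"
  cnt <- as.data.frame(table(m$class), stringsAsFactors = FALSE)
  names(cnt) <- c("class", "n")
  ratio_rmse <- merge(cnt, rmse, by = "class")
  list(sensitivity = sens, precision = prec,
       n_planted = if (is.null(ps)) 0L else nrow(ps),
       n_calls = n_calls, false_calls = false_calls,
       ratio_rmse = ratio_rmse)
}
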