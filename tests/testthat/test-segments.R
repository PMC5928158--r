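test_that("window tiling and start-coordinate membership follow the defaults", {
  ann <- toy_annotation(c("g1", "g2"), spacing = 300000, chrom_len = 1e6)
  # g1 at 300,000; g2 at 600,000
  segs <- build_segments(ann, c("g1", "g2"))
  expect_equal(segs$start, c(1, 250001, 500001, 750001))
  expect_equal(segs$end, c(500000, 750000, 1000000, 1000000))
  # a gene starting at 300,000 sits in [1, 500,000] and [250,001, 750,000]
  expect_equal(which(vapply(segs$loci, function(g) "g1" %in% g, logical(1))),
               c(1L, 2L))
})

test_that("each locus falls in exactly two windows away from chromosome ends", {
  cfg <- small_synth_config(seed = 8)
  ann <- generate_annotation(cfg)
  segs <- build_segments(ann, ann$symbol)
  counts <- table(unlist(segs$loci))
  w <- map_config()$window_size
  lens <- attr(ann, "chromosome_lengths")
  interior <- ann$start > w & ann$start <= lens[ann$chromosome] - w
  expect_true(all(counts[ann$symbol[interior]] == 2))
  expect_true(all(counts >= 1))
})

test_that("chromosomes without loci keep their (uncallable) empty windows", {
  ann <- genome_annotation(
    data.frame(symbol = "g1", chromosome = "1", start = 100, end = 200,
               biotype = "known_gene", stringsAsFactors = FALSE),
    c("1" = 1e6, "2" = 1e6))
  segs <- build_segments(ann, "g1")
  expect_true(all(segs$n_genes[segs$chromosome == "2"] == 0))
  expect_equal(nrow(build_segments(ann, "g1", drop_empty = TRUE)), 1)
})

test_that("extreme-locus flagging matches brute-force percentiles", {
  v <- stats::setNames(as.numeric(1:1000), sprintf("g%04d", 1:1000))
  fl <- flag_extreme_loci(v, 2.5)
  expect_setequal(fl$over_set, sprintf("g%04d", 976:1000))
  expect_setequal(fl$under_set, sprintf("g%04d", 1:25))
  expect_equal(fl$K_over, 25L)

  v40 <- stats::setNames(as.numeric(1:40), sprintf("g%02d", 1:40))
  fl40 <- flag_extreme_loci(v40, 2.5)
  expect_equal(fl40$over_set, "g40")
  expect_equal(fl40$under_set, "g01")

  const <- stats::setNames(rep(5, 100), sprintf("g%03d", 1:100))
  flc <- flag_extreme_loci(const, 2.5)
  expect_length(flc$over_set, 0)
  expect_length(flc$under_set, 0)
})

test_that("hypergeometric upper tail matches enumeration oracles", {
  expect_equal(hypergeometric_pvalue(0, 5, 3, 20), 1)
  expect_equal(hypergeometric_pvalue(5, 10, 5, 10), 1)  # all items drawn
  # literal enumeration over all C(20, 6) draws
  expect_equal(hypergeometric_pvalue(3, 6, 5, 20),
               hyper_tail_enumeration(3, 6, 5, 20), tolerance = 1e-12)
  # counting-sum oracle over a grid of parameter combinations
  for (N in c(7, 13, 22)) {
    for (K in c(1, floor(N / 2), N - 1)) {
      for (n in c(1, floor(N / 3), N)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_pvalue(k, n, K, N),
                       hyper_tail_oracle(k, n, K, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_pvalue(4, 3, 5, 20), "min")
  expect_error(hypergeometric_pvalue(1, 3, 25, 20), "N")
})

test_that("candidate tagging needs both the gene count and the segment value", {
  set.seed(17)
  syms <- sprintf("g%04d", 1:2000)
  values <- stats::setNames(rnorm(2000, 0, 0.1), syms)
  giants <- c("g0001", "g0002", "g0003",    # hot window H
              "g0010", "g0011",             # two-gene window K2
              "g0020", "g0021", "g0022")    # mid-value window M
  values[giants] <- 5
  flags <- flag_extreme_loci(values, 2.5)
  expect_true(all(giants %in% flags$over_set))

  bg <- setdiff(syms, giants)
  seg_row <- function(start, loci) data.frame(
    chromosome = "1", start = start, end = start + 499999,
    n_genes = length(loci), loci = I(list(loci)),
    stringsAsFactors = FALSE)
  segs <- rbind(
    seg_row(1, c("g0001", "g0002", "g0003")),
    seg_row(250001, c("g0010", "g0011")),
    seg_row(500001, c("g0020", "g0021", "g0022",
                      "g0100", "g0101", "g0102", "g0103", "g0104")),
    do.call(rbind, lapply(1:100, function(i) {
      seg_row(1e6 + i * 5e5, bg[(200 + 5 * i):(204 + 5 * i)])
    })))
  # window M's five background partners pulled far down: k = 3 but value mid
  values[c("g0100", "g0101", "g0102", "g0103", "g0104")] <- -3
  tagged <- tag_and_test_segments(segs, flags, values)
  # H: 3 flagged genes and extreme value -> candidate, called
  expect_equal(tagged$call[1], "over")
  expect_true(tagged$q_over[1] < 0.05)
  # K2: extreme value but only 2 flagged genes -> never a candidate
  expect_true(is.na(tagged$p_over[2]))
  expect_equal(tagged$call[2], "none")
  # M: 3 flagged genes but unremarkable segment value -> not a candidate
  expect_true(is.na(tagged$p_over[3]))
  # every call satisfies both conditions post hoc
  called <- tagged[tagged$call == "over", ]
  expect_true(all(called$k_over >= 3))
  # BH keeps q >= p
  cand <- !is.na(tagged$p_over)
  expect_true(all(tagged$q_over[cand] >= tagged$p_over[cand]))
})

test_that("a planted gene-dense segment is recovered by the full machinery", {
  # 2,000 loci; one 500 kb window holds 8 members at ratio 3, background 1
  set.seed(23)
  n_bg <- 1992
  bg_start <- (seq_len(n_bg)) * 2e5
  p0 <- 250000 * 300 + 1
  keep <- bg_start < p0 - 5e5 | bg_start > p0 + 1e6
  bg_start <- bg_start[keep]
  planted <- sprintf("PL_%d", 1:8)
  ann_df <- rbind(
    data.frame(symbol = sprintf("bg%04d", seq_along(bg_start)),
               chromosome = "1", start = bg_start, end = bg_start + 999,
               biotype = "known_gene", stringsAsFactors = FALSE),
    data.frame(symbol = planted, chromosome = "1",
               start = p0 + (0:7) * 60000, end = p0 + (0:7) * 60000 + 999,
               biotype = "known_gene", stringsAsFactors = FALSE))
  ann <- genome_annotation(ann_df, c("1" = 4.1e8))
  values <- stats::setNames(
    c(rnorm(length(bg_start), 0, 0.2 / log(2)), rep(log2(3), 8)),
    c(sprintf("bg%04d", seq_along(bg_start)), planted))
  flags <- flag_extreme_loci(values, 2.5)
  expect_true(all(planted %in% flags$over_set))
  segs <- build_segments(ann, names(values), drop_empty = TRUE)
  tagged <- tag_and_test_segments(segs, flags, values)
  called <- tagged[tagged$call == "over", ]
  expect_gt(nrow(called), 0)
  expect_true(all(called$end >= p0 & called$start <= p0 + 5e5 - 1))
  dedup <- deduplicate_segments(tagged)
  dedup_over <- dedup[dedup$call == "over", ]
  expect_gte(nrow(dedup_over), 1)
  expect_lt(nrow(dedup_over), nrow(called))
  # the kept representative is the most extreme of its chain
  expect_equal(max(dedup_over$segment_value), max(called$segment_value))
})

test_that("overlap deduplication keeps the most extreme window of a chain", {
  row <- function(chr, start, loci, value, q, call = "over") data.frame(
    chromosome = chr, start = start, end = start + 499999,
    n_genes = length(loci), loci = I(list(loci)), segment_value = value,
    q_over = if (call == "over") q else NA_real_,
    q_under = if (call == "under") q else NA_real_,
    call = call, stringsAsFactors = FALSE)
  # two half-overlapping windows over one hotspot: keep value 3.1
  two <- rbind(row("1", 1, c("a", "b", "c", "d"), 2.8, 0.01),
               row("1", 250001, c("b", "c", "d"), 3.1, 0.02))
  kept <- deduplicate_segments(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$segment_value, 3.1)
  # different chromosomes: both kept
  twochr <- rbind(row("1", 1, c("a", "b", "c"), 2.8, 0.01),
                  row("2", 1, c("x", "y", "z"), 3.1, 0.01))
  expect_equal(nrow(deduplicate_segments(twochr)), 2)
  # identical content and value: leftmost wins
  tie <- rbind(row("1", 1, c("a", "b", "c"), 2.0, 0.01),
               row("1", 250001, c("a", "b", "c"), 2.0, 0.01))
  expect_equal(deduplicate_segments(tie)$start, 1)
  # under-direction chains keep the smallest value
  und <- rbind(row("1", 1, c("a", "b", "c"), -2.0, 0.01, "under"),
               row("1", 250001, c("b", "c"), -2.5, 0.02, "under"))
  expect_equal(deduplicate_segments(und)$segment_value, -2.5)
})

test_that("single-gene mode attributes calls only to prevailing flagged genes", {
  # 156 quiet background genes plus four constructed cases; positions are
  # chosen so each special pair always shares its 25 kb windows
  set.seed(29)
  bg <- sprintf("bg%03d", 1:156)
  specials <- c("X", "U", "V", "W", "T")
  pos <- c(1e6 + (1:156) * 40000,
           X = 11250003, U = 11500003, V = 11505003,
           W = 11750003, T = 11755003)
  ann <- genome_annotation(
    data.frame(symbol = c(bg, specials), chromosome = "1", start = pos,
               end = pos + 499, biotype = "known_gene",
               stringsAsFactors = FALSE),
    c("1" = 2e7))
  values <- stats::setNames(
    c(rnorm(156, 0, 0.05), 2.5, 2.0, 1.2, 1.8, 0.9),
    c(bg, specials))
  res <- single_gene_mode(values, ann)
  over <- res[res$direction == "over", ]
  # isolated flagged gene X: called with its window's q
  expect_true("X" %in% over$symbol)
  expect_true(all(over$q < 0.05))
  # U prevails over flagged neighbour V: only U attributed
  expect_true("U" %in% over$symbol)
  expect_false("V" %in% over$symbol)
  # flagged W with a neutral neighbour still extreme: attributed to W
  expect_true("W" %in% over$symbol)
  expect_false("T" %in% over$symbol)
})

test_that("a structureless map yields no segment calls", {
  v <- stats::setNames(rep(1, 500), sprintf("g%03d", 1:500))
  ann <- toy_annotation(names(v), spacing = 1e5, chrom_len = 6e7)
  flags <- flag_extreme_loci(v, 2.5)
  segs <- build_segments(ann, names(v), drop_empty = TRUE)
  tagged <- tag_and_test_segments(segs, flags, v)
  expect_true(all(tagged$call == "none"))
})
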