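test_that("annotation generation is deterministic, sorted and non-overlapping", {
  cfg <- small_synth_config(seed = 4)
  ann1 <- generate_annotation(cfg)
  ann2 <- generate_annotation(cfg)
  expect_identical(as.data.frame(ann1), as.data.frame(ann2))
  expect_equal(nrow(ann1), sum(cfg$genes_per_chromosome))
  for (chr in cfg$chromosomes) {
    sub <- ann1[ann1$chromosome == chr, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(utils::head(sub$end, -1) < utils::tail(sub$start, -1)))
  }
  # gene sizes are realistic: mean length within a factor 4 of 67 kb
  mean_len <- mean(ann1$end - ann1$start + 1)
  expect_gt(mean_len, 67000 / 4)
  expect_lt(mean_len, 67000 * 4)
})

test_that("planted segments displace background genes and carry their ratio", {
  cfg <- small_synth_config(
    seed = 6,
    planted_segments = data.frame(chromosome = "1", start = 10000001,
                                  n_genes = 8, ratio = 3))
  ann <- generate_annotation(cfg)
  pg <- attr(ann, "planted_genes")
  expect_equal(nrow(pg), 8)
  inside <- ann[ann$start >= 10000001 & ann$start <= 10500000 &
                  ann$chromosome == "1", ]
  expect_setequal(inside$symbol, pg$symbol)
  sim <- simulate_pools(cfg, ann)
  tg <- sim$truth$genes
  expect_true(all(tg$true_ratio[tg$symbol %in% pg$symbol] == 3))
  expect_equal(attr(ann, "planted_segments")$direction, "over")
})

test_that("the noiseless limit reproduces the dosage ratio exactly", {
  cfg <- small_synth_config(
    seed = 5, noise_sigma = 0, escape_fraction = 0,
    trans_over = 0L, trans_under = 0L,
    platforms = list(list(platform_id = "PL", feature_count = 5000L,
                          coverage = 0.9, bias_gamma = 1,
                          log_format = "linear")),
    samples_per_pool = 3L)
  ann <- generate_annotation(cfg)
  sim <- simulate_pools(cfg, ann)
  a <- sim$samples_a[[1]]$values
  b <- sim$samples_b[[1]]$values
  plat <- sim$platforms$PL
  gene <- plat$probe_map[names(a)]
  chr <- ann$chromosome[match(gene, ann$symbol)]
  tri <- !is.na(chr) & chr == "21"
  expect_equal(unname(a[tri] / b[tri]), rep(1.5, sum(tri)))
  other <- !is.na(chr) & chr != "21"
  expect_equal(unname(a[other] / b[other]), rep(1, sum(other)))
})

test_that("full escape makes the trisomic chromosome indistinguishable", {
  cfg <- small_synth_config(seed = 7, escape_fraction = 1,
                            trans_over = 0L, trans_under = 0L)
  ann <- generate_annotation(cfg)
  sim <- simulate_pools(cfg, ann)
  expect_true(all(sim$truth$genes$true_ratio == 1))
  res <- run_pipeline(sim$samples_a, sim$samples_b, sim$platforms, ann,
                      run_segments = FALSE, run_single_gene = FALSE)
  tri_ratio <- res$chromosome_summary$ratio[
    res$chromosome_summary$chromosome == "21"]
  expect_lt(abs(tri_ratio - 1), 0.1)
})

test_that("truth classes partition the genes consistently with the config", {
  cfg <- small_synth_config(seed = 9)
  ann <- generate_annotation(cfg)
  sim <- simulate_pools(cfg, ann)
  tg <- sim$truth$genes
  n_tri_chr <- sum(ann$chromosome == "21")
  expect_equal(sum(tg$class %in% c("trisomic_dosage", "escaping")), n_tri_chr)
  expect_equal(sum(tg$class == "escaping"),
               round(cfg$escape_fraction * n_tri_chr))
  expect_equal(sum(tg$class == "trans_over"), cfg$trans_over)
  expect_equal(sum(tg$class == "trans_under"), cfg$trans_under)
  expect_true(all(tg$true_ratio[tg$class == "trisomic_dosage"] == 1.5))
  expect_true(all(tg$true_ratio[tg$class == "escaping"] == 1))
})

test_that("emitted log formats round-trip through linearize", {
  base <- list(platform_id = "PL", feature_count = 5000L, coverage = 0.8,
               bias_gamma = 1.1)
  cfg_lin <- small_synth_config(
    seed = 11, platforms = list(c(base, log_format = "linear")),
    samples_per_pool = 3L)
  cfg_log <- small_synth_config(
    seed = 11, platforms = list(c(base, log_format = "log2")),
    samples_per_pool = 3L)
  ann <- generate_annotation(cfg_lin)
  lin <- simulate_pools(cfg_lin, ann)$samples_a[[1]]
  logd <- simulate_pools(cfg_log, generate_annotation(cfg_log))$samples_a[[1]]
  expect_equal(logd$scale, "log2")
  expect_equal(linearize(logd)$values, lin$values, tolerance = 1e-9)
})

test_that("written datasets are byte-identical under a fixed seed", {
  cfg <- small_synth_config(seed = 13, samples_per_pool = 3L)
  ann <- generate_annotation(cfg)
  sim <- simulate_pools(cfg, ann)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_dataset(sim, d1)
  write_synthetic_dataset(simulate_pools(cfg, generate_annotation(cfg)), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("truth_report scores perfect, absent and null calls as specified", {
  ps <- data.frame(chromosome = "1", start = 1e6, n_genes = 8, ratio = 3,
                   width = 5e5, end = 1.5e6 - 1, segment_id = 1,
                   direction = "over", stringsAsFactors = FALSE)
  truth <- structure(list(
    genes = data.frame(symbol = c("a", "b"), chromosome = "1",
                       true_ratio = c(3, 1), class = c("planted",
                                                       "background"),
                       stringsAsFactors = FALSE),
    planted_segments = ps, config = NULL), class = "synthetic_truth")
  cmp <- data.frame(symbol = c("a", "b"), ratio = c(3, 1),
                    stringsAsFactors = FALSE)
  hit <- data.frame(chromosome = "1", start = 1.1e6, end = 1.6e6,
                    call = "over", stringsAsFactors = FALSE)
  perfect <- truth_report(truth, list(comparison = cmp, called = hit))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  none <- truth_report(truth, list(comparison = cmp, called = hit[0, ]))
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$precision))
  # no planted structure: precision undefined, stray calls counted
  null_truth <- truth
  null_truth$planted_segments <- NULL
  null_rep <- truth_report(null_truth, list(comparison = cmp, called = hit))
  expect_true(is.na(null_rep$precision))
  expect_equal(null_rep$false_calls, 1L)
  # mismatched annotation is an error
  bad_cmp <- data.frame(symbol = "zz", ratio = 1, stringsAsFactors = FALSE)
  expect_error(truth_report(truth, list(comparison = bad_cmp, called = hit)),
               "mismatched")
})
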