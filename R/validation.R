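# qPCR-side arithmetic: 2^-ddCt relative quantification and the
# expected-vs-observed Pearson correlation used to validate a map against
# independent Real-Time RT-PCR measurements.

#' Relative expression ratio by the 2^-ddCt method
#'
#' Computes the trisomic/euploid expression ratio of a target gene from
#' qPCR threshold cycles: dCt(pool) = Ct_target(pool) - mean(Ct of the
#' reference genes in that pool); ddCt = dCt(test) - dCt(control); ratio =
#' 2^-ddCt. Multiple reference genes are combined by the arithmetic mean of
#' their Ct values (equivalently the geometric mean of their relative
#' quantities). One cycle less for the target in the test pool, references
#' unchanged, doubles the ratio.
#'
#' @param ct_target_test mean Ct of the target gene in the test (trisomic)
#'   pool.
#' @param ct_target_control mean Ct of the target in the control (euploid)
#'   pool.
#' @param ct_ref_test numeric vector of reference-gene Cts in the test pool.
#' @param ct_ref_control reference-gene Cts in the control pool.
#' @return The observed expression ratio `2^-ddCt`.
#' @export
delta_delta_ct <- function(ct_target_test, ct_target_control,
                           ct_ref_test, ct_ref_control) {
  cts <- c(ct_target_test, ct_target_control, ct_ref_test, ct_ref_control)
  if (length(ct_ref_test) == 0 || length(ct_ref_control) == 0) {
    stop("at least one reference-gene Ct required per pool")
  }
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be finite and positive")
  }
  d_test <- ct_target_test - mean(ct_ref_test)
  d_control <- ct_target_control - mean(ct_ref_control)
  2^(-(d_test - d_control))
}

#' Observed ratios from a replicate-level Ct table
#'
#' Averages technical replicates per gene and pool, then applies
#' [delta_delta_ct()] per target gene against the named reference genes.
#'
#' @param ct_table data.frame with columns `gene`, `pool` (`"test"` /
#'   `"control"`), `ct` (one row per replicate).
#' @param reference_genes character vector of reference gene symbols present
#'   in the table.
#' @return data.frame `gene`, `observed_ratio` for all non-reference genes.
#' @export
qpcr_relative_ratios <- function(ct_table, reference_genes) {
  stopifnot(all(c("gene", "pool", "ct") %in% names(ct_table)))
  if (!all(reference_genes %in% ct_table$gene)) {
    stop("reference gene(s) missing from the Ct table: ",
         paste(setdiff(reference_genes, ct_table$gene), collapse = ", "))
  }
  mean_ct <- stats::aggregate(ct ~ gene + pool, data = ct_table, FUN = mean)
  get_ct <- function(g, p) {
    v <- mean_ct$ct[mean_ct$gene == g & mean_ct$pool == p]
    if (length(v) != 1) stop(sprintf("missing Ct for gene '%s' pool '%s'", g, p))
    v
  }
  targets <- setdiff(unique(ct_table$gene), reference_genes)
  ref_test <- vapply(reference_genes, get_ct, numeric(1), p = "test")
  ref_control <- vapply(reference_genes, get_ct, numeric(1), p = "control")
  data.frame(gene = targets,
             observed_ratio = vapply(targets, function(g) {
               delta_delta_ct(get_ct(g, "test"), get_ct(g, "control"),
                              ref_test, ref_control)
             }, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of expected vs observed ratios
#'
#' The map validation statistic: the product-moment correlation between the
#' expected ratios (from the integrated map) and the observed ratios (from
#' 2^-ddCt qPCR), with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param expected,observed positive numeric vectors of matched ratios
#'   (length >= 3).
#' @return `list(r = , p = , n = )`.
#' @export
correlate_ratios <- function(expected, observed) {
  if (length(expected) != length(observed)) {
    stop("expected and observed must have equal length")
  }
  if (length(expected) < 3) stop("at least 3 ratio pairs required")
  if (stats::sd(expected) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in one of the ratio columns")
  }
  ct <- stats::cor.test(expected, observed, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(expected))
}

#' Published fibroblast qPCR validation panel
#'
#' The 13-gene panel used to validate a trisomy-21 vs euploid fibroblast
#' transcriptome map in vitro: per-pool expected expression values (EEV A
#' trisomic, EEV B euploid, percent-of-mean units from the integrated map),
#' the expected ratio ER = EEV A / EEV B, and the observed ratio OR from
#' Real-Time RT-PCR (2^-ddCt against GAPDH and B2M). Values as published.
#'
#' @return data.frame with columns `gene`, `eev_a`, `eev_b`,
#'   `expected_ratio`, `observed_ratio`.
#' @export
load_qpcr_panel <- function() {
  path <- system.file("extdata", "fibroblast_qpcr_panel.tsv",
                      package = "trisomap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published SOD1 per-tissue dosage panel
#'
#' Per-tissue consensus expression values (percent-of-mean units) of SOD1,
#' a gene with a long-established 3:2 dosage effect, in trisomic vs euploid
#' pools across six tissues/cell types, with the published ratios. Used to
#' check the package's ratio arithmetic against printed values.
#'
#' @return data.frame with columns `tissue`, `mean_trisomic`,
#'   `mean_euploid`, `published_ratio`.
#' @export
load_sod1_panel <- function() {
  path <- system.file("extdata", "sod1_tissue_panel.tsv",
                      package = "trisomap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Validate a map against a qPCR panel
#'
#' Recomputes the expected ratio from the per-pool consensus values,
#' compares it (at 2 d.p.) with the stored expected-ratio column, and
#' correlates expected with observed ratios.
#'
#' @param panel a validation panel like [load_qpcr_panel()] (columns
#'   `gene`, `eev_a`, `eev_b`, `expected_ratio`, `observed_ratio`).
#' @return list with `panel` (augmented with `er_recomputed` and
#'   `er_matches`), `n_matching`, and the correlation `r`, `p`, `n`.
#' @export
run_validation <- function(panel = load_qpcr_panel()) {
  panel$er_recomputed <- round_half_up(panel$eev_a / panel$eev_b, 2)
  panel$er_matches <- panel$er_recomputed == round_half_up(panel$expected_ratio, 2)
  corr <- correlate_ratios(panel$expected_ratio, panel$observed_ratio)
  list(panel = panel, n_matching = sum(panel$er_matches),
       r = corr$r, p = corr$p, n = corr$n)
}
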