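# Two-stage normalization: per-sample global normalization (percent of the
# sample mean) after non-positive thresholding, then cross-sample scaled
# quantile normalization on a fixed-resolution quantile grid, which is what
# makes platforms with very different feature counts comparable.

#' Threshold non-positive intensities
#'
#' Raw values at or below zero cannot enter ratio arithmetic (x/0 is
#' undefined and 0 in a numerator erases genuine strong over-expression), so
#' they are replaced by 95% of the minimum positive value observed in the
#' same sample: "just below the detection floor".
#'
#' @param x numeric vector of raw intensities (or a `locus_records` object,
#'   whose record values are thresholded in place).
#' @param factor multiplier on the minimum positive value (default 0.95).
#' @return Same shape as `x`, with every value > 0.
#' @export
threshold_nonpositive <- function(x, factor = 0.95) {
  if (inherits(x, "locus_records")) {
    x$records$value <- threshold_nonpositive(x$records$value, factor)
    return(x)
  }
  pos <- x[x > 0]
  if (length(pos) == 0) {
    stop("sample unusable: no positive expression values")
  }
  floor_val <- factor * min(pos)
  x[x <= 0] <- floor_val
  x
}

#' Intra-sample global normalization
#'
#' Each value becomes its percentage of the sample mean, so every sample has
#' mean 100 and samples of wildly different overall intensity become
#' comparable (classic "global normalization").
#'
#' @param x positive numeric vector (or a `locus_records` object).
#' @return Same shape as `x`, rescaled so that `mean(x) == 100`.
#' @export
intra_sample_normalize <- function(x) {
  if (inherits(x, "locus_records")) {
    x$records$value <- intra_sample_normalize(x$records$value)
    class(x) <- unique(c("normalized_sample", class(x)))
    return(x)
  }
  if (length(x) == 0) stop("cannot normalize an empty sample")
  100 * x / mean(x)
}

#' Threshold and globally normalize one sample
#'
#' Convenience wrapper: [threshold_nonpositive()] then
#' [intra_sample_normalize()], in that order (the sample mean is taken over
#' thresholded values).
#'
#' @param rec a `locus_records` object from [resolve_probes()].
#' @param threshold_factor multiplier on the minimum positive value.
#' @return A `normalized_sample` (percent-of-mean units).
#' @export
normalize_sample <- function(rec, threshold_factor = 0.95) {
  intra_sample_normalize(threshold_nonpositive(rec, threshold_factor))
}

sample_values <- function(s) {
  if (inherits(s, "locus_records")) s$records$value else as.numeric(s)
}

#' Build a scaled-quantile reference
#'
#' Evaluates each sample's empirical quantile function (linear
#' interpolation, i.e. `stats::quantile` type 7) on a fixed probability grid
#' `k/(n_points - 1)`, `k = 0..n_points - 1`, and averages pointwise across
#' samples. Because the grid resolution is fixed, samples with different
#' numbers of features contribute on equal footing; in the limit where all
#' samples share the same feature count equal to `n_points`, the reference
#' equals the classical quantile-normalization reference.
#'
#' The reference must be built jointly over both pools of an analysis:
#' per-pool references would normalize away the very pool-level shifts the
#' differential map measures.
#'
#' @param samples list of `normalized_sample` objects or numeric vectors
#'   (each with at least 2 values).
#' @param n_points grid resolution (default 1001).
#' @return A `quantile_reference`: probability grid `$probs` and
#'   nondecreasing value grid `$grid`.
#' @export
build_quantile_reference <- function(samples, n_points = 1001) {
  if (length(samples) < 1) stop("at least one sample required")
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("n_points must be >= 2")
  probs <- seq(0, 1, length.out = n_points)
  qs <- vapply(samples, function(s) {
    v <- sample_values(s)
    if (length(v) < 2) stop("each sample needs at least 2 values")
    stats::quantile(v, probs = probs, type = 7, names = FALSE)
  }, numeric(n_points))
  grid <- rowMeans(qs)
  structure(list(n_points = n_points, probs = probs, grid = grid),
            class = "quantile_reference")
}

#' Scaled quantile normalization of one sample
#'
#' Replaces each value by the reference quantile at the value's own
#' fractional rank within its sample (ties share the mean rank; linear
#' interpolation on the reference grid). Within-sample rank order is
#' preserved; the output distribution matches the reference.
#'
#' @param sample a `normalized_sample` object or numeric vector with at
#'   least 2 values.
#' @param ref a [build_quantile_reference()] result.
#' @return Same shape as `sample`, with values mapped onto the reference.
#' @export
scaled_quantile_normalize <- function(sample, ref) {
  stopifnot(inherits(ref, "quantile_reference"))
  if (inherits(sample, "locus_records")) {
    sample$records$value <- scaled_quantile_normalize(sample$records$value, ref)
    return(sample)
  }
  n <- length(sample)
  if (n < 2) stop("sample needs at least 2 values")
  r <- rank(sample, ties.method = "average")
  p <- (r - 1) / (n - 1)
  stats::approx(ref$probs, ref$grid, xout = p, rule = 2, ties = "ordered")$y
}
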