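# Independent oracles, deliberately implemented apart from the package's
# own code paths.

# Hypergeometric upper tail by direct summation of counting terms.
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Literal enumeration over all size-n draws from N items of which K are
# flagged (tiny N only); cross-validates hyper_tail_oracle itself.
hyper_tail_enumeration <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  flagged <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% flagged) >= k))
}

# Classical full-vector quantile normalization at equal lengths, no ties.
classical_qn <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  apply(mat, 2, function(col) ref[rank(col)])
}
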