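# Independent brute-force oracles, deliberately written as plain loops
# so they share no code path with the implementation they check.

hamming_oracle <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) d <- d + 1L
  d
}

majority_oracle <- function(m, tie_vector) {
  out <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    ones <- 0L
    for (i in seq_len(nrow(m))) if (m[i, j] == 1L) ones <- ones + 1L
    zeros <- nrow(m) - ones
    out[j] <- if (ones > zeros) 1L else if (ones < zeros) 0L
    else tie_vector[j]
  }
  out
}

# all length-n binary vectors, as rows
all_bitvectors <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# bin-histogram transit oracle: counts per bin by explicit looping
bin_counts_oracle <- function(t, t0, bin_us, n_bins) {
  counts <- integer(n_bins)
  for (ti in t) {
    b <- (ti - t0) %/% bin_us + 1
    if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
  }
  counts
}
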