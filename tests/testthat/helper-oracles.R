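# Independent oracles shared by the unit and acceptance suites. These stay
# deliberately naive: per-base enumeration for binned coverage, and direct
# combinatorial summation for hypergeometric tails.

# Per-base brute-force average of piecewise-constant coverage over window
# bins, with the same cpm/log2 normalization and strand flip as the
# implementation under test.
oracle_signal <- function(track, windows) {
  iv <- track$intervals
  out <- matrix(0, nrow(windows), windows$bins[1],
                dimnames = list(windows$transcript_id, NULL))
  for (w in seq_len(nrow(windows))) {
    civ <- iv[iv$chrom == windows$chrom[w], , drop = FALSE]
    bw <- windows$bin_size[w]
    for (b in seq_len(windows$bins[w])) {
      bs <- windows$window_start[w] + (b - 1) * bw
      vals <- numeric(bw)
      for (o in seq_len(bw)) {
        pos <- bs + o - 1
        if (pos >= 0) {
          hit <- which(civ$start <= pos & civ$end > pos)
          if (length(hit)) vals[o] <- civ$value[hit[1]]
        }
      }
      out[w, b] <- mean(vals)
    }
    if (windows$strand[w] == "-") out[w, ] <- rev(out[w, ])
  }
  log2(1 + out * 1e6 / track$library_size)
}

random_track <- function(n_iv = 40, span = 4000, seed = 1) {
  set.seed(seed)
  bounds <- sort(sample(0:span, n_iv + 1))
  keep <- diff(bounds) > 0
  data.frame(chrom = "chr1", start = bounds[-length(bounds)][keep],
             end = bounds[-1][keep],
             value = round(stats::runif(sum(keep), 0, 5), 3))
}

# P(X >= k) for X ~ Hypergeometric(N, K, n) by direct summation
enum_hyper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
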