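# Brute-force oracles, written independently of the package internals
# they check.

# Largest empty interval between consecutive sorted unique values,
# restricted to [lo, hi]; literal double loop over ordered pairs.
brute_gap <- function(x, lo = -Inf, hi = Inf) {
  x <- sort(unique(x[x >= lo & x <= hi]))
  if (length(x) < 2) return(0)
  best <- 0
  for (i in seq_len(length(x) - 1)) {
    g <- x[i + 1] - x[i]
    if (g > best) best <- g
  }
  best
}

# Weighted band means read straight off a distribution's support and
# probabilities by splitting at the notch midpoint.
brute_band_means <- function(dist) {
  mid <- mean(dist$notch)
  lo <- dist$support < mid
  c(sum(dist$support[lo] * dist$probabilities[lo]) / sum(dist$probabilities[lo]),
    sum(dist$support[!lo] * dist$probabilities[!lo]) / sum(dist$probabilities[!lo]))
}

# Literal odd-one-out rule: summed absolute distance to the other two.
brute_oddity <- function(stats) {
  d <- c(abs(stats[1] - stats[2]) + abs(stats[1] - stats[3]),
         abs(stats[2] - stats[1]) + abs(stats[2] - stats[3]),
         abs(stats[3] - stats[1]) + abs(stats[3] - stats[2]))
  which(d >= max(d) - 1e-12)
}

# Test-double observer that reads the trial's ground truth; an upper
# bound on achievable accuracy, never a perceptual model.
omniscient_observer <- function() {
  observer_model("omniscient", function(trial) {
    if (trial$task == "oddity") trial$odd_index else trial$dmax_direction
  }, needs = "trial")
}
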