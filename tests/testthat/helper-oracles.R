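# Brute-force step-up FDR oracle: q_i = min over {j : p_j >= p_i} of
# m * p_j / rank_j, clipped at 1. Kept independent of the implementation.
brute_force_stepup <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_along(p), function(i) {
    keep <- p >= p[i]
    min(1, min(m * p[keep] / r[keep]))
  }, numeric(1))
}
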