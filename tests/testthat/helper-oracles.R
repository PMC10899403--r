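# Brute-force oracles kept deliberately independent of the implementations
# they check.

# Naive O(m^2) Benjamini-Hochberg step-up: the adjusted value of the i-th
# p-value is min over j >= rank(i) of p_(j) * m / j, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)
    cand <- vapply(seq(k, m), function(j) p[ord[j]] * m / j, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}
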