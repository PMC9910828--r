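# Independent brute-force oracles shared across test files.

# Exact two-sided signed-rank p over all 2^n sign assignments.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(Ws <= W_obs)
  p_ge <- mean(Ws >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}
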