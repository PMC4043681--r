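# Independent brute-force oracles for the rank statistics. These enumerate
# the exact null distributions directly and share no code with the
# implementation under test.

# exact two-sided Mann-Whitney p by enumerating all C(m+n, m) labelings
brute_force_mw_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  mu <- m * n / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
brute_force_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}
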