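# Independent brute-force oracles for the statistical kernel. These stay
# deliberately naive (loops, direct definitions) so they share no code path
# with the implementations they check.

oracle_avg_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

oracle_spearman_r <- function(x, y) {
  rx <- oracle_avg_ranks(x)
  ry <- oracle_avg_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_mk_S <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

oracle_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

oracle_pw <- function(no2, pop) {
  s <- 0; w <- 0
  for (i in seq_along(no2)) {
    s <- s + no2[i] * pop[i]
    w <- w + pop[i]
  }
  s / w
}
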