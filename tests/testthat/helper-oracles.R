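# Independent reference implementations used as oracles. These evaluate the
# published formulas directly in R, separately from the package's compiled
# path, so the two routes can be compared.

oracle_bws_B <- function(control, case) {
  n1 <- length(control); n2 <- length(case); N <- n1 + n2
  r <- rank(c(control, case), ties.method = "average")
  G <- sort(r[seq_len(n1)])
  H <- sort(r[-seq_len(n1)])
  comp <- function(R, na, nb) {
    i <- seq_len(na)
    d <- R - (N / na) * i
    mean(d * abs(d) / ((i / (na + 1)) * (1 - i / (na + 1)) * (nb * N / na)))
  }
  (comp(G, n1, n2) - comp(H, n2, n1)) / 2
}

# Exhaustive permutation p-value of D = -B (small samples only):
# Pr(D_perm >= D_obs) over all C(N, n1) label assignments.
oracle_perm_p_right <- function(control, case) {
  pooled <- c(control, case)
  N <- length(pooled); n1 <- length(control)
  D_obs <- -oracle_bws_B(control, case)
  splits <- utils::combn(N, n1)
  Ds <- apply(splits, 2, function(idx)
    -oracle_bws_B(pooled[idx], pooled[-idx]))
  mean(Ds >= D_obs - 1e-12)
}

# Closed-form mean of a truncated normal on (lo, hi).
oracle_truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

make_strata <- function(K, n1 = 20, n2 = 20, shift = 0, gen = rnorm) {
  lapply(seq_len(K), function(k)
    list(control = gen(n1), case = gen(n2) + shift))
}
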