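# Independent single-expression oracles for every mass-balance and kinetic
# formula, plus brute-force enumeration oracles for the rank-based tests.
# These are kept deliberately separate from the package implementations.

oracle_daily_hd <- function(V, D, n, UE) (V * D * n) / 7 + UE
oracle_daily_ctrl <- function(V, U) V * U
oracle_session <- function(V, D) V * D
oracle_ktv <- function(R, t, UF, W) -log(R - 0.008 * t) + (4 - 3.5 * R) * UF / W
oracle_intake_hd <- function(V, Du, n, UUE, BW, UPE) {
  6.25 * (0.028 * ((V * Du * n) / 7 + UUE) + 0.031 * BW) + UPE
}
oracle_intake_ctrl <- function(UUE, BW, UPE) 6.25 * (0.028 * UUE + 0.031 * BW) + UPE
oracle_clearance <- function(V, D, T, Ppre, Ppost) {
  ((V * D) / T) / ((Ppre + Ppost) / 2) * (1000 / 60)
}
oracle_fractional <- function(cl, cl_cr) cl / cl_cr * 100

# exact two-sided p of the rank-sum statistic by full enumeration of the
# choose(n_a + n_b, n_a) group assignments (small n, no ties)
perm_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2 # Mann-Whitney U of group a
  idx <- utils::combn(length(pooled), n_a)
  us <- apply(idx, 2, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  mu <- n_a * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# exact two-sided p of the signed-rank statistic by 2^n sign-flip enumeration
signflip_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mean(abs(vs - mu) >= abs(obs - mu) - 1e-12)
}

# contingency-table cross-product odds ratio
crossprod_or <- function(x, y) {
  tab <- table(factor(x, c(0, 1)), factor(y, c(FALSE, TRUE)))
  (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
}

# small deterministic cohort for structural tests
tiny_cohort <- function(seed = 42, n_hd = 20, n_ctrl = 12) {
  generate_cohort(default_config(n_hd = n_hd, n_ctrl = n_ctrl, seed = seed))
}
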