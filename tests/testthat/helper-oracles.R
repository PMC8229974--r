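# Independent brute-force oracles used to check the statistical routines.
# These deliberately use different routes than the package implementation.

# Spearman rho through the classic difference formula (tie-free data only)
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Mann-Whitney U for group a by direct pairwise counting
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) u <- u + sum(ai > b) + 0.5 * sum(ai == b)
  u
}

# exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values into groups of sizes n1/n2, with U from pairwise counting
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# two-sided Fisher p by enumerating all tables with the observed margins,
# with probabilities from binomial coefficients (no dhyper)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  p_of <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(as, p_of, numeric(1))
  p_obs <- p_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# three standard-error binomial tolerance
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)

make_amplicon <- function(n_cpg = 6L, seed = 42L, ...) {
  synthetic_amplicon(sprintf("amp%d", n_cpg), n_cpg = n_cpg, seed = seed, ...)
}
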