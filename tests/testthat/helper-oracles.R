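# Independent brute-force oracles used to cross-check the package's
# statistical wrappers. These deliberately avoid stats::p.adjust,
# stats::fisher.test and stats::binom.test.

# Literal Benjamini-Hochberg step-up: for the i-th smallest p, the adjusted
# value is min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) sorted[j] * m / j, numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric probability of a 2x2 table via binomial coefficients only.
table_prob <- function(a, b, c, d) {
  n <- a + b + c + d
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(n, a + c))
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins: sum the probabilities of tables no more probable than the observed
# one (relative tie tolerance 1e-7).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) table_prob(k, r1 - k, c1 - k, n - r1 - c1 + k),
                  numeric(1))
  obs <- table_prob(a, b, c, d)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Exact two-sided binomial p by enumeration of the probability mass function.
binom_two_sided_oracle <- function(k, n, p0 = 0.5) {
  mass <- vapply(0:n, function(i) {
    exp(lchoose(n, i) + i * log(p0) + (n - i) * log(1 - p0))
  }, numeric(1))
  obs <- mass[k + 1]
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}
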