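# Independent oracles used across the test suite.

# Closed-form log marginal likelihood of a segment under the
# Normal-Inverse-Gamma prior (prior mean m0, pseudo-count k0 = nu0,
# prior scale^2 s0sq). Computed from the NIG normalizing constants,
# independently of the package's sequential predictive chain.
nig_log_marginal <- function(x, m0 = 0, k0 = 1, nu0 = 1, s0sq = 1) {
  n <- length(x)
  if (n == 0L) return(0)
  a0 <- nu0 / 2; b0 <- nu0 * s0sq / 2
  kn <- k0 + n
  an <- a0 + n / 2
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  bn <- b0 + ss / 2 + k0 * n * (xbar - m0)^2 / (2 * kn)
  lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(k0) - log(kn)) - n / 2 * log(2 * pi)
}

# Exhaustive changepoint-pattern posterior for a short sequence:
# enumerate all 2^(t-1) changepoint patterns (a change may precede each
# observation after the first), weight each by hazard prior x product of
# per-segment marginal likelihoods, and return, for each time t, the
# posterior probability over the current context length c = 1..t.
oracle_beliefs <- function(x, hazard, m0 = 0, k0 = 1, nu0 = 1, s0sq = 1) {
  n <- length(x)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    xt <- x[seq_len(t)]
    b <- numeric(t)
    n_pat <- 2^(t - 1)
    for (pat in 0:(n_pat - 1)) {
      cps <- if (t >= 2) which(bitwAnd(pat, 2^(0:(t - 2))) > 0) + 1L
             else integer(0)
      starts <- c(1L, cps)
      ends <- c(cps - 1L, t)
      logw <- length(cps) * log(hazard) +
        (t - 1 - length(cps)) * log(1 - hazard)
      for (s in seq_along(starts)) {
        logw <- logw + nig_log_marginal(xt[starts[s]:ends[s]],
                                        m0, k0, nu0, s0sq)
      }
      clen <- t - max(starts) + 1L
      b[clen] <- b[clen] + exp(logw)
    }
    out[[t]] <- b / sum(b)
  }
  out
}

# Quadrature oracle for the one-step posterior predictive under the NIG
# prior: integrate Normal(x; mn, s2 * (1 + 1/kn)) over the Inverse-Gamma
# posterior of s2 numerically.
nig_predictive_quadrature <- function(x, data, m0 = 0, k0 = 1, nu0 = 1,
                                      s0sq = 1) {
  n <- length(data)
  a0 <- nu0 / 2; b0 <- nu0 * s0sq / 2
  kn <- k0 + n
  an <- a0 + n / 2
  mn <- (k0 * m0 + sum(data)) / kn
  ss <- if (n > 0) sum((data - mean(data))^2) else 0
  bn <- b0 + ss / 2 +
    if (n > 0) k0 * n * (mean(data) - m0)^2 / (2 * kn) else 0
  dig <- function(s2) bn^an / gamma(an) * s2^(-an - 1) * exp(-bn / s2)
  f <- function(s2) stats::dnorm(x, mn, sqrt(s2 * (1 + 1 / kn))) * dig(s2)
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# Direct Jensen-Shannon divergence from its definition.
js_direct <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Random probability vector.
rand_simplex <- function(k) {
  v <- stats::rexp(k)
  v / sum(v)
}
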