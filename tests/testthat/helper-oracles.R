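# Independent brute-force oracles used to check the statistical routes.
# These never call the implementation under test.

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's
fisher_2x2_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(1)
  }
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# two-sided binomial p against 0.5 by minimum-likelihood tail summation
binom_twosided_oracle <- function(a, b) {
  n <- a + b
  probs <- stats::dbinom(0:n, n, 0.5)
  obs <- probs[a + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# exact HWE p by normalising the unconditional multinomial over all
# genotype configurations compatible with the observed allele counts
hwe_oracle <- function(hom_a, het, hom_b) {
  n <- hom_a + het + hom_b
  n_a <- 2 * hom_a + het
  if (n_a == 0 || 2 * n - n_a == 0) {
    return(1)
  }
  p <- n_a / (2 * n)
  hets <- seq(min(n_a, 2 * n - n_a) %% 2, min(n_a, 2 * n - n_a), by = 2)
  probs <- vapply(hets, function(h) {
    stats::dmultinom(c((n_a - h) / 2, h, n - (n_a + h) / 2),
                     prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[match(het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Clopper-Pearson bounds by bisection on the binomial tail probabilities
clopper_pearson_oracle <- function(k, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  bisect <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (k == 0) 0 else
    bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) < alpha)
  high <- if (k == n) 1 else
    bisect(function(p) stats::pbinom(k, n, p) >= alpha)
  c(low, high)
}
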