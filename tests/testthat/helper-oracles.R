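# Independent oracles used across the suite. These deliberately avoid the
# package's separable-kernel code path: the sampling kernel is enumerated
# term by term from its double-sum definition, OLS is solved via the normal
# equations, and waiting times are measured on a per-cell simulator.

# Brute-force enumeration of the unnormalized sampling kernel theta.
enumerate_theta_raw <- function(freqs, params, omega) {
  n <- params$n; m <- params$m; mu <- params$mu
  raw <- matrix(0, n + 1, m + 1)
  for (k in 0:n) for (l in 0:m) {
    acc <- 0
    for (i in 0:k) for (j in 0:l) {
      surv <- if (params$survival_exponent == "as_printed")
        (1 - mu)^(n - i + m - j) else (1 - mu)^((n - k) + (m - l))
      w <- if (params$fitness_weighting == "offspring")
        omega[k + 1, l + 1] else omega[i + 1, j + 1]
      acc <- acc + choose(n - i, k - i) * choose(m - j, l - j) *
        mu^(k - i + l - j) * surv * w * freqs[i + 1, j + 1]
    }
    raw[k + 1, l + 1] <- acc
  }
  raw
}

ols_normal_equations <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Two-sample chi-square homogeneity test on quantile-binned counts.
two_sample_chisq_p <- function(a, b, nbins = 6) {
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  brk <- unique(stats::quantile(pooled, seq(0, 1, length.out = nbins + 1)))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  ta <- table(cut(a, brk)); tb <- table(cut(b, brk))
  keep <- (ta + tb) > 0
  suppressWarnings(stats::chisq.test(rbind(ta[keep], tb[keep]))$p.value)
}

# Small mixed-clone state on the tiny (n = 1, m = 2) genotype grid.
tiny_mixed_state <- function(params) {
  counts <- matrix(0, params$n + 1, params$m + 1)
  counts[1, 1] <- 120; counts[2, 1] <- 50; counts[1, 2] <- 30
  population_state(counts, 0L, params)
}

# First generation at which clone (k, l) is populated, per-cell simulation.
oracle_first_hit <- function(params, k, l, max_t = params$T) {
  st <- initial_state(params)
  for (t in seq_len(max_t)) {
    st <- oracle_step(st, params)
    if (st$counts[k + 1, l + 1] > 0) return(t)
  }
  NA_real_
}

tiny_oracle_params <- function() {
  model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
               N0 = 200, NT = 200, T = 20)
}
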