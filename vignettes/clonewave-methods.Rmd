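---
title: "clonewave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonewave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`clonewave` simulates tumor progression as a discrete-generation
Wright-Fisher process with two classes of beneficial mutations. A cell's
genotype is summarized by the pair $(k, \ell)$: the number of mutated
*superdriver* loci (out of $n = 10$) and mutated *driver* loci (out of
$m = 100$). Drivers confer a selective advantage $s \in [0, 1]$ each;
superdrivers are rare, potent drivers — think *TP53* point mutations or
*EGFR* amplifications — with advantage $r = c\,s$, $c \ge 1$. Fitness
effects multiply, so a $(k, \ell)$ cell has relative fitness

$$\omega_{k\ell} =
  \frac{(1+r)^k (1+s)^\ell}{\sum_{i,j} (1+r)^i (1+s)^j x_{ij}},$$

where $x_{ij}$ is the frequency of clone $(i, j)$; the denominator is the
population mean fitness, so the frequency-weighted mean of $\omega$ is
exactly 1 at every generation (asserted to $10^{-10}$ in the tests).

The population grows deterministically from $N(0) = 10^6$ to
$N(T) = 10^9$ cells over $T = 4500$ generations (about 12 years at one
division per day), multiplied each generation by
$\alpha = \exp[\log(N(T)/N(0))/T]$. Each new generation is an exact
multinomial resample of $N(t+1)$ cells with clone probabilities

$$\theta_{k\ell} = \sum_{i=0}^{k}\sum_{j=0}^{\ell}
  \binom{n-i}{k-i}\binom{m-j}{\ell-j}
  \mu^{k-i+\ell-j}(1-\mu)^{n-i+m-j}\,\omega_{k\ell}\,x_{ij},$$

with per-gene mutation probability $\mu = 10^{-8}$ and no back mutation.
The binomial coefficients vanish for $k < i$ or beyond the locus caps, so
$n$ and $m$ bound the genotype space without extra logic.

### Numerical and interpretation choices

* **Size schedule.** Rather than multiplying $N(t)$ by $\alpha$ and
  rounding each step, the schedule $N(t) = \mathrm{round}(N_0\alpha^t)$ is
  precomputed. This avoids cumulative rounding drift and makes
  $N(T) = N(T)$ exact at both ends.
* **Kernel normalization.** The $\theta$ kernel above is not an exact
  probability distribution (its total differs from 1 by $O((n+m)\mu)$;
  about $2\times10^{-4}$ on the small test preset with $\mu = 10^{-3}$).
  It is renormalized before the multinomial draw and the raw sum is kept
  (`sampling_distribution()$raw_sum`).
* **Two kernel switches.** The formula weights a mutation transition
  $(i,j)\to(k,\ell)$ by the *offspring* fitness $\omega_{k\ell}$ and uses
  the parent-indexed survival exponent $(1-\mu)^{n-i+m-j}$. A per-cell
  mechanistic reading (reproduce, then mutate each free locus) would use
  the *parent* fitness $\omega_{ij}$ and the offspring-indexed exponent
  $(1-\mu)^{(n-k)+(m-\ell)}$. Both variants are implemented
  (`fitness_weighting`, `survival_exponent` in `model_params()`); the
  defaults are the formula as displayed above. At default parameters the
  variants differ by $O(\mu s)$ — far below Monte-Carlo resolution, as the
  oracle-equivalence test demonstrates.
* **Separable evaluation.** The double sum factorizes into two
  lower-triangular per-class kernels, so $\theta$ is computed as
  $A X B^\top$ (matrix products of size $11\times11$ and
  $101\times101$) rather than a quadruple loop. The test suite checks this
  against a term-by-term enumeration oracle.
* **Sampling at $N = 10^9$.** `rmultinom()` draws exact multinomials for
  totals up to $2^{31}-1$, which covers the default final size; counts are
  stored as doubles.
* **Per-cell oracle.** `oracle_step()` simulates the identical update cell
  by cell (parent sampled with probability $\omega_{ij}x_{ij}$, then
  per-locus Bernoulli mutation) and is restricted to $N \le 10^5$. It is
  the independent check on the multinomial path: a two-sample chi-square
  per clone (quantile-binned counts, $\alpha = 0.01$, 500 draws per arm,
  fixed seeds) accepts homogeneity.

## Replicate ensembles and the parameter grid

`run_ensemble()` averages clone counts across independent replicates
(default 50); per-replicate seeds are derived deterministically from a
master seed and recorded, so any replicate can be replayed alone. Because
the size schedule is deterministic, mean frequencies are mean counts
divided by $N(t)$.

`grid_spec()` defaults to the study design:
$s \in \{0.005, 0.01, 0.02, 0.03, 0.04, 0.05\}$ and $c$ spanning 1–3. The
original $c$ grid is stated as "1, 1.1, 1.3, …, 3" with named values 1.1,
1.3, 1.5, 2.6, 2.8, 3.0; the shipped default
$\{1.0, 1.1, 1.3, 1.5, 1.7, 1.9, 2.1, 2.3, 2.6, 2.8, 3.0\}$ covers the
range, includes every named value, and is fully overridable.

## Waiting times

The expected generation at which the first $(k, \ell)$ cell appears is
approximated by decoupling the two classes and summing their
traveling-wave waiting times:

$$T_k^S \approx \frac{k\,\log^2[r/(\mu n)]}{r\,\log[N(T)\,N(0)]},\qquad
  T_\ell^D \approx \frac{\ell\,\log^2[s/(\mu m)]}{s\,\log[N(T)\,N(0)]},\qquad
  \tau_{k\ell} \approx T_k^S + T_\ell^D.$$

All logarithms are natural. The population-size term is implemented as the
product $N(T)N(0)$ as displayed; because a ratio $N(T)/N(0)$ is a
plausible intended reading, `size_log_arg = "ratio"` switches to it.

**Event definition.** The empirical waiting time is the first generation at
which the *exact* clone $(k, \ell)$ holds at least one cell
(`at_least = TRUE` switches to the cumulative event
$\sum_{i \ge k, j \ge \ell} N_{ij} \ge 1$, which can only be earlier).
Replicates that never reach the clone by $T$ are censored: they are
excluded from the mean and counted, and residual-table rows with more than
50% censoring are excluded from regressions.

**Where the approximation applies.** The formula prices each successive
class at the establishment-paced interval of a traveling wave. The very
first single-mutant, however, is produced directly by the large initial
population at rate $\approx N_0\mu n$ per generation — within a few
generations at default sizes — so for $(1, 0)$ and $(0, 1)$ the formula
overestimates grossly. From $k, \ell \ge 1$ onward the approximation
tracks simulation well (relative deviation $\lesssim 0.35$ for
$k, \ell \le 2$ at $s = 0.01$, $c = 2$) and systematically
*underestimates*, increasingly so for larger $k + \ell$. Concordance
checks therefore evaluate $k, \ell \in \{1, 2\}$, matching the ranges the
residual analysis uses ($k = 1\ldots6$, $\ell = 1\ldots10$).

**Residual regressions.** `fit_error_model()` regresses the residual
$\varepsilon = \tau_{\text{sim}} - \tau_{\text{approx}}$ on an intercept
plus either $(s, r, k, \ell)$ or $(s, c, k, \ell)$ with $c = r/s$,
reporting coefficients, standard errors, standardized coefficients,
adjusted $R^2$ and the overall $F$ test. Designs that are rank-deficient
(e.g. a single $s$ value makes $r = cs$ collinear) are rejected with the
aliased columns named. At the full study scale these regressions reach
adjusted $R^2 \approx 0.77$–$0.78$; the package's test suite exercises a
scaled design (2 $s$-values $\times$ 3 $c$-values, 3 replicates) chosen to
span the $s$ range, which runs in under a minute and yields full-rank fits
with adjusted $R^2 \approx 0.6$–$0.75$. At that scale the *absolute*
residual in fact shrinks with $s$ at fixed $(k, \ell)$ (the relative gap
grows), so standardized-coefficient rankings involving $s$ are
scale-sensitive; the full-grid ranking is only reproducible at full scale
(hours of CPU), which `run_grid()` supports but the tests do not run.

## Traveling-wave analysis

Clone abundance pulses are detected per clone as maximal contiguous runs
of generations with abundance at or above a threshold; the default is
frequency 0.01 (1% of the population), configurable, since no canonical
threshold exists. From the detected segments the package computes the four
wave statistics: number of driver waves within a superdriver class
(operationalized as the number of driver classes $\ell \le 10$ with at
least one detected wave at fixed $k$), wave widths (spans at least 500
generations by default), absolute height differences of consecutive driver
waves within a superdriver class, and peak spacings of consecutive
superdriver waves at fixed $\ell$.

Quadratic polynomials are fitted to each wave by least squares on the
natural log of abundance: a Gaussian pulse is exactly parabolic in log
space, so the vertex gives the wave's location, its height (log
frequency), and the second-order coefficient its curvature
$-1/(2\sigma^2)$. Fits with non-negative curvature or a vertex outside the
segment (e.g. monotone edge episodes) are flagged rejected. Linear-scale
fits are available via `scale = "linear"`. Generation indices are 0-based
throughout; wave tables report inclusive bounds.

## What the generator does and does not emulate

The simulator *is* the data generator for every analysis: there is no
external data. Small-parameter presets (`make_fixture()`) provide fast,
deterministic instances for testing — a neutral model, a mutation-heavy
tiny model matched to the per-cell oracle's feasible size, a constructed
two-Gaussian series with known peaks, heights and crossing points, and a
shortened default-parameter run. Passing tests on these presets establish
the machinery (kernel arithmetic, scheduling, detection geometry,
regression algebra) and the scaled-replicate runs establish the
qualitative dynamics; they do not establish biological realism. The model
ignores deleterious and passenger mutations, mutator phenotypes, epistasis,
spatial structure, and continuous-time effects, and treats $s$ and $c$ as
constants rather than draws from a fitness distribution.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use: replicate ensembles of
R = 5 at $(s, c) = (0.01, 2)$, $(0.01, 1.1)$ and $(0.01, 3)$ for the
succession and wave-direction checks; R = 10 at $(0.01, 2)$ for
waiting-time concordance; and the scaled grid above for the regressions.
Each full-length trajectory (T = 4500, $N$ up to $10^9$) takes roughly
2–3 seconds, so the whole battery completes in a few minutes on one CPU.
The full study design (6 × 11 grid, R = 50) is available through
`run_grid()` or the `grid` CLI subcommand and takes a few CPU-hours.
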