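#' Population state of the two-class Wright-Fisher model
#'
#' A snapshot of the cell population at one generation: the
#' `(n + 1) x (m + 1)` matrix of absolute clone counts `N_kl`, where rows
#' index superdriver counts `k = 0..n` and columns driver counts `l = 0..m`.
#'
#' @param counts Non-negative count matrix, dimensions `(n + 1) x (m + 1)`.
#' @param t Generation index, integer `>= 0`.
#' @param params A [model_params()] object (used to validate dimensions).
#' @return Object of class `clonewave_state`: list with `t`, `counts`,
#'   `total` (= `sum(counts)`) and `freqs` (= `counts / total`).
#' @examples
#' p <- model_params(n = 1, m = 2, N0 = 100, NT = 100, T = 5)
#' st <- initial_state(p)
#' st$freqs[1, 1]   # all mass on the wild type (0, 0)
#' @export
population_state <- function(counts, t, params) {
  stopifnot(inherits(params, "clonewave_params"))
  if (!is.matrix(counts) ||
      !identical(dim(counts), c(params$n + 1L, params$m + 1L)))
    stop(sprintf("counts must be a %d x %d matrix", params$n + 1, params$m + 1),
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("population is extinct (total count 0)", call. = FALSE)
  if (t < 0 || t != round(t)) stop("t must be an integer >= 0", call. = FALSE)
  structure(list(t = as.integer(t), counts = counts, total = total,
                 freqs = counts / total),
            class = "clonewave_state")
}

#' @rdname population_state
#' @export
initial_state <- function(params) {
  counts <- matrix(0, params$n + 1L, params$m + 1L)
  counts[1, 1] <- size_schedule(params)[1]
  population_state(counts, 0L, params)
}

#' @export
print.clonewave_state <- function(x, ...) {
  occ <- which(x$counts > 0, arr.ind = TRUE)
  cat(sprintf("Population state at generation %d: %g cells, %d occupied clone(s)\n",
              x$t, x$total, nrow(occ)))
  show <- utils::head(order(-x$counts[occ]), 8)
  for (i in show)
    cat(sprintf("  clone (k=%d, l=%d): %g cells (%.3g)\n",
                occ[i, 1] - 1, occ[i, 2] - 1, x$counts[occ][i],
                x$freqs[occ][i]))
  invisible(x)
}

#' Relative fitness of every clone
#'
#' Fitness effects are multiplicative: a cell with `k` superdrivers and `l`
#' drivers has unnormalized fitness `(1 + r)^k * (1 + s)^l`. Dividing by the
#' population mean fitness `sum_ij (1 + r)^i (1 + s)^j x_ij` gives the
#' relative fitness `omega_kl`, so that the frequency-weighted mean of
#' `omega` is exactly 1.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] object.
#' @return Object of class `clonewave_fitness`: list with `omega`
#'   (`(n + 1) x (m + 1)` matrix) and `mean_fitness` (the normalizing
#'   denominator).
#' @examples
#' p <- model_params(n = 1, m = 1, s = 0.1, c = 2, N0 = 10, NT = 10, T = 1)
#' st <- initial_state(p)
#' relative_fitness(st, p)$omega
#' @export
relative_fitness <- function(state, params) {
  stopifnot(inherits(state, "clonewave_state"),
            inherits(params, "clonewave_params"))
  if (!identical(dim(state$counts), c(params$n + 1L, params$m + 1L)))
    stop("state dimensions do not match params", call. = FALSE)
  Wnum <- outer((1 + params$r)^(0:params$n), (1 + params$s)^(0:params$m))
  mf <- sum(Wnum * state$freqs)
  structure(list(omega = Wnum / mf, mean_fitness = mf),
            class = "clonewave_fitness")
}

#' Offspring sampling distribution with mutation and selection
#'
#' The probability that a cell sampled for the next generation belongs to
#' clone `(k, l)`: parents `(i, j)` with `i <= k`, `j <= l` contribute via
#' binomial per-locus mutation,
#' `theta_kl = sum_ij C(n-i, k-i) C(m-j, l-j) mu^(k-i+l-j) (1-mu)^(n-i+m-j)
#' omega_kl x_ij` (with the fitness-weighting and survival-exponent variants
#' selected in `params`). The raw kernel is not an exact probability
#' distribution; it is renormalized to sum to 1 and the raw sum (deficit
#' `O((n + m) mu)`) is preserved.
#'
#' @param state A [population_state()].
#' @param fitness The [relative_fitness()] of `state`; computed if `NULL`.
#' @param params A [model_params()] object.
#' @return Object of class `clonewave_sampling`: list with `theta`
#'   (renormalized, sums to 1) and `raw_sum`.
#' @export
sampling_distribution <- function(state, fitness = NULL, params) {
  stopifnot(inherits(state, "clonewave_state"),
            inherits(params, "clonewave_params"))
  if (is.null(fitness)) fitness <- relative_fitness(state, params)
  ker <- model_kernels(params)
  raw <- theta_raw(state$freqs, fitness$omega, ker, params$fitness_weighting)
  rs <- sum(raw)
  structure(list(theta = raw / rs, raw_sum = rs), class = "clonewave_sampling")
}

# Unnormalized theta via the separable kernel: the double sum over parents
# factorizes into A %*% X %*% t(B) with per-class lower-triangular kernels.
theta_raw <- function(freqs, omega, ker, fitness_weighting) {
  if (fitness_weighting == "offspring") {
    omega * (ker$A %*% freqs %*% ker$Bt)
  } else {
    ker$A %*% (omega * freqs) %*% ker$Bt
  }
}

#' One Wright-Fisher generation update
#'
#' Draws the next generation's clone counts from an exact multinomial with
#' total equal to the scheduled population size `N(t + 1)` and cell
#' probabilities given by [sampling_distribution()]. Uses the current R
#' random stream; seed it with [set.seed()] for reproducibility.
#'
#' @param state A [population_state()] at generation `t < T`.
#' @param params A [model_params()] object.
#' @return The [population_state()] at generation `t + 1`.
#' @examples
#' p <- model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
#'                   N0 = 200, NT = 200, T = 20)
#' set.seed(1)
#' wf_step(initial_state(p), p)
#' @export
wf_step <- function(state, params) {
  stopifnot(inherits(state, "clonewave_state"),
            inherits(params, "clonewave_params"))
  if (state$t >= params$T)
    stop("state is already at the final generation T", call. = FALSE)
  sched <- size_schedule(params)
  samp <- sampling_distribution(state, NULL, params)
  counts <- draw_multinomial(sched[state$t + 2L], samp$theta)
  population_state(counts, state$t + 1L, params)
}

# Exact multinomial draw reshaped to the clone grid. rmultinom supports
# totals up to .Machine$integer.max (2^31 - 1), which covers NT = 1e9.
draw_multinomial <- function(total, theta) {
  if (total > .Machine$integer.max)
    stop("population size exceeds multinomial sampler limit (2^31 - 1)",
         call. = FALSE)
  matrix(as.numeric(stats::rmultinom(1, total, as.vector(theta))),
         nrow(theta), ncol(theta))
}

#' Per-cell brute-force generation update (test oracle)
#'
#' Simulates the same generation update cell by cell, without the
#' multinomial shortcut: each offspring independently picks a parent clone
#' with probability `omega_ij * x_ij`, then mutates each of its unmutated
#' superdriver and driver loci independently with probability `mu`.
#' Deliberately slow and restricted to small populations; used to validate
#' [wf_step()] distributionally.
#'
#' @param state A [population_state()] with `total <= 1e5`.
#' @param params A [model_params()] object.
#' @return The [population_state()] at generation `t + 1`.
#' @export
oracle_step <- function(state, params) {
  stopifnot(inherits(state, "clonewave_state"),
            inherits(params, "clonewave_params"))
  if (state$total > 1e5)
    stop("oracle_step is a brute-force oracle; total must be <= 1e5",
         call. = FALSE)
  if (state$t >= params$T)
    stop("state is already at the final generation T", call. = FALSE)
  total_next <- size_schedule(params)[state$t + 2L]
  omega <- relative_fitness(state, params)$omega
  nclone <- length(state$counts)
  # omega * x sums to 1 by construction; sample parents per offspring cell
  parent <- sample.int(nclone, total_next, replace = TRUE,
                       prob = as.vector(omega * state$freqs))
  ki <- (parent - 1L) %% (params$n + 1L)          # parent superdriver count
  li <- (parent - 1L) %/% (params$n + 1L)         # parent driver count
  k <- ki + stats::rbinom(total_next, params$n - ki, params$mu)
  l <- li + stats::rbinom(total_next, params$m - li, params$mu)
  counts <- matrix(0, params$n + 1L, params$m + 1L)
  tab <- table(factor(k + (params$n + 1L) * l, levels = 0:(nclone - 1L)))
  counts[] <- as.numeric(tab)
  population_state(counts, state$t + 1L, params)
}

#' Simulate one tumor-progression trajectory
#'
#' Runs the Wright-Fisher process from a monomorphic wild-type population of
#' `N0` cells through `T` generations of mutation, selection and
#' deterministic exponential growth, recording every generation's clone
#' counts.
#'
#' @param params A [model_params()] object.
#' @param seed Integer seed; recorded in the returned object.
#' @return Object of class `clonewave_traj`: list with
#'   \describe{
#'     \item{params, seed}{inputs as given;}
#'     \item{counts}{numeric array `(n + 1) x (m + 1) x (T + 1)`, clone
#'       counts per generation (third index is `t + 1`);}
#'     \item{schedule}{the deterministic population sizes `N(0..T)`;}
#'     \item{first_hit}{`(n + 1) x (m + 1)` matrix: first generation at
#'       which each exact clone had at least one cell (`NA` if never).}
#'   }
#' @examples
#' p <- model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
#'                   N0 = 200, NT = 200, T = 20)
#' tr <- simulate_trajectory(p, seed = 1)
#' tr$counts[, , 21]          # final generation
#' @export
simulate_trajectory <- function(params, seed = 1L) {
  stopifnot(inherits(params, "clonewave_params"))
  set.seed(seed)
  sched <- size_schedule(params)
  ker <- model_kernels(params)
  nr <- params$n + 1L; nc <- params$m + 1L
  X <- matrix(0, nr, nc); X[1, 1] <- sched[1]
  counts <- array(0, c(nr, nc, params$T + 1L))
  counts[, , 1] <- X
  first_hit <- matrix(NA_real_, nr, nc)
  first_hit[1, 1] <- 0
  for (t in seq_len(params$T)) {
    x <- X / sched[t]
    omega <- ker$Wnum / sum(ker$Wnum * x)
    raw <- theta_raw(x, omega, ker, params$fitness_weighting)
    X <- draw_multinomial(sched[t + 1L], raw / sum(raw))
    counts[, , t + 1L] <- X
    newly <- is.na(first_hit) & X > 0
    if (any(newly)) first_hit[newly] <- t
  }
  structure(list(params = params, seed = as.integer(seed), counts = counts,
                 schedule = sched, first_hit = first_hit),
            class = "clonewave_traj")
}

#' @export
print.clonewave_traj <- function(x, ...) {
  cat(sprintf("Wright-Fisher trajectory: T = %d generations, N %g -> %g cells, seed %d\n",
              x$params$T, x$schedule[1], x$schedule[length(x$schedule)],
              x$seed))
  cat(sprintf("  clones ever observed: %d of %d\n", sum(!is.na(x$first_hit)),
              length(x$first_hit)))
  invisible(x)
}

# Generation t slice of a trajectory as a population_state.
state_at <- function(traj, t) {
  population_state(traj$counts[, , t + 1L], t, traj$params)
}
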