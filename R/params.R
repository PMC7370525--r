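#' Model parameters for the two-class Wright-Fisher tumor model
#'
#' Bundles all scalar constants of the model: locus counts, mutation rate,
#' selection coefficients, the deterministic population-size schedule, and
#' two resolution switches for ambiguities in the sampling kernel.
#'
#' Cells are classified by their joint mutation counts `(k, l)`: `k`
#' superdriver mutations out of `n` loci and `l` driver mutations out of
#' `m` loci. Drivers carry selective advantage `s`; superdrivers carry
#' `r = c * s` with `c >= 1`. The population grows deterministically from
#' `N0` to `NT` cells over `T` generations, multiplied each generation by
#' `alpha = exp(log(NT / N0) / T)`.
#'
#' @param n Number of superdriver loci (genotype-space cap on superdriver
#'   mutations per cell).
#' @param m Number of driver loci.
#' @param mu Per-gene, per-generation mutation probability.
#' @param s Driver selective advantage, in `[0, 1]`.
#' @param c Superdriver fitness increase factor, `>= 1`; the superdriver
#'   advantage is derived as `r = c * s`.
#' @param N0 Initial population size (cells).
#' @param NT Final population size (cells).
#' @param T Number of generations simulated.
#' @param fitness_weighting Which clone's relative fitness weights the
#'   sampling probability of an `(i, j) -> (k, l)` mutation transition:
#'   `"offspring"` uses `omega_kl` (the printed form of the kernel),
#'   `"parent"` uses `omega_ij` (the form implied by per-cell reproduction).
#' @param survival_exponent Exponent of the `(1 - mu)` locus-survival factor:
#'   `"as_printed"` uses `(1 - mu)^(n - i + m - j)` (parent-indexed),
#'   `"per_locus"` uses `(1 - mu)^((n - k) + (m - l))` (offspring-indexed,
#'   consistent with independent per-locus mutation). At `mu = 1e-8` the two
#'   differ by less than 1e-6 relative.
#'
#' @return An object of class `clonewave_params`: a list with the arguments
#'   above plus the derived `r = c * s` and `alpha`.
#'
#' @examples
#' p <- model_params()            # defaults: n = 10, m = 100, T = 4500, ...
#' p$alpha^p$T * p$N0             # == p$NT
#' model_params(s = 0.05, c = 3)$r
#' @export
model_params <- function(n = 10, m = 100, mu = 1e-8, s = 0.01, c = 2,
                         N0 = 1e6, NT = 1e9, T = 4500,
                         fitness_weighting = c("offspring", "parent"),
                         survival_exponent = c("as_printed", "per_locus")) {
  fitness_weighting <- match.arg(fitness_weighting)
  survival_exponent <- match.arg(survival_exponent)
  stop_invalid <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  for (nm in c("n", "m", "mu", "s", "c", "N0", "NT", "T")) {
    v <- get(nm)
    stop_invalid(!is.numeric(v) || length(v) != 1 || !is.finite(v),
                 sprintf("'%s' must be a single finite number", nm))
  }
  stop_invalid(n < 1 || n != round(n), "'n' must be an integer >= 1")
  stop_invalid(m < 1 || m != round(m), "'m' must be an integer >= 1")
  stop_invalid(mu < 0 || mu > 1, "'mu' must be in [0, 1]")
  stop_invalid(s < 0 || s > 1, "'s' must be in [0, 1]")
  stop_invalid(c < 1, "'c' must be >= 1")
  stop_invalid(N0 < 1, "'N0' must be >= 1")
  stop_invalid(NT < N0, "'NT' must be >= N0")
  stop_invalid(T < 1 || T != round(T), "'T' must be an integer >= 1")

  p <- list(n = as.integer(n), m = as.integer(m), mu = mu, s = s, c = c,
            r = c * s, N0 = N0, NT = NT, T = as.integer(T),
            alpha = derive_growth_factor(N0, NT, T),
            fitness_weighting = fitness_weighting,
            survival_exponent = survival_exponent)
  class(p) <- "clonewave_params"
  p
}

#' @export
print.clonewave_params <- function(x, ...) {
  cat("Two-class Wright-Fisher model parameters\n")
  cat(sprintf("  loci:       n = %d superdriver, m = %d driver\n", x$n, x$m))
  cat(sprintf("  mutation:   mu = %g per gene per generation\n", x$mu))
  cat(sprintf("  selection:  s = %g (driver), c = %g, r = c*s = %g (superdriver)\n",
              x$s, x$c, x$r))
  cat(sprintf("  growth:     N0 = %g -> NT = %g over T = %d generations (alpha = %.8f)\n",
              x$N0, x$NT, x$T, x$alpha))
  cat(sprintf("  switches:   fitness_weighting = %s, survival_exponent = %s\n",
              x$fitness_weighting, x$survival_exponent))
  invisible(x)
}

#' Per-generation growth factor of the deterministic size schedule
#'
#' The population is multiplied by a constant factor each generation so that
#' it grows from `N0` to `NT` cells in exactly `T` generations:
#' `alpha = exp(log(NT / N0) / T)`.
#'
#' @param N0,NT Initial and final population sizes, cells, both `> 0`.
#' @param T Number of generations, `>= 1`.
#' @return The growth multiplier `alpha`, satisfying `alpha^T * N0 = NT`.
#' @examples
#' derive_growth_factor(1e6, 1e9, 4500)
#' @export
derive_growth_factor <- function(N0, NT, T) {
  if (!is.numeric(N0) || !is.numeric(NT) || !is.numeric(T) ||
      N0 <= 0 || NT <= 0 || T < 1)
    stop("invalid parameters: need N0 > 0, NT > 0, T >= 1", call. = FALSE)
  exp(log(NT / N0) / T)
}

#' Deterministic population-size schedule
#'
#' The multinomial resampling totals for generations `0 .. T`. Sizes are
#' precomputed as `round(N0 * alpha^t)` rather than multiplied step by step,
#' which avoids cumulative rounding drift and makes `N(T) = NT` exact.
#'
#' @param params A [model_params()] object.
#' @return Numeric vector of length `T + 1`; element `t + 1` is `N(t)`.
#' @examples
#' size_schedule(model_params(T = 10))
#' @export
size_schedule <- function(params) {
  stopifnot(inherits(params, "clonewave_params"))
  round(params$N0 * params$alpha^(0:params$T))
}

# Lower-triangular per-class mutation kernel: entry [k+1, i+1] is the
# probability factor for a parent with i mutated loci (out of nloci) gaining
# k - i further mutations. The survival exponent is parent-indexed
# ("as_printed", (1-mu)^(nloci-i)) or offspring-indexed ("per_locus",
# (1-mu)^(nloci-k)). choose() returns 0 for k < i, so no back mutation by
# construction.
mutation_kernel <- function(nloci, mu, survival_exponent = "as_printed") {
  i <- 0:nloci
  gained <- outer(i, i, function(k, i) k - i)       # offspring minus parent
  remaining <- matrix(nloci - i, nloci + 1, nloci + 1, byrow = TRUE)
  A <- choose(remaining, gained) * mu^pmax(gained, 0)
  A[gained < 0] <- 0
  surv <- if (survival_exponent == "as_printed") {
    matrix((1 - mu)^(nloci - i), nloci + 1, nloci + 1, byrow = TRUE)
  } else {
    matrix((1 - mu)^(nloci - i), nloci + 1, nloci + 1)
  }
  A * surv
}

# Both kernels plus the unnormalized fitness surface, computed once per run.
model_kernels <- function(params) {
  list(A = mutation_kernel(params$n, params$mu, params$survival_exponent),
       Bt = t(mutation_kernel(params$m, params$mu, params$survival_exponent)),
       Wnum = outer((1 + params$r)^(0:params$n), (1 + params$s)^(0:params$m)))
}
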