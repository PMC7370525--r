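#' Analytic waiting time to k superdrivers (or l drivers)
#'
#' Closed-form approximation of the expected number of generations until the
#' first cell with `k` superdriver mutations appears, obtained by decoupling
#' selection and mutation in the traveling-wave regime: each successive
#' class takes `log^2(r / (mu n)) / (r log(N(T) N(0)))` generations, so
#' `T_k = k log^2(r / (mu n)) / (r log(N(T) N(0)))` (natural logarithms).
#' [analytic_T_driver()] is the same form with `(s, m, l)` in place of
#' `(r, n, k)`. The size term uses the product `N(T) * N(0)` by default;
#' `size_log_arg = "ratio"` substitutes `N(T) / N(0)`.
#'
#' The approximation models establishment-paced accumulation, so it is not
#' meaningful for the very first mutant produced directly by the large
#' initial population (see the package vignette).
#'
#' @param k,l Number of superdriver / driver mutations waited for
#'   (vectorized, `>= 0`).
#' @param params A [model_params()] object.
#' @param size_log_arg `"product"` for `log(N(T) * N(0))` or `"ratio"` for
#'   `log(N(T) / N(0))`.
#' @return Expected waiting time in generations; 0 when `k` (or `l`) is 0.
#' @examples
#' p <- model_params(s = 0.01, c = 2)
#' analytic_T_super(1:3, p)
#' analytic_T_driver(1:3, p)
#' @export
analytic_T_super <- function(k, params, size_log_arg = c("product", "ratio")) {
  stopifnot(inherits(params, "clonewave_params"))
  analytic_T_class(k, params$r, params$n, params,
                   match.arg(size_log_arg), "superdriver")
}

#' @rdname analytic_T_super
#' @export
analytic_T_driver <- function(l, params, size_log_arg = c("product", "ratio")) {
  stopifnot(inherits(params, "clonewave_params"))
  analytic_T_class(l, params$s, params$m, params,
                   match.arg(size_log_arg), "driver")
}

analytic_T_class <- function(k, adv, nloci, params, size_log_arg, label) {
  if (any(k < 0 | k != round(k)))
    stop("mutation count must be a non-negative integer", call. = FALSE)
  out <- numeric(length(k))
  pos <- k > 0
  if (any(pos)) {
    if (adv <= 0)
      stop(sprintf("%s advantage must be > 0 for a positive waiting time",
                   label), call. = FALSE)
    if (adv <= params$mu * nloci)
      stop(sprintf("%s advantage must exceed mu * loci for the approximation",
                   label), call. = FALSE)
    denom_arg <- if (size_log_arg == "product") params$NT * params$N0
                 else params$NT / params$N0
    out[pos] <- k[pos] * log(adv / (params$mu * nloci))^2 /
      (adv * log(denom_arg))
  }
  out
}

#' Analytic waiting time to a joint (k, l) mutant
#'
#' The waiting time to the first cell carrying `k` superdriver and `l`
#' driver mutations, approximated as the sum of the two single-class
#' waiting times: `tau_kl ~ T_k^S + T_l^D`.
#'
#' @inheritParams analytic_T_super
#' @examples
#' tau_approx(2, 3, model_params(s = 0.01, c = 2))
#' @export
tau_approx <- function(k, l, params, size_log_arg = c("product", "ratio")) {
  size_log_arg <- match.arg(size_log_arg)
  analytic_T_super(k, params, size_log_arg) +
    analytic_T_driver(l, params, size_log_arg)
}

#' Empirical waiting time to clone (k, l)
#'
#' Per replicate, the first generation at which clone `(k, l)` had at least
#' one cell; returns the mean over replicates that reached the clone, plus
#' censoring counts for replicates that never did within the horizon `T`.
#' By default the event is the appearance of the exact clone (exactly `k`
#' superdrivers and `l` drivers); `at_least = TRUE` instead uses the first
#' generation at which any clone `(i >= k, j >= l)` is populated.
#'
#' @param x A `clonewave_ensemble`, a single `clonewave_traj`, or a list of
#'   `clonewave_traj` objects.
#' @param k,l Target superdriver and driver counts.
#' @param at_least Use the cumulative (at-least) event definition?
#' @return List with `mean` (generations, `NaN` when fully censored), `n`
#'   (uncensored replicates), `censored` (censored replicates) and
#'   `times` (per-replicate first-hit generations, `NA` when censored).
#' @examples
#' p <- model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
#'                   N0 = 500, NT = 500, T = 30)
#' ens <- run_ensemble(p, replicates = 5, master_seed = 3)
#' empirical_waiting_time(ens, 1, 0)
#' @export
empirical_waiting_time <- function(x, k, l, at_least = FALSE) {
  fh <- first_hit_stack(x)      # replicates x (n+1) x (m+1)
  nk <- dim(fh)[2] - 1L; nl <- dim(fh)[3] - 1L
  if (k < 0 || k > nk || l < 0 || l > nl)
    stop(sprintf("clone (%d, %d) outside the genotype space (%d, %d)",
                 k, l, nk, nl), call. = FALSE)
  times <- if (at_least) {
    apply(fh[, (k + 1):(nk + 1), (l + 1):(nl + 1), drop = FALSE], 1,
          function(sl) suppressWarnings(min(sl, na.rm = TRUE)))
  } else {
    fh[, k + 1L, l + 1L]
  }
  times[!is.finite(times)] <- NA_real_
  list(mean = mean(times, na.rm = TRUE), n = sum(!is.na(times)),
       censored = sum(is.na(times)), times = times)
}

first_hit_stack <- function(x) {
  if (inherits(x, "clonewave_ensemble")) return(x$first_hit)
  if (inherits(x, "clonewave_traj")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "clonewave_traj"))) {
    fh <- array(NA_real_, c(length(x), dim(x[[1]]$first_hit)))
    for (i in seq_along(x)) fh[i, , ] <- x[[i]]$first_hit
    return(fh)
  }
  stop("x must be an ensemble, a trajectory, or a list of trajectories",
       call. = FALSE)
}

#' Residual table: simulated vs analytic waiting times over a grid
#'
#' For every grid ensemble and every requested `(k, l)`, records the mean
#' simulated waiting time, the analytic approximation `T_k^S + T_l^D`, and
#' their residual. Cells where more than `max_censored` of the replicates
#' never reached the clone are flagged (`regression_ok = FALSE`) and
#' excluded from downstream regressions; fully censored cells have `NA`
#' residual.
#'
#' @param grid_results A `clonewave_grid` from [run_grid()].
#' @param k_range,l_range Mutation-count ranges (defaults 1..6 and 1..10,
#'   capped at the genotype space).
#' @param at_least Passed to [empirical_waiting_time()].
#' @param size_log_arg Passed to [tau_approx()].
#' @param max_censored Maximum tolerated censored fraction for a row to
#'   enter regressions (default 0.5).
#' @return A data frame with one row per (s, c, k, l): columns `s, c, r, k,
#'   l, tau_sim, n_uncensored, censored_frac, T_super, T_driver, tau_approx,
#'   residual, regression_ok`.
#' @export
build_residual_table <- function(grid_results, k_range = 1:6, l_range = 1:10,
                                 at_least = FALSE,
                                 size_log_arg = c("product", "ratio"),
                                 max_censored = 0.5) {
  stopifnot(inherits(grid_results, "clonewave_grid"))
  size_log_arg <- match.arg(size_log_arg)
  rows <- list()
  for (key in names(grid_results)) {
    ens <- grid_results[[key]]
    p <- ens$params
    k_use <- k_range[k_range <= p$n]
    l_use <- l_range[l_range <= p$m]
    for (k in k_use) for (l in l_use) {
      ew <- empirical_waiting_time(ens, k, l, at_least)
      ts <- analytic_T_super(k, p, size_log_arg)
      td <- analytic_T_driver(l, p, size_log_arg)
      cf <- ew$censored / ens$replicates
      rows[[length(rows) + 1L]] <- data.frame(
        s = p$s, c = p$c, r = p$r, k = k, l = l,
        tau_sim = if (ew$n > 0) ew$mean else NA_real_,
        n_uncensored = ew$n, censored_frac = cf,
        T_super = ts, T_driver = td, tau_approx = ts + td,
        residual = if (ew$n > 0) ew$mean - (ts + td) else NA_real_,
        regression_ok = ew$n > 0 && cf <= max_censored)
    }
  }
  do.call(rbind, rows)
}

#' Linear residual-correction model
#'
#' Ordinary least squares of the waiting-time residual
#' `epsilon = tau_sim - tau_approx` on an intercept and four covariates:
#' either `(s, r, k, l)` or `(s, c, k, l)` (with `c = r / s`). The fitted
#' model quantifies where the sum approximation deviates from simulation
#' and can be added back to `tau_approx` as a correction.
#'
#' @param table A residual table from [build_residual_table()]; rows with
#'   `regression_ok = FALSE` are dropped.
#' @param covariate_set `"s,r,k,l"` or `"s,c,k,l"`.
#' @return Object of class `clonewave_error_model`: list with `covariate_set`,
#'   `beta` (named coefficients), `std_errors`, `t_values`, `p_values`,
#'   `standardized` (coefficients rescaled by sd(covariate)/sd(residual)),
#'   `adj_r2`, `f_stat`, `p_value` (overall F test), `n_obs` and `fit` (the
#'   underlying `lm` object).
#' @examples
#' tab <- data.frame(s = runif(12), c = rep(c(1, 2, 3), 4),
#'                   k = rep(1:2, 6), l = rep(1:4, 3),
#'                   regression_ok = TRUE)
#' tab$r <- tab$c * tab$s
#' tab$residual <- 2 + 3 * tab$s
#' fit_error_model(tab, "s,r,k,l")$beta
#' @export
fit_error_model <- function(table, covariate_set = c("s,r,k,l", "s,c,k,l")) {
  covariate_set <- match.arg(covariate_set)
  covs <- strsplit(covariate_set, ",", fixed = TRUE)[[1]]
  need <- c(covs, "residual", "regression_ok")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- table[table$regression_ok & !is.na(table$residual), , drop = FALSE]
  if (nrow(dat) < 6)
    stop("need at least 6 uncensored rows to fit the error model",
         call. = FALSE)
  X <- cbind(1, as.matrix(dat[covs]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(covs, response = "residual")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  fs <- sm$fstatistic
  std <- stats::coef(fit)[-1] *
    vapply(dat[covs], stats::sd, 0) / stats::sd(dat$residual)
  structure(list(covariate_set = covariate_set,
                 beta = stats::coef(fit),
                 std_errors = sm$coefficients[, "Std. Error"],
                 t_values = sm$coefficients[, "t value"],
                 p_values = sm$coefficients[, "Pr(>|t|)"],
                 standardized = std,
                 adj_r2 = sm$adj.r.squared,
                 f_stat = unname(fs[1]),
                 p_value = unname(stats::pf(fs[1], fs[2], fs[3],
                                            lower.tail = FALSE)),
                 n_obs = nrow(dat), fit = fit),
            class = "clonewave_error_model")
}

#' @export
print.clonewave_error_model <- function(x, ...) {
  cat(sprintf("Residual model (%s), n = %d\n", x$covariate_set, x$n_obs))
  tab <- cbind(estimate = x$beta, std_error = x$std_errors,
               t = x$t_values, p = x$p_values)
  print(signif(tab, 4))
  cat(sprintf("adjusted R^2 = %.3f, F = %.1f, p = %.3g\n",
              x$adj_r2, x$f_stat, x$p_value))
  invisible(x)
}
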