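#' Replicate ensemble of tumor-progression trajectories
#'
#' Simulates `replicates` independent trajectories under one parameter set
#' and averages clone counts per generation. Per-replicate seeds are derived
#' deterministically from `master_seed` so that any single replicate can be
#' replayed with [simulate_trajectory()].
#'
#' @param params A [model_params()] object.
#' @param replicates Number of independent replicates (`>= 1`).
#' @param master_seed Integer master seed for the ensemble.
#' @param keep_replicates Keep the full per-replicate trajectories? Default
#'   `FALSE`: only ensemble means and per-replicate first-hit matrices are
#'   retained (a full default-size trajectory is ~40 MB).
#' @return Object of class `clonewave_ensemble`: list with `params`,
#'   `replicates`, `rep_seeds`, `schedule`, `mean_counts` (array
#'   `(n + 1) x (m + 1) x (T + 1)` of mean clone counts), `first_hit`
#'   (array `replicates x (n + 1) x (m + 1)` of per-replicate first
#'   appearance generations, `NA` when censored) and, if requested,
#'   `trajectories`. Mean frequencies are `mean_counts[, , t + 1] / N(t)`
#'   because the size schedule is deterministic; see [clone_series()].
#' @examples
#' p <- model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
#'                   N0 = 200, NT = 200, T = 20)
#' ens <- run_ensemble(p, replicates = 3, master_seed = 42)
#' ens$mean_counts[, , 21]
#' @export
run_ensemble <- function(params, replicates = 50, master_seed = 1L,
                         keep_replicates = FALSE) {
  stopifnot(inherits(params, "clonewave_params"))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  rep_seeds <- derive_seeds(master_seed, replicates)
  nr <- params$n + 1L; nc <- params$m + 1L
  acc <- array(0, c(nr, nc, params$T + 1L))
  first_hit <- array(NA_real_, c(replicates, nr, nc))
  kept <- if (keep_replicates) vector("list", replicates) else NULL
  sched <- NULL
  for (rep in seq_len(replicates)) {
    tr <- tryCatch(simulate_trajectory(params, rep_seeds[rep]),
                   error = function(e)
                     stop(sprintf("replicate %d failed: %s", rep,
                                  conditionMessage(e)), call. = FALSE))
    acc <- acc + tr$counts
    first_hit[rep, , ] <- tr$first_hit
    sched <- tr$schedule
    if (keep_replicates) kept[[rep]] <- tr
  }
  structure(list(params = params, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 rep_seeds = rep_seeds, schedule = sched,
                 mean_counts = acc / replicates, first_hit = first_hit,
                 trajectories = kept),
            class = "clonewave_ensemble")
}

# Substream seeds: drawn from the master seed's stream, reproducible and
# recorded in outputs so any replicate can be rerun on its own.
derive_seeds <- function(master_seed, replicates) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, replicates)
}

#' @export
print.clonewave_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d replicates (master seed %d): s = %g, c = %g, T = %d\n",
              x$replicates, x$master_seed, x$params$s, x$params$c, x$params$T))
  invisible(x)
}

#' Parameter grid specification
#'
#' The simulation study design: a grid over driver selection `s` and
#' superdriver factor `c`, replicated `replicates` times per cell. Defaults
#' are the study grid: `s` in \{0.005, 0.01, 0.02, 0.03, 0.04, 0.05\} and
#' `c` spanning 1 to 3 (the named values 1.1, 1.3, 1.5, 2.6, 2.8, 3.0 plus
#' an even filling of the middle of the range), with 50 replicates.
#'
#' @param s_values Driver selection coefficients, each in `[0, 1]`.
#' @param c_values Superdriver factors, each `>= 1`.
#' @param replicates Replicates per grid cell.
#' @param master_seed Master seed; each grid cell gets a derived sub-seed.
#' @return Object of class `clonewave_grid_spec`.
#' @export
grid_spec <- function(s_values = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05),
                      c_values = c(1.0, 1.1, 1.3, 1.5, 1.7, 1.9,
                                   2.1, 2.3, 2.6, 2.8, 3.0),
                      replicates = 50, master_seed = 1L) {
  if (any(s_values < 0 | s_values > 1))
    stop("all s_values must be in [0, 1]", call. = FALSE)
  if (any(c_values < 1)) stop("all c_values must be >= 1", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(s_values = s_values, c_values = c_values,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "clonewave_grid_spec")
}

#' Run a replicate ensemble for every (s, c) grid cell
#'
#' @param grid A [grid_spec()].
#' @param base A [model_params()] object providing all non-grid parameters;
#'   each cell reuses it with `s` and `c` (hence `r = c * s`) replaced.
#' @param keep_replicates Passed to [run_ensemble()].
#' @return Object of class `clonewave_grid`: list of
#'   [run_ensemble()] results named `"s=<s>,c=<c>"`, with a `manifest`
#'   attribute (data frame of s, c, r, replicates, seed per run).
#' @examples
#' p <- model_params(n = 1, m = 2, mu = 1e-3, N0 = 200, NT = 200, T = 20)
#' g <- run_grid(grid_spec(s_values = 0.05, c_values = c(1, 2),
#'                         replicates = 2, master_seed = 7), p)
#' attr(g, "manifest")
#' @export
run_grid <- function(grid, base, keep_replicates = FALSE) {
  stopifnot(inherits(grid, "clonewave_grid_spec"),
            inherits(base, "clonewave_params"))
  cells <- expand.grid(s = grid$s_values, c = grid$c_values,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(grid$master_seed, nrow(cells))
  out <- vector("list", nrow(cells))
  names(out) <- grid_key(cells$s, cells$c)
  for (i in seq_len(nrow(cells))) {
    p <- base
    p$s <- cells$s[i]; p$c <- cells$c[i]; p$r <- p$c * p$s
    out[[i]] <- run_ensemble(p, grid$replicates, cell_seeds[i],
                             keep_replicates)
  }
  manifest <- data.frame(key = names(out), s = cells$s, c = cells$c,
                         r = cells$c * cells$s,
                         replicates = grid$replicates, seed = cell_seeds)
  structure(out, manifest = manifest, class = "clonewave_grid")
}

grid_key <- function(s, c) sprintf("s=%g,c=%g", s, c)

#' @export
print.clonewave_grid <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Parameter grid: %d ensembles (%d replicates each)\n",
              nrow(man), man$replicates[1]))
  print(utils::head(man, 10))
  invisible(x)
}
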