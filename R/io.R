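#' Default run configuration
#'
#' All tunables of a simulation study in one nested list: model parameters,
#' grid design, analysis settings, and I/O options. [load_config()] fills
#' unspecified fields from these defaults.
#'
#' @return Object of class `clonewave_config` (a nested list with sections
#'   `model`, `grid`, `analysis`, `io`, `seed`).
#' @export
default_config <- function() {
  structure(list(
    model = list(n = 10L, m = 100L, mu = 1e-8, s = 0.01, c = 2,
                 N0 = 1e6, NT = 1e9, T = 4500L,
                 fitness_weighting = "offspring",
                 survival_exponent = "as_printed"),
    grid = list(s_values = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05),
                c_values = c(1.0, 1.1, 1.3, 1.5, 1.7, 1.9,
                             2.1, 2.3, 2.6, 2.8, 3.0),
                replicates = 50L),
    analysis = list(threshold = 0.01, min_span = 500L,
                    k_range = 1:6, l_range = 1:10,
                    size_log_arg = "product", at_least = FALSE,
                    fit_scale = "log", max_censored = 0.5),
    io = list(out_dir = ".", keep_replicates = FALSE),
    seed = 1L), class = "clonewave_config")
}

#' Load (and validate) a run configuration file
#'
#' Reads a YAML or JSON configuration whose structure mirrors
#' [default_config()]. Validation is strict: unknown keys are an error, as
#' are invalid values (e.g. `c < 1`). Missing keys take the defaults, so an
#' empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `clonewave_config`.
#' @seealso [save_config()] for the lossless inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()        # empty file -> all defaults
  as_config(raw)
}

#' @rdname load_config
#' @param config A `clonewave_config` to write.
#' @param path Output path; format chosen by extension as in [load_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "clonewave_config"))
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path, precision = 15)
  }
  invisible(path)
}

# Merge user values over defaults, strictly: unknown keys anywhere fail.
as_config <- function(raw) {
  cfg <- unclass(default_config())
  if (length(raw)) {
    bad <- setdiff(names(raw), c(names(cfg)))
    if (length(bad))
      stop("unknown config section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (sec in names(raw)) {
      if (sec == "seed") { cfg$seed <- raw$seed; next }
      bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        stop(sprintf("unknown key(s) in section '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  # model_params() and grid_spec() own the value checks; surface their
  # messages with the offending section prefixed.
  try_section <- function(sec, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("config section '%s': %s", sec, conditionMessage(e)),
           call. = FALSE))
  }
  try_section("model", do.call(model_params, cfg$model))
  try_section("grid", grid_spec(cfg$grid$s_values, cfg$grid$c_values,
                                cfg$grid$replicates, 1L))
  a <- cfg$analysis
  if (a$threshold <= 0)
    stop("config section 'analysis': threshold must be > 0", call. = FALSE)
  if (!a$size_log_arg %in% c("product", "ratio"))
    stop("config section 'analysis': size_log_arg must be 'product' or 'ratio'",
         call. = FALSE)
  if (!a$fit_scale %in% c("log", "linear"))
    stop("config section 'analysis': fit_scale must be 'log' or 'linear'",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config: seed must be a single integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "clonewave_config")
}

#' Model parameters and grid spec from a configuration
#'
#' @param config A `clonewave_config`.
#' @return [config_params()]: the `model_params()` object;
#'   [config_grid()]: the `grid_spec()` object (master seed = config seed).
#' @export
config_params <- function(config) {
  stopifnot(inherits(config, "clonewave_config"))
  do.call(model_params, config$model)
}

#' @rdname config_params
#' @export
config_grid <- function(config) {
  stopifnot(inherits(config, "clonewave_config"))
  grid_spec(config$grid$s_values, config$grid$c_values,
            config$grid$replicates, config$seed)
}

#' Write / read a trajectory or ensemble as tidy TSV + JSON sidecar
#'
#' The TSV holds one row per occupied clone per generation with columns
#' `replicate, generation, k, l, count` (zero counts are implied and not
#' written; `replicate` is the replicate's seed for single trajectories,
#' `"mean"` for ensemble means). Counts of single trajectories are exact
#' integers, so `read_trajectory(write_trajectory(x))` reproduces the count
#' array bit-exactly. A JSON sidecar at `<path>.json` records the model
#' parameters, seed(s), size schedule and package version.
#'
#' @param x A `clonewave_traj` or `clonewave_ensemble`.
#' @param path Output TSV path.
#' @return `write_trajectory()`: the path, invisibly. `read_trajectory()`:
#'   the reconstructed object (ensembles come back with mean counts and
#'   first-hit data dropped unless present in the sidecar).
#' @export
write_trajectory <- function(x, path) {
  if (inherits(x, "clonewave_traj")) {
    df <- counts_long(x$counts, as.character(x$seed))
    meta <- list(type = "trajectory", params = unclass(x$params),
                 seed = x$seed, schedule = x$schedule,
                 version = as.character(utils::packageVersion("clonewave")))
  } else if (inherits(x, "clonewave_ensemble")) {
    df <- counts_long(x$mean_counts, "mean")
    meta <- list(type = "ensemble", params = unclass(x$params),
                 replicates = x$replicates, master_seed = x$master_seed,
                 rep_seeds = x$rep_seeds, schedule = x$schedule,
                 first_hit = x$first_hit,
                 version = as.character(utils::packageVersion("clonewave")))
  } else stop("x must be a trajectory or ensemble", call. = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

counts_long <- function(arr, replicate_label) {
  occ <- which(arr > 0, arr.ind = TRUE)
  df <- data.frame(replicate = replicate_label,
                   generation = occ[, 3] - 1L,
                   k = occ[, 1] - 1L, l = occ[, 2] - 1L,
                   count = arr[occ])
  df[order(df$generation, df$k, df$l), ]
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pm <- meta$params
  params <- model_params(pm$n, pm$m, pm$mu, pm$s, pm$c, pm$N0, pm$NT, pm$T,
                         pm$fitness_weighting, pm$survival_exponent)
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "numeric", "numeric",
                                               "numeric"))
  check_trajectory_rows(df, params)
  arr <- array(0, c(params$n + 1L, params$m + 1L, params$T + 1L))
  arr[cbind(df$k + 1L, df$l + 1L, df$generation + 1L)] <- df$count
  if (identical(meta$type, "trajectory")) {
    fh <- first_hits_from_array(arr)
    structure(list(params = params, seed = as.integer(meta$seed),
                   counts = arr, schedule = as.numeric(meta$schedule),
                   first_hit = fh), class = "clonewave_traj")
  } else {
    fh <- meta$first_hit
    if (!is.null(fh)) fh <- array(as.numeric(fh), dim(fh))
    structure(list(params = params, replicates = as.integer(meta$replicates),
                   master_seed = as.integer(meta$master_seed),
                   rep_seeds = as.integer(meta$rep_seeds),
                   schedule = as.numeric(meta$schedule),
                   mean_counts = arr, first_hit = fh, trajectories = NULL),
              class = "clonewave_ensemble")
  }
}

check_trajectory_rows <- function(df, params) {
  need <- c("replicate", "generation", "k", "l", "count")
  if (!identical(names(df), need))
    stop("malformed trajectory TSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$generation) | !is.finite(df$k) |
               !is.finite(df$l) | !is.finite(df$count) |
               df$generation < 0 | df$generation > params$T |
               df$k < 0 | df$k > params$n | df$l < 0 | df$l > params$m |
               df$count < 0)
  if (length(bad))
    stop(sprintf("malformed trajectory TSV at data line %d", bad[1] + 1L),
         call. = FALSE)
  df
}

first_hits_from_array <- function(arr) {
  d <- dim(arr)
  fh <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    w <- which(arr[i, j, ] > 0)
    if (length(w)) fh[i, j] <- w[1] - 1
  }
  fh
}

#' Named small-parameter fixtures for tests and demos
#'
#' \describe{
#'   \item{`"tiny-neutral"`}{neutral, mutation-free toy model
#'     (`n = 1, m = 2, mu = 0, s = 0, c = 1, N = 200, T = 20`); the
#'     population stays monomorphic wild type. Returns a trajectory.}
#'   \item{`"tiny-oracle"`}{small mutating model
#'     (`n = 1, m = 2, N = 200, T = 20, mu = 1e-3, s = 0.05, c = 2`) sized
#'     so the per-cell oracle is feasible. Returns a trajectory.}
#'   \item{`"two-gaussian-waves"`}{a synthetic (not simulated) abundance
#'     series over generations 0..400: Gaussian pulses of height 0.3 at
#'     t = 100 (sd 20) and 0.1 at t = 250 (sd 30), separated by a
#'     sub-threshold valley; exactly two waves at threshold 0.01. Returns a
#'     named numeric series.}
#'   \item{`"paper-default-short"`}{default model parameters with the
#'     horizon shortened to T = 500. Returns a trajectory.}
#' }
#'
#' @param preset One of the names above.
#' @param seed Seed for the simulated presets.
#' @return A `clonewave_traj`, or a numeric series for
#'   `"two-gaussian-waves"`.
#' @export
make_fixture <- function(preset = c("tiny-neutral", "tiny-oracle",
                                    "two-gaussian-waves",
                                    "paper-default-short"),
                         seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "tiny-neutral" = simulate_trajectory(
      model_params(n = 1, m = 2, mu = 0, s = 0, c = 1,
                   N0 = 200, NT = 200, T = 20), seed),
    "tiny-oracle" = simulate_trajectory(
      model_params(n = 1, m = 2, mu = 1e-3, s = 0.05, c = 2,
                   N0 = 200, NT = 200, T = 20), seed),
    "two-gaussian-waves" = {
      t <- 0:400
      y <- 0.3 * exp(-(t - 100)^2 / (2 * 20^2)) +
           0.1 * exp(-(t - 250)^2 / (2 * 30^2))
      names(y) <- t
      y
    },
    "paper-default-short" = simulate_trajectory(
      model_params(T = 500), seed))
}
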