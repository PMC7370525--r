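#' Abundance time series of one clone
#'
#' Extracts the per-generation abundance of clone `(k, l)` from a
#' trajectory or ensemble, on the cell-count or relative-frequency scale.
#' For ensembles, counts are replicate means and frequencies are the means
#' divided by the (deterministic) population size.
#'
#' @param x A `clonewave_traj` or `clonewave_ensemble`.
#' @param k,l Clone mutation counts.
#' @param scale `"frequency"` (default) or `"counts"`.
#' @return Numeric vector of length `T + 1`, named by generation `0..T`.
#' @export
clone_series <- function(x, k, l, scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  counts <- if (inherits(x, "clonewave_ensemble")) x$mean_counts
            else if (inherits(x, "clonewave_traj")) x$counts
            else stop("x must be a trajectory or ensemble", call. = FALSE)
  p <- x$params
  if (k < 0 || k > p$n || l < 0 || l > p$m)
    stop(sprintf("clone (%d, %d) outside the genotype space", k, l),
         call. = FALSE)
  y <- counts[k + 1L, l + 1L, ]
  if (scale == "frequency") y <- y / x$schedule
  names(y) <- 0:p$T
  y
}

#' Detect traveling-wave episodes in an abundance series
#'
#' A wave is a maximal contiguous run of generations during which the
#' clone's abundance stays at or above `threshold`. Each run yields one
#' segment with its peak generation (earliest generation in case of ties)
#' and peak abundance.
#'
#' @param series Numeric abundance series; names, if present, are taken as
#'   generation indices (otherwise generations are `0, 1, ...`).
#' @param threshold Detection threshold, same scale as `series`, `> 0`.
#'   The default 0.01 corresponds to 1\% of the population on the
#'   frequency scale.
#' @return Data frame with one row per wave: `start_gen`, `end_gen`,
#'   `peak_gen`, `peak_value`, `span` (`end_gen - start_gen + 1`). Zero
#'   rows when the series never reaches the threshold.
#' @examples
#' tser <- dnorm(0:400, 200, 30)
#' detect_waves(tser, 0.001)
#' @export
detect_waves <- function(series, threshold = 0.01) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  gens <- if (!is.null(names(series))) as.numeric(names(series))
          else seq_along(series) - 1
  above <- series >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(start_gen = numeric(0), end_gen = numeric(0),
                    peak_gen = numeric(0), peak_value = numeric(0),
                    span = numeric(0))
  for (i in keep) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(series[idx])]          # which.max: earliest tie
    out <- rbind(out, data.frame(start_gen = gens[starts[i]],
                                 end_gen = gens[ends[i]],
                                 peak_gen = gens[pk],
                                 peak_value = series[pk],
                                 span = gens[ends[i]] - gens[starts[i]] + 1))
  }
  rownames(out) <- NULL
  out
}

#' Number of driver waves within one superdriver class
#'
#' Counts how many driver classes `l` in `0..l_max` produce at least one
#' detected wave of clone `(k, l)` — the driver waves arising within the
#' epoch dominated by `k` superdrivers.
#'
#' @param x A `clonewave_traj` or `clonewave_ensemble`.
#' @param k Superdriver class.
#' @param threshold Detection threshold (frequency scale).
#' @param l_max Largest driver count considered (default 10).
#' @param scale Abundance scale for detection.
#' @return Integer count.
#' @export
count_driver_waves <- function(x, k, threshold = 0.01, l_max = 10,
                               scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  l_max <- min(l_max, x$params$m)
  hits <- vapply(0:l_max, function(l) {
    nrow(detect_waves(clone_series(x, k, l, scale), threshold)) > 0
  }, TRUE)
  sum(hits)
}

#' Wave widths across the clone grid
#'
#' Detects waves for every clone `(k <= k_max, l <= l_max)` and returns the
#' spans of those lasting at least `min_span` generations.
#'
#' @inheritParams count_driver_waves
#' @param min_span Minimum span in generations (default 500).
#' @param k_max Largest superdriver count considered (default `n`).
#' @return Data frame with columns `k, l, start_gen, end_gen, peak_gen,
#'   peak_value, span`; zero rows if nothing qualifies.
#' @export
wave_widths <- function(x, threshold = 0.01, min_span = 500,
                        k_max = NULL, l_max = 10,
                        scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  p <- x$params
  if (is.null(k_max)) k_max <- p$n
  k_max <- min(k_max, p$n); l_max <- min(l_max, p$m)
  rows <- list()
  for (k in 0:k_max) for (l in 0:l_max) {
    seg <- detect_waves(clone_series(x, k, l, scale), threshold)
    seg <- seg[seg$span >= min_span, , drop = FALSE]
    if (nrow(seg)) rows[[length(rows) + 1L]] <- cbind(k = k, l = l, seg)
  }
  if (!length(rows))
    return(data.frame(k = numeric(0), l = numeric(0), start_gen = numeric(0),
                      end_gen = numeric(0), peak_gen = numeric(0),
                      peak_value = numeric(0), span = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Height differences between consecutive driver waves
#'
#' Within superdriver class `k`, collects all detected waves of clones
#' `(k, l)` for `l = 0..l_max`, orders them by peak generation, and returns
#' the absolute differences in peak abundance between consecutive waves.
#'
#' @inheritParams count_driver_waves
#' @return Numeric vector (empty when fewer than two waves).
#' @export
peak_height_differences <- function(x, k, threshold = 0.01, l_max = 10,
                                    scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  segs <- collect_waves(x, k = k, l_values = 0:min(l_max, x$params$m),
                        threshold = threshold, scale = scale)
  if (nrow(segs) < 2) return(numeric(0))
  segs <- segs[order(segs$peak_gen), ]
  abs(diff(segs$peak_value))
}

#' Generations between consecutive superdriver wave peaks
#'
#' At fixed driver count `l`, takes each superdriver class `k = 0, 1, ...`
#' whose clone `(k, l)` has a detected wave (using the highest-peaked wave
#' per clone), and returns the differences in peak generation between
#' consecutive classes.
#'
#' @inheritParams count_driver_waves
#' @param l Driver class held fixed.
#' @param k_max Largest superdriver count considered (default `n`).
#' @return Numeric vector (empty when fewer than two classes have waves).
#' @export
peak_spacings <- function(x, l, threshold = 0.01, k_max = NULL,
                          scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  if (is.null(k_max)) k_max <- x$params$n
  peaks <- c()
  for (k in 0:min(k_max, x$params$n)) {
    seg <- detect_waves(clone_series(x, k, l, scale), threshold)
    if (nrow(seg)) peaks <- c(peaks, seg$peak_gen[which.max(seg$peak_value)])
  }
  if (length(peaks) < 2) return(numeric(0))
  diff(peaks)
}

# All wave segments of clones (k, l) for l in l_values, tagged with l.
collect_waves <- function(x, k, l_values, threshold, scale) {
  rows <- list()
  for (l in l_values) {
    seg <- detect_waves(clone_series(x, k, l, scale), threshold)
    if (nrow(seg)) rows[[length(rows) + 1L]] <- cbind(l = l, seg)
  }
  if (!length(rows))
    return(data.frame(l = numeric(0), start_gen = numeric(0),
                      end_gen = numeric(0), peak_gen = numeric(0),
                      peak_value = numeric(0), span = numeric(0)))
  do.call(rbind, rows)
}

#' Quadratic fit to one wave
#'
#' Least-squares quadratic fit to a wave segment, by default on the natural
#' log of abundance: a Gaussian pulse `A exp(-(t - t0)^2 / (2 sigma^2))` is
#' exactly parabolic in log space, with vertex `t0`, height `log A` and
#' curvature `-1 / (2 sigma^2)`. Fits with non-negative curvature or a
#' vertex outside the segment are returned with `accepted = FALSE`.
#'
#' @param series Abundance series as from [clone_series()].
#' @param segment One row of a [detect_waves()] result (or any list with
#'   `start_gen` and `end_gen`).
#' @param scale `"log"` (default) fits `log(abundance)`; `"linear"` fits
#'   the raw abundance.
#' @return Object of class `clonewave_quadfit`: list with `location`
#'   (vertex generation), `height` (fitted value at the vertex, on the fit
#'   scale), `curvature` (second-order coefficient), `r2`, `accepted`, and
#'   `reject_reason` (`NA` when accepted).
#' @examples
#' tser <- exp(-0.001 * ((0:400) - 200)^2 + 5)
#' names(tser) <- 0:400
#' seg <- detect_waves(tser, 1)[1, ]
#' fit_wave_quadratic(tser, seg)
#' @export
fit_wave_quadratic <- function(series, segment, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  gens <- if (!is.null(names(series))) as.numeric(names(series))
          else seq_along(series) - 1
  idx <- which(gens >= segment$start_gen & gens <= segment$end_gen)
  if (length(idx) < 3)
    stop("segment must contain at least 3 generations", call. = FALSE)
  tt <- gens[idx]
  y <- if (scale == "log") log(series[idx]) else series[idx]
  if (any(!is.finite(y)))
    stop("non-positive abundance inside segment; cannot fit on log scale",
         call. = FALSE)
  tc <- tt - mean(tt)                     # center for conditioning
  fit <- stats::lm(y ~ tc + I(tc^2))
  b <- stats::coef(fit)
  curvature <- unname(b[3])
  location <- if (curvature != 0) mean(tt) - unname(b[2]) / (2 * curvature)
              else NA_real_
  height <- if (is.na(location)) NA_real_
            else unname(b[1] + b[2] * (location - mean(tt)) +
                        curvature * (location - mean(tt))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  reject <- if (!is.finite(curvature) || curvature >= 0) "non-negative curvature"
            else if (location < segment$start_gen ||
                     location > segment$end_gen) "vertex outside segment"
            else NA_character_
  structure(list(location = location, height = height, curvature = curvature,
                 r2 = r2, accepted = is.na(reject), reject_reason = reject,
                 scale = scale),
            class = "clonewave_quadfit")
}

#' @export
print.clonewave_quadfit <- function(x, ...) {
  cat(sprintf("Quadratic wave fit (%s scale): %s\n", x$scale,
              if (x$accepted) "accepted" else paste("rejected:",
                                                    x$reject_reason)))
  cat(sprintf("  location %.1f, height %.4g, curvature %.4g, R^2 %.4f\n",
              x$location, x$height, x$curvature, x$r2))
  invisible(x)
}

#' Quadratic fits for every wave of a trajectory or ensemble
#'
#' Convenience wrapper: detects waves for all clones up to `(k_max, l_max)`
#' and fits each with [fit_wave_quadratic()].
#'
#' @inheritParams wave_widths
#' @param min_points Minimum segment length (generations) to attempt a fit.
#' @param fit_scale Passed to [fit_wave_quadratic()] as `scale`.
#' @return Data frame with columns `k, l, start_gen, end_gen, span,
#'   location, height, curvature, r2, accepted`.
#' @export
fit_all_waves <- function(x, threshold = 0.01, k_max = NULL, l_max = 10,
                          scale = c("frequency", "counts"),
                          fit_scale = c("log", "linear"), min_points = 3) {
  scale <- match.arg(scale); fit_scale <- match.arg(fit_scale)
  p <- x$params
  if (is.null(k_max)) k_max <- p$n
  rows <- list()
  for (k in 0:min(k_max, p$n)) for (l in 0:min(l_max, p$m)) {
    ser <- clone_series(x, k, l, scale)
    segs <- detect_waves(ser, threshold)
    for (i in seq_len(nrow(segs))) {
      if (segs$span[i] < min_points) next
      qf <- fit_wave_quadratic(ser, segs[i, ], fit_scale)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, l = l, start_gen = segs$start_gen[i],
        end_gen = segs$end_gen[i], span = segs$span[i],
        location = qf$location, height = qf$height,
        curvature = qf$curvature, r2 = qf$r2, accepted = qf$accepted)
    }
  }
  if (!length(rows))
    return(data.frame(k = numeric(0), l = numeric(0), start_gen = numeric(0),
                      end_gen = numeric(0), span = numeric(0),
                      location = numeric(0), height = numeric(0),
                      curvature = numeric(0), r2 = numeric(0),
                      accepted = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
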