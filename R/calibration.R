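#' Per-pixel mean and variance of a calibration stack
#'
#' For each pixel of a `height x width x n_frames` stack, computes the sample
#' mean and unbiased (n - 1 denominator) sample variance of its time series
#' of image counts.
#'
#' @param stack 3-D numeric array with at least two frames.
#' @return Data frame with columns `pixel`, `mean`, `var`.
#' @export
pixel_stats <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3L || d[3L] < 2L)
    stop("`stack` must be a height x width x frames array with >= 2 frames")
  m <- matrix(as.numeric(stack), nrow = d[1L] * d[2L])
  n <- d[3L]
  mu <- rowMeans(m)
  v <- (rowSums(m^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0   # guard against tiny negative round-off
  data.frame(pixel = seq_len(nrow(m)), mean = mu, var = v)
}

#' Fit the mean-variance line of a calibration experiment
#'
#' Ordinary least squares of per-pixel variance on per-pixel mean, after
#' discarding the lowest `trim_low` and highest `trim_high` quantiles of the
#' pixel means within each experiment (outlier control). With the gain off
#' the slope estimates `1/f`; with the gain on it estimates `2g/f`.
#'
#' @param points Data frame with columns `mean` and `var`, optionally
#'   `experiment` (trimming is applied per experiment before pooling).
#' @param trim_low,trim_high Quantile fractions trimmed per experiment.
#' @return An object of class `mv_line_fit` with `slope`, `intercept`,
#'   `n_points_used` and the trim fractions.
#' @export
fit_mv_line <- function(points, trim_low = 0.01, trim_high = 0.01) {
  stopifnot(is.data.frame(points), all(c("mean", "var") %in% names(points)))
  if (is.null(points$experiment)) points$experiment <- 1L
  keep <- unlist(lapply(split(seq_len(nrow(points)), points$experiment),
                        function(idx) {
    x <- points$mean[idx]
    q <- stats::quantile(x, c(trim_low, 1 - trim_high), names = FALSE)
    idx[x >= q[1L] & x <= q[2L]]
  }), use.names = FALSE)
  pts <- points[keep, ]
  if (nrow(pts) < 10L) stop("fewer than 10 points remain after trimming")
  if (stats::sd(pts$mean) < .Machine$double.eps^0.5 * max(1, mean(pts$mean)))
    stop("degenerate mean-variance data: no spread in pixel means")
  fit <- stats::lm.fit(cbind(1, pts$mean), pts$var)
  structure(
    list(slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         n_points_used = nrow(pts),
         trim_fractions = c(low = trim_low, high = trim_high)),
    class = "mv_line_fit")
}

#' @export
print.mv_line_fit <- function(x, ...) {
  cat(sprintf("Mean-variance line: var = %.6g * mean + %.6g  (%d pixels)\n",
              x$slope, x$intercept, x$n_points_used))
  invisible(x)
}

#' Chip parameters from the two mean-variance line fits
#'
#' Combines the gain-off fit (slope `k_nogain ~ 1/f`, intercept `C_nogain`)
#' and the gain-on fit (slope `k_gain ~ 2g/f`, intercept `C_gain`) into the
#' four chip constants:
#' `f = 1/k_nogain`, `g = k_gain * f / 2`,
#' `delta = f (C_nogain - C_gain) / (2g - 1)` and
#' `r^2 = C_nogain - 1/12 + delta/f`.
#'
#' @param fit_nogain,fit_gain [fit_mv_line()] results (or any lists with
#'   `slope` and `intercept`).
#' @return A [chip_params()] object (gain on).
#' @export
chip_from_fits <- function(fit_nogain, fit_gain) {
  k0 <- fit_nogain$slope; c0 <- fit_nogain$intercept
  k1 <- fit_gain$slope;   c1 <- fit_gain$intercept
  if (!is.finite(k0) || k0 <= 0) stop("gain-off slope must be positive")
  f <- 1 / k0
  g <- k1 * f / 2
  if (2 * g - 1 <= 0)
    stop("inconsistent calibration: 2g - 1 <= 0 from the fitted slopes")
  delta <- f * (c0 - c1) / (2 * g - 1)
  r2 <- c0 - 1 / 12 + delta / f
  if (r2 < 0)
    stop("inconsistent calibration: negative readout-noise variance")
  chip_params(g = g, f = f, r = sqrt(r2), delta = delta)
}

#' Subsampling uncertainty of the chip-parameter estimate
#'
#' Repeats the complete estimation (both line fits plus [chip_from_fits()])
#' on random subsets of `subset_size` pixels drawn without replacement from
#' each mode's pixel pool, and summarises each parameter by its median and
#' interquartile range over the repetitions.
#'
#' @param points_nogain,points_gain Data frames as accepted by
#'   [fit_mv_line()].
#' @param subset_size Pixels per subset (per experiment pool).
#' @param n_reps Number of repetitions.
#' @param trim_low,trim_high Trim fractions for each subset fit.
#' @return An object of class `chip_estimate`: the point-estimate `params`
#'   (fit on all pixels), a `summary` data frame (median, q25, q75 per
#'   parameter) and the per-repetition `reps` data frame.
#' @export
subsample_uncertainty <- function(points_nogain, points_gain,
                                  subset_size = 1000, n_reps = 200,
                                  trim_low = 0.01, trim_high = 0.01) {
  full <- chip_from_fits(fit_mv_line(points_nogain, trim_low, trim_high),
                         fit_mv_line(points_gain, trim_low, trim_high))
  draw_subset <- function(points) {
    if (nrow(points) <= subset_size) return(points)
    points[sample.int(nrow(points), subset_size), ]
  }
  if (nrow(points_nogain) < subset_size || nrow(points_gain) < subset_size) {
    warning("fewer pixels than `subset_size`; reporting the single full fit")
    n_reps <- 1L
  }
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    est <- try(chip_from_fits(
      fit_mv_line(draw_subset(points_nogain), trim_low, trim_high),
      fit_mv_line(draw_subset(points_gain), trim_low, trim_high)),
      silent = TRUE)
    reps[[b]] <- if (inherits(est, "try-error")) {
      data.frame(g = NA_real_, f = NA_real_, r = NA_real_, delta = NA_real_)
    } else data.frame(g = est$g, f = est$f, r = est$r, delta = est$delta)
  }
  reps <- do.call(rbind, reps)
  smry <- do.call(rbind, lapply(c("g", "f", "r", "delta"), function(p) {
    q <- stats::quantile(reps[[p]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    data.frame(parameter = p, median = q[2L], q25 = q[1L], q75 = q[3L])
  }))
  structure(list(params = full, summary = smry, reps = reps,
                 subset_size = subset_size, n_reps = n_reps),
            class = "chip_estimate")
}

#' @export
print.chip_estimate <- function(x, ...) {
  cat("Chip parameter estimate (point fit on all pixels):\n")
  print(x$params)
  cat(sprintf("Subsampling uncertainty (%d reps of %d pixels):\n",
              x$n_reps, x$subset_size))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Full mean-variance calibration from simulated or recorded stacks
#'
#' Convenience wrapper: computes [pixel_stats()] for every stack, pools the
#' gain-off and gain-on pixel pools (tagged by experiment for per-experiment
#' trimming), fits both mean-variance lines, converts them to chip
#' parameters and attaches the subsampling uncertainty.
#'
#' @param stacks A list as returned by [make_calibration_stacks()], i.e.
#'   with `gain_on` and `gain_off` lists of 3-D arrays.
#' @param exclude_levels Optional integer indices of illumination levels to
#'   drop (dataset-specific outliers).
#' @inheritParams subsample_uncertainty
#' @return A `chip_estimate` (see [subsample_uncertainty()]), with the two
#'   `mv_line_fit`s attached as `fit_nogain` / `fit_gain`.
#' @export
calibrate_chip <- function(stacks, exclude_levels = integer(),
                           subset_size = 1000, n_reps = 200,
                           trim_low = 0.01, trim_high = 0.01) {
  keep <- setdiff(seq_along(stacks$gain_on), exclude_levels)
  pool <- function(stack_list) {
    do.call(rbind, lapply(keep, function(i) {
      st <- pixel_stats(stack_list[[i]])
      st$experiment <- i
      st
    }))
  }
  pts0 <- pool(stacks$gain_off)
  pts1 <- pool(stacks$gain_on)
  est <- subsample_uncertainty(pts0, pts1, subset_size = subset_size,
                               n_reps = n_reps, trim_low = trim_low,
                               trim_high = trim_high)
  est$fit_nogain <- fit_mv_line(pts0, trim_low, trim_high)
  est$fit_gain <- fit_mv_line(pts1, trim_low, trim_high)
  est
}
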