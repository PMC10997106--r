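#' Characteristic function of the EMCCD count distribution
#'
#' Closed-form characteristic function of the rounded image count produced by
#' the full EMCCD noise chain: Poisson photoelectron arrivals, Gamma
#' multiplication noise (gain on), Gaussian readout noise, offset, and
#' rounding to the nearest integer. With the gain on,
#' \deqn{\varphi(p) = e^{-p^2 r^2/2 + ip\Delta}\,
#'       \exp\{\lambda(1/(1 - ip\,g/f) - 1)\}\,
#'       \mathrm{sinc}(p/2),}
#' with \eqn{\mathrm{sinc}(x) = \sin(x)/x}. With the gain off the
#' multiplication factor is replaced by the Poisson characteristic function
#' \eqn{\exp\{\lambda(e^{ip/f} - 1)\}}.
#'
#' @param p Numeric vector of transform values (radians per image count).
#' @param model A [noise_model()].
#' @return Complex vector of the same length as `p`.
#' @examples
#' m <- noise_model(chip_params(18.82, 35.17, 1.45, 26.37), 22)
#' cf_emccd(0, m)            # always 1
#' Mod(cf_emccd(2.5, m))     # modulus never exceeds 1
#' @export
cf_emccd <- function(p, model) {
  stopifnot(is_noise_model(model))
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("`p` must be a finite numeric vector")
  chip <- model$chip
  lam <- model$lam
  sinc <- rep(1, length(p))
  nz <- p != 0
  sinc[nz] <- sin(p[nz] / 2) / (p[nz] / 2)
  base <- exp(-p^2 * chip$r^2 / 2 + 1i * p * chip$delta) * sinc
  if (chip$gain_on) {
    amp <- exp(lam * (1 / (1 - 1i * p * (chip$g / chip$f)) - 1))
  } else {
    amp <- exp(lam * (exp(1i * p / chip$f) - 1))
  }
  base * amp
}

#' Symmetric transform grid for characteristic-function inversion
#'
#' Chooses the quadrature grid for the inverse Fourier integral. The cutoff
#' `half_width` is picked so that the modulus envelope of the characteristic
#' function drops below `cf_floor` at the cutoff; when `r = 0` the Gaussian
#' envelope is absent, decay is only ~1/p from the rounding kernel, and a
#' fixed cutoff of 64*pi is used. The spacing is set so that the aliasing
#' period of the discretised inverse transform comfortably exceeds
#' `alias_width` integer counts.
#'
#' @param model A [noise_model()].
#' @param alias_width Minimal aliasing period in counts (at least 1024).
#' @param cf_floor Target modulus of the CF envelope at the cutoff.
#' @return An object of class `transform_grid` with fields `p_values`
#'   (symmetric about 0), `half_width` and `n_points`.
#' @export
transform_grid <- function(model, alias_width = 1024, cf_floor = 1e-12) {
  stopifnot(is_noise_model(model))
  chip <- model$chip
  half_width <- if (chip$r > 0) {
    # envelope: exp(-p^2 r^2/2) * exp(lam(1/(1+p^2 G^2)-1)) * min(1, 2/p)
    G <- if (chip$gain_on) chip$g / chip$f else 0
    env <- function(p)
      -p^2 * chip$r^2 / 2 + model$lam * (1 / (1 + p^2 * G^2) - 1) +
        log(pmin(1, 2 / p))
    p_try <- 2^seq(-2, 14, by = 0.25)
    p_hit <- p_try[env(p_try) < log(cf_floor)]
    if (length(p_hit)) min(p_hit) else 64 * pi
  } else 64 * pi
  alias_width <- max(alias_width, 1024)
  dp <- 2 * pi / alias_width
  n_half <- ceiling(half_width / dp)
  n_points <- max(2L * n_half + 1L, 1024L)
  structure(
    list(p_values = seq(-n_half, n_half) * dp, half_width = n_half * dp,
         n_points = n_points, dp = dp, n_half = n_half),
    class = "transform_grid")
}

# Quadrature engine: precomputes, for a fixed chip / support / grid, every
# lambda-independent part of the inverse-transform sum so that evaluating the
# PMF at a new lambda costs one complex exp over the grid plus two
# matrix-vector products. Used heavily inside the truncated MLE scan.
pmf_engine <- function(chip, support, grid_model = NULL,
                       alias_width = NULL, cf_floor = 1e-12) {
  stopifnot(is_chip_params(chip))
  support <- as.integer(support)
  if (is.null(alias_width))
    alias_width <- max(4L * length(support) + 512L, 1024L)
  if (is.null(grid_model)) grid_model <- noise_model(chip, 0)
  grid <- transform_grid(grid_model, alias_width = alias_width,
                         cf_floor = cf_floor)
  # one-sided grid, j = 0..n_half; symmetry doubles the j > 0 terms
  p <- seq(0L, grid$n_half) * grid$dp
  sinc <- rep(1, length(p))
  sinc[-1L] <- sin(p[-1L] / 2) / (p[-1L] / 2)
  base <- exp(-p^2 * chip$r^2 / 2 + 1i * p * chip$delta) * sinc
  w <- rep(grid$dp / pi, length(p))        # 2 * dp / (2*pi)
  w[1L] <- w[1L] / 2                       # p = 0 counted once
  w[length(w)] <- w[length(w)] / 2         # trapezoid end point
  h <- if (chip$gain_on) {
    1 / (1 - 1i * p * (chip$g / chip$f)) - 1
  } else {
    exp(1i * p / chip$f) - 1
  }
  big <- length(support) * length(p) > 4e7
  if (!big) {
    ang <- outer(support, p)
    Cmat <- cos(ang); Smat <- sin(ang)
    ang <- NULL
  } else Cmat <- Smat <- NULL
  list(chip = chip, support = support, p = p, w = w, base = base, h = h,
       Cmat = Cmat, Smat = Smat, grid = grid, big = big)
}

# PMF over engine$support at Poisson parameter lam (not normalised/clipped).
engine_pmf <- function(engine, lam) {
  cf <- engine$base * exp(lam * engine$h)
  wr <- engine$w * Re(cf)
  wi <- engine$w * Im(cf)
  if (!engine$big) {
    drop(engine$Cmat %*% wr + engine$Smat %*% wi)
  } else {
    vapply(engine$support, function(n) {
      sum(cos(n * engine$p) * wr) + sum(sin(n * engine$p) * wi)
    }, numeric(1))
  }
}

#' Exact count distribution by characteristic-function inversion
#'
#' Computes the probability mass function of the rounded image count on a
#' contiguous integer support by numerical inversion of [cf_emccd()]
#' (trapezoidal quadrature of the inverse Fourier integral). The support
#' starts at mean +/- 8 standard deviations (from the closed-form moments)
#' and is extended until the captured probability mass reaches
#' `1 - tail_mass`. Tiny negative quadrature ripple (above `-1e-9`) is
#' clipped to zero and the mass renormalised; anything more negative aborts,
#' since it signals an inadequate transform grid.
#'
#' @param model A [noise_model()].
#' @param grid Optional [transform_grid()]; by default one is chosen from the
#'   model (cutoff where the CF modulus falls below 1e-12).
#' @param tail_mass Upper bound on the probability mass left outside the
#'   returned support.
#' @return An object of class `count_distribution` with integer `support`,
#'   `pmf` and `cdf` (running sum, i.e. `cdf[i] = P(X <= support[i])`).
#' @examples
#' m <- noise_model(chip_params(18.82, 35.17, 1.45, 26.37), 22)
#' d <- build_distribution(m)
#' sum(d$pmf)
#' @export
build_distribution <- function(model, grid = NULL, tail_mass = 1e-9) {
  stopifnot(is_noise_model(model))
  mom <- emccd_moments(model)
  sd0 <- sqrt(mom[["variance"]])
  lo <- floor(mom[["mean"]] - 8 * max(sd0, 1))
  hi <- ceiling(mom[["mean"]] + 8 * max(sd0, 1))
  alias_width <- if (!is.null(grid)) round(2 * pi / grid$dp) else NULL
  step <- max(ceiling(4 * sd0), 4)
  for (round_i in 1:12) {
    support <- seq.int(lo, hi)
    eng <- pmf_engine(model$chip, support, grid_model = model,
                      alias_width = max(4L * length(support) + 512L,
                                        if (is.null(alias_width)) 1024L
                                        else as.integer(alias_width)))
    pmf <- engine_pmf(eng, model$lam)
    if (min(pmf) < -1e-9)
      stop("characteristic-function inversion failed: negative PMF values ",
           "beyond quadrature-ripple tolerance (min = ", format(min(pmf)),
           "); the transform grid is inadequate for this model")
    pmf[pmf < 0] <- 0
    mass <- sum(pmf)
    if (mass >= 1 - tail_mass) break
    # extend on whichever side still carries mass
    if (pmf[1L] > tail_mass / length(pmf)) lo <- lo - step
    if (pmf[length(pmf)] > tail_mass / length(pmf)) hi <- hi + step
    if (round_i == 12L && mass < 1 - 1e-4)
      stop("characteristic-function inversion failed: captured mass ",
           format(mass), " after maximal support extension")
  }
  pmf <- pmf / sum(pmf)
  structure(
    list(support = support, pmf = pmf, cdf = cumsum(pmf), model = model),
    class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("EMCCD count distribution on [%d, %d] (%d atoms)\n",
              x$support[1L], x$support[length(x$support)],
              length(x$support)))
  cat(sprintf("  lambda = %s, mean = %.4f, sd = %.4f\n", format(x$model$lam),
              sum(x$support * x$pmf),
              sqrt(sum(x$support^2 * x$pmf) - sum(x$support * x$pmf)^2)))
  invisible(x)
}

# CDF lookup P(X <= n) for integer n (vectorised), using the running sum.
dist_cdf <- function(dist, n) {
  idx <- findInterval(n, dist$support)
  out <- numeric(length(n))
  out[idx > 0] <- dist$cdf[idx[idx > 0]]
  out[n >= dist$support[length(dist$support)]] <- 1
  out
}

#' Closed-form mean and variance of the EMCCD count distribution
#'
#' Gain on: mean \eqn{\lambda g/f + \Delta}, variance
#' \eqn{2\lambda (g/f)^2 + r^2 + 1/12}; gain off: mean
#' \eqn{\lambda/f + \Delta}, variance \eqn{\lambda/f^2 + r^2 + 1/12}.
#' The 1/12 term is the variance of the rounding error under the uniform
#' approximation.
#'
#' @param model A [noise_model()].
#' @return Named numeric vector `c(mean, variance)`.
#' @export
emccd_moments <- function(model) {
  stopifnot(is_noise_model(model))
  chip <- model$chip
  if (chip$gain_on) {
    mu <- model$lam * chip$g / chip$f + chip$delta
    v <- 2 * model$lam * (chip$g / chip$f)^2 + chip$r^2 + 1 / 12
  } else {
    mu <- model$lam / chip$f + chip$delta
    v <- model$lam / chip$f^2 + chip$r^2 + 1 / 12
  }
  c(mean = mu, variance = v)
}

#' Upper-tail quantile of the EMCCD count distribution
#'
#' Returns the smallest integer `N` such that `1 - cdf(N) <= p_tail`, i.e.
#' the tightest count threshold for which classifying counts above `N` as
#' signal keeps the background false-positive probability at or below
#' `p_tail`.
#'
#' @param p_tail Tail probability, strictly inside (0, 1).
#' @param model A [noise_model()], or a precomputed `count_distribution`.
#' @return Integer count threshold.
#' @export
invert_cdf <- function(p_tail, model) {
  if (!is.numeric(p_tail) || length(p_tail) != 1L || !is.finite(p_tail) ||
      p_tail <= 0 || p_tail >= 1)
    stop("`p_tail` must be a single probability strictly inside (0, 1)")
  dist <- if (inherits(model, "count_distribution")) model
          else build_distribution(model)
  tail <- 1 - dist$cdf
  idx <- which(tail <= p_tail)
  dist$support[idx[1L]]
}

#' Background p-value for the summed counts of a pixel region
#'
#' Probability that the sum of `k` independent background pixel counts is at
#' least `observed_sum`. For `k` up to `k_exact_max` the distribution of the
#' sum is obtained exactly by inverting the k-th power of the characteristic
#' function; beyond that a normal approximation with mean `k*mu`, variance
#' `k*sigma^2` and a half-count continuity correction is used.
#'
#' @param observed_sum Total image counts over the region.
#' @param k Number of pixels in the region (>= 1).
#' @param model Background [noise_model()].
#' @param k_exact_max Largest region size handled by exact inversion.
#' @return A p-value in `[0, 1]`.
#' @export
region_sum_pvalue <- function(observed_sum, k, model, k_exact_max = 64) {
  stopifnot(is_noise_model(model))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a single integer >= 1")
  k <- as.integer(k)
  mom <- emccd_moments(model)
  if (k == 1L) {
    dist <- build_distribution(model)
    return(1 - dist_cdf(dist, observed_sum - 1))
  }
  if (k <= k_exact_max) {
    mu_k <- k * mom[["mean"]]
    sd_k <- sqrt(k * mom[["variance"]])
    lo <- floor(mu_k - 10 * sd_k)
    hi <- ceiling(mu_k + 10 * sd_k)
    if (observed_sum > hi) {
      # beyond the captured support: fall back to the Gaussian tail bound
      return(stats::pnorm((observed_sum - 0.5 - mu_k) / sd_k,
                          lower.tail = FALSE))
    }
    support <- seq.int(lo, hi)
    eng <- pmf_engine(model$chip, support, grid_model = model,
                      alias_width = max(4L * length(support) + 512L, 1024L))
    # k-th CF power: raise both the lambda-free base and the Poisson factor
    cf <- (eng$base * exp(model$lam * eng$h))^k
    wr <- eng$w * Re(cf); wi <- eng$w * Im(cf)
    pmf <- if (!eng$big) drop(eng$Cmat %*% wr + eng$Smat %*% wi)
           else vapply(support, function(n)
             sum(cos(n * eng$p) * wr) + sum(sin(n * eng$p) * wi), numeric(1))
    pmf[pmf < 0] <- 0
    pmf <- pmf / sum(pmf)
    if (observed_sum <= lo) return(1)
    return(sum(pmf[support >= observed_sum]))
  }
  stats::pnorm((observed_sum - 0.5 - k * mom[["mean"]]) /
                 sqrt(k * mom[["variance"]]), lower.tail = FALSE)
}
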