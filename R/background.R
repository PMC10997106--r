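#' Candidate truncation points for the background fit
#'
#' Ascending unique image-count values from the `min_fraction` data quantile
#' up to the maximum observed count, optionally thinned to at most
#' `max_candidates` values evenly spaced in empirical-quantile space (first
#' and last candidates always kept).
#'
#' @param counts Integer vector of image counts.
#' @param min_fraction Smallest fraction of the data that any truncation must
#'   keep (the lowest candidate sits at this quantile).
#' @param max_candidates Cap on the number of candidates.
#' @return Ascending integer vector of candidate truncation points.
#' @export
truncation_grid <- function(counts, min_fraction = 0.25,
                            max_candidates = 60) {
  counts <- sort(as.integer(counts))
  if (length(unique(counts)) < 2L)
    stop("all image counts are identical; no truncation scan possible")
  q <- counts[max(1L, ceiling(min_fraction * length(counts)))]
  cand <- unique(counts[counts >= q])
  if (length(cand) > max_candidates) {
    # empirical quantile of each candidate; pick candidates closest to an
    # even quantile ladder between the first and last candidate
    ecdf_vals <- stats::ecdf(counts)(cand)
    targets <- seq(ecdf_vals[1L], ecdf_vals[length(ecdf_vals)],
                   length.out = max_candidates)
    idx <- unique(vapply(targets, function(t)
      which.min(abs(ecdf_vals - t)), integer(1)))
    idx <- sort(unique(c(1L, idx, length(cand))))
    cand <- cand[idx]
  }
  cand
}

# Tabulate counts once: integer values and occurrence numbers, plus the
# cumulative number of pixels at or below each value.
tabulate_counts <- function(counts) {
  counts <- sort(as.integer(counts))
  vals <- unique(counts)
  occ <- tabulate(match(counts, vals))
  list(values = vals, occ = occ, cum = cumsum(occ), m = length(counts))
}

# Truncated negative log-likelihood at lambda for counts <= trunc, using a
# shared quadrature engine whose support covers [support_min, trunc_max].
trunc_negloglik <- function(lam, engine, tab, trunc) {
  pmf <- engine_pmf(engine, lam)
  sup <- engine$support
  cdf_t <- sum(pmf[sup <= trunc])
  # lambda so large that the truncated window carries no mass: the model is
  # numerically void there; a penalty sloped in lambda steers the
  # golden-section search back into the supported range
  if (!is.finite(cdf_t) || cdf_t < 1e-12) return(1e8 * (1 + lam))
  pmf[pmf < 1e-300] <- 1e-300
  sel <- tab$values <= trunc
  idx <- match(tab$values[sel], sup)
  n_below <- sum(tab$occ[sel])
  -(sum(tab$occ[sel] * log(pmf[idx])) - n_below * log(cdf_t))
}

# Engine support for a background fit: from well below the offset-only
# distribution up to the largest truncation considered.
background_engine <- function(chip, counts, trunc_max) {
  lo <- floor(min(chip$delta - 10 * (chip$r + 1), min(counts)))
  pmf_engine(chip, seq.int(lo, trunc_max),
             grid_model = noise_model(chip, 0))
}

#' Truncated maximum-likelihood estimate of the background strength
#'
#' Maximises the truncated log-likelihood
#' \eqn{\sum_{n_j \le N} \log \mathrm{pmf}(n_j|\theta) -
#'      m_N \log \mathrm{cdf}(N|\theta)}
#' over the Poisson parameter, where the PMF is the inverse transform of
#' [cf_emccd()] and `N` is the truncation point. The search is a bounded
#' derivative-free scalar optimisation on
#' `[1e-3, 50 * lam_init]`, started from the moment initialiser
#' `lam_init = (median(counts) - delta) / (g/f)` (clipped to at least 1e-3).
#'
#' @param counts Integer image counts (the full, untruncated sample; the
#'   truncation is applied internally).
#' @param truncation Integer truncation point.
#' @param chip A [chip_params()].
#' @param engine,tab Optional precomputed internals (used by
#'   [fit_background()] to share work across a truncation scan).
#' @return The estimate `lambda_hat`, with attributes `loglik` and
#'   `lam_init`.
#' @export
truncated_mle <- function(counts, truncation, chip, engine = NULL,
                          tab = NULL) {
  stopifnot(is_chip_params(chip))
  if (is.null(tab)) tab <- tabulate_counts(counts)
  if (is.null(engine)) engine <- background_engine(chip, tab$values,
                                                   truncation)
  gf <- if (chip$gain_on) chip$g / chip$f else 1 / chip$f
  med <- tab$values[which.max(tab$cum >= tab$m / 2)]
  lam_init <- max((med - chip$delta) / gf, 1e-3)
  opt <- stats::optimize(trunc_negloglik, engine = engine, tab = tab,
                         trunc = truncation,
                         interval = c(1e-3, 50 * lam_init),
                         tol = max(1e-4 * lam_init, 1e-6))
  structure(opt$minimum, loglik = -opt$objective, lam_init = lam_init)
}

#' Chi-square goodness of fit of a truncated background model
#'
#' Bins the truncated support into five contiguous count intervals whose
#' expected probabilities under the fitted truncated PMF are as close to 1/5
#' as integer bin edges allow (greedy accumulation of PMF mass), computes
#' the Pearson statistic over the counts at or below the truncation point,
#' and returns the upper-tail p-value on 5 - 1 - 1 = 3 degrees of freedom
#' (one parameter having been estimated from the data).
#'
#' @param counts Integer image counts.
#' @param truncation Truncation point.
#' @param model Fitted background [noise_model()].
#' @param engine,tab Optional precomputed internals.
#' @return The p-value, with attributes `statistic`, `df`, `observed`,
#'   `expected`; `NA` with attribute `failed = TRUE` when fewer than 5
#'   populated bins are achievable or fewer than 25 data points lie at or
#'   below the truncation.
#' @export
gof_chi2 <- function(counts, truncation, model, engine = NULL, tab = NULL) {
  stopifnot(is_noise_model(model))
  if (is.null(tab)) tab <- tabulate_counts(counts)
  if (is.null(engine)) engine <- background_engine(model$chip, tab$values,
                                                   truncation)
  failed <- function() structure(NA_real_, failed = TRUE)
  sel <- tab$values <= truncation
  n_below <- sum(tab$occ[sel])
  if (n_below < 25L) return(failed())
  pmf <- engine_pmf(engine, model$lam)
  pmf[pmf < 0] <- 0
  sup <- engine$support
  in_t <- sup <= truncation
  if (sum(pmf[in_t]) < 1e-12) return(failed())
  q <- pmf[in_t] / sum(pmf[in_t])     # truncated PMF over [support_min, N]
  sup_t <- sup[in_t]
  # greedy integer bin edges at the 1/5-quantiles of the truncated PMF
  cumq <- cumsum(q)
  edges <- integer(4L)
  last <- 0L
  for (j in 1:4) {
    k <- which(cumq >= j / 5)[1L]
    if (is.na(k)) return(failed())
    k <- max(k, last + 1L)              # at least one integer per bin
    if (k > length(sup_t) - (4L - j) - 1L) return(failed())
    edges[j] <- k
    last <- k
  }
  bin_of_idx <- findInterval(seq_along(sup_t), edges + 1L) + 1L
  expected_p <- vapply(1:5, function(b) sum(q[bin_of_idx == b]), numeric(1))
  obs_idx <- match(tab$values[sel], sup_t)
  obs_bin <- bin_of_idx[obs_idx]
  observed <- vapply(1:5, function(b) sum(tab$occ[sel][obs_bin == b]),
                     numeric(1))
  expected <- n_below * expected_p
  if (any(expected <= 0)) return(failed())
  stat <- sum((observed - expected)^2 / expected)
  structure(stats::pchisq(stat, df = 3, lower.tail = FALSE),
            statistic = stat, df = 3, observed = observed,
            expected = expected)
}

#' Fit the background illumination strength of an image
#'
#' Estimates the Poisson background parameter of an image that contains both
#' background and signal pixels, making no assumption about the signal
#' statistics. The sorted counts are fitted by truncated maximum likelihood
#' at a scan of candidate truncation points (see [truncation_grid()]); each
#' fit is scored by [gof_chi2()]; the accepted truncation is the largest one
#' whose goodness-of-fit p-value reaches `p_gof`, and the background
#' estimate is that truncation's maximum-likelihood value.
#'
#' @param counts Integer image counts (vector or matrix).
#' @param chip A [chip_params()].
#' @param p_gof Goodness-of-fit acceptance level.
#' @param min_fraction,max_candidates Passed to [truncation_grid()].
#' @param min_pixels Floor on the number of pixels for a meaningful fit.
#' @param on_no_pass What to do when no truncation reaches `p_gof`:
#'   `"error"` (default) raises the `pia_no_fit` condition; `"accept-best"`
#'   accepts the truncation with the highest goodness-of-fit p-value and
#'   marks the fit with `fallback = TRUE` (single-image workflows with no
#'   neighbouring tile to borrow from).
#' @return An object of class `background_fit`: `lam_bg`, `n_icr_bg`, the
#'   full `scan` data frame (`truncation_point`, `lambda_hat`, `gof_pvalue`,
#'   `n_below`), `p_gof`, `m` and the `chip`. Errors with condition class
#'   `pia_no_fit` (carrying the scan in its `scan` field) when no truncation
#'   passes.
#' @examples
#' chip <- chip_params(18.82, 35.17, 1.45, 26.37)
#' x <- draw_counts(22, chip, n = 4096, seed = 1)
#' fit <- fit_background(x, chip)
#' coef(fit)
#' @export
fit_background <- function(counts, chip, p_gof = 0.01, min_fraction = 0.25,
                           max_candidates = 60, min_pixels = 100,
                           on_no_pass = c("error", "accept-best")) {
  on_no_pass <- match.arg(on_no_pass)
  stopifnot(is_chip_params(chip))
  counts <- as.integer(counts)
  if (length(counts) < min_pixels)
    stop("need at least ", min_pixels, " pixels for a background fit")
  cand <- truncation_grid(counts, min_fraction, max_candidates)
  tab <- tabulate_counts(counts)
  engine <- background_engine(chip, tab$values, max(cand))
  scan <- data.frame(truncation_point = cand,
                     lambda_hat = NA_real_, gof_pvalue = NA_real_,
                     n_below = NA_integer_)
  for (i in seq_along(cand)) {
    lam_hat <- truncated_mle(counts, cand[i], chip, engine = engine,
                             tab = tab)
    p <- gof_chi2(counts, cand[i], noise_model(chip, as.numeric(lam_hat)),
                  engine = engine, tab = tab)
    scan$lambda_hat[i] <- as.numeric(lam_hat)
    scan$gof_pvalue[i] <- as.numeric(p)
    scan$n_below[i] <- sum(tab$occ[tab$values <= cand[i]])
  }
  pass <- which(!is.na(scan$gof_pvalue) & scan$gof_pvalue >= p_gof)
  fallback <- FALSE
  if (!length(pass)) {
    if (on_no_pass == "error" || all(is.na(scan$gof_pvalue))) {
      cond <- structure(
        class = c("pia_no_fit", "error", "condition"),
        list(message = "no truncation point passed the goodness-of-fit test",
             call = sys.call(-1), scan = scan))
      stop(cond)
    }
    warning("no truncation passed the goodness-of-fit test; accepting the ",
            "best-fitting one (fallback)")
    pass <- which.max(scan$gof_pvalue)
    fallback <- TRUE
  }
  acc <- pass[length(pass)]
  structure(
    list(lam_bg = scan$lambda_hat[acc],
         n_icr_bg = scan$truncation_point[acc],
         scan = scan, p_gof = p_gof, m = length(counts), chip = chip,
         fallback = fallback, counts_range = range(counts)),
    class = "background_fit")
}

#' @export
print.background_fit <- function(x, ...) {
  cat("Truncated maximum-likelihood background fit\n")
  cat(sprintf("  lambda_bg     = %.4f photoelectrons/pixel\n", x$lam_bg))
  cat(sprintf("  truncation    = %d counts (largest passing GoF at p >= %g)\n",
              x$n_icr_bg, x$p_gof))
  cat(sprintf("  pixels        = %d, scan of %d truncation points\n",
              x$m, nrow(x$scan)))
  invisible(x)
}

#' @export
summary.background_fit <- function(object, ...) {
  cat(sprintf("Background fit: lambda_bg = %.4f at truncation %d (m = %d)\n",
              object$lam_bg, object$n_icr_bg, object$m))
  cat("Truncation scan:\n")
  print(object$scan, row.names = FALSE)
  invisible(object$scan)
}

#' @export
coef.background_fit <- function(object, ...) {
  c(lambda_bg = object$lam_bg)
}

#' @export
plot.background_fit <- function(x, counts = NULL, ...) {
  model <- noise_model(x$chip, x$lam_bg)
  dist <- build_distribution(model)
  if (!is.null(counts)) {
    h <- graphics::hist(counts, breaks = seq(min(counts) - 0.5,
                                             max(counts) + 0.5),
                        plot = FALSE)
    graphics::plot(h$mids, h$density, type = "h",
                   col = ifelse(h$mids <= x$n_icr_bg, "steelblue", "orange"),
                   xlab = "image count", ylab = "density",
                   main = "Background fit", ...)
    graphics::lines(dist$support, dist$pmf, lwd = 2)
  } else {
    graphics::plot(dist$support, dist$pmf, type = "h",
                   xlab = "image count", ylab = "probability",
                   main = sprintf("Fitted background PMF (lambda = %.2f)",
                                  x$lam_bg), ...)
  }
  graphics::abline(v = x$n_icr_bg + 0.5, lty = 2)
  invisible(x)
}
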