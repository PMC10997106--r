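#' Binarization threshold from a target false-positive probability
#'
#' Inverts the background count CDF: returns the smallest count threshold
#' `N` such that a true background pixel exceeds it with probability at most
#' `p_binarize`, together with the achieved tail probability
#' `p(white|bg) = 1 - cdf(N)`.
#'
#' @param p_binarize Requested tail probability in (0, 1).
#' @param model Background [noise_model()] (or `count_distribution`).
#' @return List with `n_icr_thresh` and `p_white_given_bg`.
#' @export
threshold_from_pvalue <- function(p_binarize, model) {
  dist <- if (inherits(model, "count_distribution")) model
          else build_distribution(model)
  n <- invert_cdf(p_binarize, dist)
  list(n_icr_thresh = n, p_white_given_bg = 1 - dist_cdf(dist, n))
}

#' Binarize an image at a count threshold
#'
#' Pixels with counts at or below the threshold are black (`FALSE`); pixels
#' strictly above are white (`TRUE`).
#'
#' @param image Integer matrix of image counts.
#' @param n_icr_thresh Count threshold.
#' @return A logical matrix of class `binary_mask` (TRUE = white), with
#'   attributes `threshold` and `n_black`.
#' @export
binarize <- function(image, n_icr_thresh) {
  mask <- image > n_icr_thresh
  structure(mask, class = c("binary_mask", class(mask)),
            threshold = n_icr_thresh, n_black = sum(!mask))
}

#' Estimate the background/signal pixel split of an image
#'
#' For every integer `N_j` from the bottom of the background support up to
#' `n_icr_bg - 1`, the number of pixels with counts at or below `N_j` is
#' proportional to `cdf(N_j | theta)` with proportionality constant `n_bg`,
#' the number of background pixels. A least-squares line through the origin
#' of (# pixels <= N_j) against `cdf(N_j)` therefore estimates `n_bg`; the
#' signal pixel count is `n_s = m - n_bg`.
#'
#' @param counts Integer image counts.
#' @param model Fitted background [noise_model()].
#' @param n_icr_bg Accepted background truncation point.
#' @return List with `n_bg`, `n_s` and the number of fit points used.
#' @export
estimate_pixel_split <- function(counts, model, n_icr_bg) {
  stopifnot(is_noise_model(model))
  counts <- as.integer(counts)
  m <- length(counts)
  dist <- build_distribution(model)
  Ns <- seq.int(dist$support[1L], n_icr_bg - 1L)
  if (length(Ns) < 3L)
    stop("need at least 3 integer levels below the background truncation")
  x <- dist_cdf(dist, Ns)
  sorted <- sort(counts)
  y <- findInterval(Ns, sorted)     # pixels with count <= N_j
  slope <- sum(x * y) / sum(x * x)
  n_bg <- as.integer(min(max(round(slope), 0), m))
  list(n_bg = n_bg, n_s = m - n_bg, n_points = length(Ns))
}

#' A priori misclassification rates of a probabilistic binarization
#'
#' Books expected pixel classifications from the fitted background model
#' alone, without ground truth. With `n_bg`/`n_s` from
#' [estimate_pixel_split()] and the binarization threshold, the expected
#' number of black background pixels is `n_bg * cdf(thresh)`; subtracting
#' it from the observed black-pixel count gives the black signal pixels,
#' and the Laplace-smoothed miss probability
#' `p(black|s) = (n(black|s) + 1) / (n_s + 2)`. These feed the standard
#' confusion-matrix rates (white = positive, signal = positive class):
#' FPR, FNR, accuracy, false discovery rate, false omission rate.
#'
#' @param counts Integer image counts.
#' @param model Fitted background [noise_model()].
#' @param n_icr_thresh Binarization threshold.
#' @param n_icr_bg Background truncation point from the fit.
#' @param p_binarize Requested tail probability (recorded in the report).
#' @return An object of class `threshold_report`.
#' @export
apriori_rates <- function(counts, model, n_icr_thresh, n_icr_bg,
                          p_binarize = NA_real_) {
  counts <- as.integer(counts)
  m <- length(counts)
  split <- estimate_pixel_split(counts, model, n_icr_bg)
  n_bg <- split$n_bg; n_s <- split$n_s
  dist <- build_distribution(model)
  cdf_t <- dist_cdf(dist, n_icr_thresh)
  p_white_bg <- 1 - cdf_t
  n_black <- sum(counts <= n_icr_thresh)
  n_black_bg <- n_bg * cdf_t
  n_black_s_raw <- n_black - n_black_bg
  clipped <- n_black_s_raw < 0 || n_black_s_raw > n_s
  if (n_black_s_raw < -1 || n_black_s_raw > n_s + 1)
    warning("expected black-background count inconsistent with the pixel ",
            "split; clipping n(black|s) into [0, n_s]")
  n_black_s <- min(max(n_black_s_raw, 0), n_s)
  p_black_s <- (n_black_s + 1) / (n_s + 2)
  fpr <- p_white_bg
  fnr <- p_black_s
  acc <- (n_bg * (1 - fpr) + n_s * (1 - fnr)) / m
  fdr_den <- n_bg * fpr + n_s * (1 - fnr)
  for_den <- n_s * fnr + n_bg * (1 - fpr)
  zero_den <- c(fdr = fdr_den == 0, for_ = for_den == 0)
  fdr <- if (fdr_den > 0) n_bg * fpr / fdr_den else 0
  for_ <- if (for_den > 0) n_s * fnr / for_den else 0
  structure(
    list(n_icr_thresh = n_icr_thresh, p_binarize = p_binarize,
         p_white_given_bg = p_white_bg, p_black_given_s = p_black_s,
         n_bg = n_bg, n_s = n_s, n_black = n_black,
         n_black_bg = n_black_bg, n_black_s = n_black_s,
         clipped = clipped, zero_denominator = zero_den,
         rates = c(FPR = fpr, FNR = fnr, ACC = acc, FDR = fdr, FOR = for_),
         m = m),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Probabilistic threshold report\n")
  cat(sprintf("  threshold      = %d counts (requested tail %s)\n",
              x$n_icr_thresh, format(x$p_binarize)))
  cat(sprintf("  p(white|bg)    = %.5f, p(black|s) = %.5f\n",
              x$p_white_given_bg, x$p_black_given_s))
  cat(sprintf("  pixels         = %d (est. %d background, %d signal)\n",
              x$m, x$n_bg, x$n_s))
  cat("  a priori rates:\n")
  print(round(x$rates, 5))
  invisible(x)
}

#' Otsu's threshold (baseline)
#'
#' Exhaustive scan over the distinct image values, maximising the
#' between-class variance (equivalently minimising the sum of within-class
#' variances) of the black (<= threshold) / white (> threshold) split.
#' Provided as a non-probabilistic baseline; it offers no control over the
#' false-positive rate.
#'
#' @param image Numeric matrix or vector.
#' @return The threshold value (counts <= threshold are black).
#' @export
otsu_threshold <- function(image) {
  x <- as.numeric(image)
  vals <- sort(unique(x))
  if (length(vals) < 2L) stop("constant image: Otsu threshold undefined")
  cand <- vals[-length(vals)]
  total_mean <- mean(x)
  n <- length(x)
  # cumulative class-0 weight and mean over candidate thresholds
  tab <- table(factor(x, levels = vals))
  cw <- cumsum(as.numeric(tab))[-length(vals)] / n
  cmu <- cumsum(as.numeric(tab) * vals)[-length(vals)] / n
  mu0 <- cmu / cw
  mu1 <- (total_mean - cmu) / (1 - cw)
  between <- cw * (1 - cw) * (mu0 - mu1)^2
  cand[which.max(between)]
}

#' Observed misclassification rates against a ground-truth mask
#'
#' Confusion-matrix rates of a binary mask (white = positive) against the
#' true signal mask (signal = positive class).
#'
#' @param mask Logical matrix, TRUE = white.
#' @param truth Logical matrix, TRUE = signal, same shape.
#' @return Named vector `c(FPR, FNR, ACC, FDR, FOR)`; rates with an empty
#'   denominator are 0.
#' @export
evaluate_vs_truth <- function(mask, truth) {
  if (is.list(truth) && !is.null(truth$mask)) truth <- truth$mask
  if (!identical(dim(mask), dim(truth)))
    stop("mask and truth have different shapes")
  tp <- sum(mask & truth); fp <- sum(mask & !truth)
  fn <- sum(!mask & truth); tn <- sum(!mask & !truth)
  safe <- function(num, den) if (den > 0) num / den else 0
  c(FPR = safe(fp, fp + tn), FNR = safe(fn, fn + tp),
    ACC = (tp + tn) / (tp + tn + fp + fn),
    FDR = safe(fp, fp + tp), FOR = safe(fn, fn + tn))
}
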