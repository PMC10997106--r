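test_that("truncation grid respects its range and quantile contracts", {
  set.seed(2)
  x <- draw_counts(22, ref_chip(), 4096)
  cand <- truncation_grid(x)
  q25 <- sort(x)[ceiling(0.25 * length(x))]
  expect_true(all(cand >= q25))
  expect_identical(max(cand), max(x))
  expect_identical(cand, sort(unique(cand)))
  # lowest candidate keeps at least 25% of the data at or below it
  expect_gte(sum(x <= cand[1L]), 0.25 * length(x))
  # thinning: 500 distinct values, cap 60, endpoints kept
  y <- rep(1:500, each = 2)
  cand2 <- truncation_grid(y, min_fraction = 0, max_candidates = 60)
  expect_length(cand2, 60)
  expect_identical(cand2[1L], 1L)
  expect_identical(cand2[60L], 500L)
  expect_error(truncation_grid(rep(7L, 100)), "identical")
})

test_that("the moment initializer follows the stated formula", {
  chip <- ref_chip()
  counts <- rep(40L, 200)  # median 40
  counts[1] <- 39L         # avoid the degenerate-grid error downstream
  lam <- truncated_mle(counts, 40L, chip)
  expect_equal(attr(lam, "lam_init"), (40 - 26.37) / (18.82 / 35.17),
               tolerance = 1e-12)
  expect_equal(attr(lam, "lam_init"), 25.47, tolerance = 1e-3)
})

test_that("truncated MLE recovers the truth on pure background", {
  chip <- ref_chip()
  set.seed(31)
  x <- draw_counts(22, chip, 4096)
  lam_hat <- as.numeric(truncated_mle(x, max(x), chip))
  # standard error from the observed information (numerical second
  # derivative of the truncated negative log-likelihood at the optimum)
  tab <- emccdpia:::tabulate_counts(x)
  eng <- emccdpia:::background_engine(chip, tab$values, max(x))
  nll <- function(l) emccdpia:::trunc_negloglik(l, eng, tab, max(x))
  h <- 1e-2
  info <- (nll(lam_hat + h) - 2 * nll(lam_hat) + nll(lam_hat - h)) / h^2
  se <- 1 / sqrt(info)
  expect_lt(abs(lam_hat - 22), 3 * se)
  # truncating at the maximum equals the untruncated MLE (cdf term ~ 1)
  pmf_ll <- function(l) {
    d <- build_distribution(noise_model(chip, l))
    -sum(log(pmax(d$pmf[match(x, d$support)], 1e-300)))
  }
  plain <- stats::optimize(pmf_ll, c(10, 40), tol = 1e-5)$minimum
  expect_equal(lam_hat, plain, tolerance = 1e-3)
})

test_that("goodness-of-fit machinery is internally consistent", {
  chip <- ref_chip()
  set.seed(32)
  x <- draw_counts(22, chip, 4096)
  lam <- as.numeric(truncated_mle(x, max(x), chip))
  p <- gof_chi2(x, max(x), noise_model(chip, lam))
  O <- attr(p, "observed"); E <- attr(p, "expected")
  expect_length(O, 5)
  expect_equal(sum(O), sum(x <= max(x)))
  expect_equal(sum(E), length(x), tolerance = 1e-6)
  # every bin expects close to a fifth of the mass
  expect_true(all(E > 0.1 * length(x) & E < 0.35 * length(x)))
  expect_equal(as.numeric(p),
               stats::pchisq(attr(p, "statistic"), df = 3,
                             lower.tail = FALSE))
  # a sample that is background + heavy low signal must be rejected
  set.seed(33)
  contaminated <- c(draw_counts(22, chip, 2800),
                    draw_counts(44, chip, 1200))
  lam_c <- as.numeric(truncated_mle(contaminated, max(contaminated), chip))
  p_c <- gof_chi2(contaminated, max(contaminated),
                  noise_model(chip, lam_c))
  expect_lt(as.numeric(p_c), 0.01)
  # too few points below the truncation: flagged, not crashed
  p_few <- gof_chi2(x[1:30], min(x[1:30]) + 1L,
                    noise_model(chip, 22))
  expect_true(is.na(p_few))
})

test_that("background fit accepts a high truncation on pure background", {
  chip <- ref_chip()
  set.seed(34)
  x <- draw_counts(22, chip, 4096)
  fit <- fit_background(x, chip)
  expect_s3_class(fit, "background_fit")
  expect_gte(fit$n_icr_bg, stats::quantile(x, 0.95))
  expect_equal(fit$lam_bg, 22, tolerance = 0.05)
  expect_equal(unname(coef(fit)), fit$lam_bg)
  # bookkeeping: n_below non-decreasing across the scan
  expect_true(all(diff(fit$scan$n_below) >= 0))
  expect_error(fit_background(rep(7L, 4096), chip))
  expect_error(fit_background(x[1:50], chip), "at least")
})

test_that("background recovery is robust to a strong signal component", {
  chip <- ref_chip()
  sc <- random_bead_scene(c(128, 128), lam_bg = 20, snr = 3, radius = 5,
                          signal_fraction = 0.30, chip = chip, seed = 35)
  fit <- fit_background(as.vector(sc$image), chip)
  expect_equal(fit$lam_bg, 20, tolerance = 0.05)
  # truncation sits below the bulk of the signal counts
  sig_median <- stats::median(sc$image[sc$truth$mask])
  expect_lt(fit$n_icr_bg, sig_median)
  # pure background at the same size: estimate moves by < 5%
  set.seed(36)
  x0 <- draw_counts(20, chip, 128 * 128)
  fit0 <- fit_background(x0, chip)
  expect_lt(abs(fit$lam_bg - fit0$lam_bg) / fit0$lam_bg, 0.05)
})

test_that("estimator error shrinks with sample size", {
  chip <- ref_chip()
  set.seed(37)
  rmse <- function(m, reps) {
    e <- replicate(reps, fit_background(draw_counts(22, chip, m),
                                        chip)$lam_bg - 22)
    sqrt(mean(e^2))
  }
  expect_gt(rmse(1024, 12) / rmse(16384, 12), 2)
})

test_that("a hopeless fit raises a condition carrying the scan", {
  chip <- ref_chip()
  set.seed(38)
  # uniform counts cannot be explained by any background parameter
  x <- sample(10:90, 4096, replace = TRUE)
  err <- tryCatch(fit_background(x, chip), pia_no_fit = function(e) e)
  expect_s3_class(err, "pia_no_fit")
  expect_true(is.data.frame(err$scan))
  expect_true(all(err$scan$gof_pvalue < 0.01, na.rm = TRUE))
})
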