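test_that("p-value threshold matches a brute-force CDF scan", {
  m <- noise_model(ref_chip(), 22)
  d <- build_distribution(m)
  th <- threshold_from_pvalue(0.01, m)
  brute <- d$support[which(1 - d$cdf <= 0.01)[1L]]
  expect_identical(th$n_icr_thresh, brute)
  expect_lte(th$p_white_given_bg, 0.01)
  expect_lte(threshold_from_pvalue(0.5, m)$n_icr_thresh, th$n_icr_thresh)
})

test_that("binarization is an exact comparison with bookkeeping", {
  img <- matrix(c(1L, 5L, 7L, 9L), 2, 2)
  mk <- binarize(img, 9L)
  expect_false(any(mk))
  expect_identical(attr(mk, "n_black"), 4L)
  mk2 <- binarize(img, 0L)
  expect_true(all(mk2))
  mk3 <- binarize(img, 6L)
  expect_identical(sum(mk3), 2L)
})

test_that("pixel-split slope through the origin recovers n_bg", {
  chip <- ref_chip()
  m <- noise_model(chip, 22)
  # counts engineered so that (# <= N) tracks 4000 * cdf(N) exactly
  d <- build_distribution(m)
  upto <- d$support[d$support <= 60]
  target <- round(4000 * emccdpia:::dist_cdf(d, upto))
  per_value <- diff(c(0, target))
  counts <- rep(upto, per_value)
  split <- estimate_pixel_split(counts, m, 50L)
  expect_identical(split$n_bg, 4000L)
  expect_error(estimate_pixel_split(counts, m, d$support[1L] + 1L),
               "at least 3")
  # simulated pure background: split finds almost everything background
  set.seed(41)
  x <- draw_counts(22, chip, 4096)
  fit <- fit_background(x, chip)
  sp <- estimate_pixel_split(x, noise_model(chip, fit$lam_bg), fit$n_icr_bg)
  expect_equal(sp$n_bg, 4096, tolerance = 0.02)
})

test_that("pixel split resolves a 15% signal admixture within 3%", {
  chip <- ref_chip()
  sc <- random_bead_scene(c(256, 256), lam_bg = 20, snr = 3, radius = 5,
                          signal_fraction = 0.15, chip = chip, seed = 42)
  fit <- fit_background(as.vector(sc$image), chip)
  sp <- estimate_pixel_split(as.vector(sc$image),
                             noise_model(chip, fit$lam_bg), fit$n_icr_bg)
  expect_equal(sp$n_bg, sum(!sc$truth$mask), tolerance = 0.03)
})

test_that("a priori rate bookkeeping balances and smooths", {
  chip <- ref_chip()
  set.seed(43)
  x <- draw_counts(22, chip, 4096)
  fit <- fit_background(x, chip)
  m <- noise_model(chip, fit$lam_bg)
  th <- threshold_from_pvalue(0.01, m)
  rep <- suppressWarnings(
    apriori_rates(x, m, th$n_icr_thresh, fit$n_icr_bg, 0.01))
  expect_identical(rep$n_bg + rep$n_s, rep$m)
  # identity n(black|bg) + n(black|s) = n_black holds pre-clipping
  if (!rep$clipped)
    expect_equal(rep$n_black_bg + rep$n_black_s, rep$n_black)
  expect_true(all(rep$rates >= 0 & rep$rates <= 1))
  expect_identical(unname(rep$rates["FPR"]), rep$p_white_given_bg)
  # all-background image: the smoothed prior path must not crash and the
  # miss probability collapses to ~1/(n_s + 2)
  expect_lte(rep$rates["FNR"], 1)
  expect_equal(unname(rep$rates["FNR"]),
               (rep$n_black_s + 1) / (rep$n_s + 2))
})

test_that("Laplace smoothing floors the miss rate on an empty signal class", {
  chip <- ref_chip()
  set.seed(44)
  x <- draw_counts(22, chip, 4096)
  fit <- fit_background(x, chip)
  m <- noise_model(chip, fit$lam_bg)
  rep <- suppressWarnings(
    apriori_rates(x, m, invert_cdf(0.01, m), fit$n_icr_bg, 0.01))
  # all-background image: the +1/+2 smoothing keeps the estimate a proper
  # probability; with no signal pixels it collapses to exactly 1/2
  expect_true(rep$p_black_given_s >= 0 && rep$p_black_given_s <= 1)
  if (rep$n_s == 0) expect_equal(rep$p_black_given_s, 0.5)
})

test_that("Otsu threshold maximises between-class variance exhaustively", {
  x <- matrix(c(rep(0L, 8), rep(10L, 8)), 4, 4)
  t0 <- otsu_threshold(x)
  expect_gte(t0, 0); expect_lt(t0, 10)
  set.seed(45)
  img <- matrix(sample(20:60, 256, replace = TRUE), 16, 16)
  brute <- function(v) {
    vals <- sort(unique(v)); cand <- vals[-length(vals)]
    wcv <- vapply(cand, function(t) {
      a <- v[v <= t]; b <- v[v > t]
      (length(a) * stats::var(a) * (length(a) - 1) / length(a)) +
        (length(b) * ifelse(length(b) > 1,
                            stats::var(b) * (length(b) - 1) / length(b), 0))
    }, numeric(1))
    cand[which.min(wcv)]
  }
  expect_equal(otsu_threshold(img), brute(as.vector(img)))
  expect_error(otsu_threshold(matrix(5, 2, 2)), "constant")
})

test_that("Otsu has no false-positive control on faint scenes", {
  chip <- ref_chip()
  sc <- random_bead_scene(c(128, 128), lam_bg = 20, snr = 1.5, radius = 5,
                          signal_fraction = 0.10, chip = chip, seed = 46)
  t_otsu <- otsu_threshold(sc$image)
  fpr_otsu <- evaluate_vs_truth(sc$image > t_otsu, sc$truth)["FPR"]
  fit <- fit_background(as.vector(sc$image), chip)
  th <- threshold_from_pvalue(0.01, noise_model(chip, fit$lam_bg))
  fpr_ours <- evaluate_vs_truth(sc$image > th$n_icr_thresh,
                                sc$truth)["FPR"]
  expect_lt(fpr_ours, 0.015)
  expect_gt(fpr_otsu, 3 * fpr_ours)
})

test_that("confusion-matrix rates behave at their extremes", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  same <- evaluate_vs_truth(truth, truth)
  expect_equal(unname(same[c("FPR", "FNR")]), c(0, 0))
  expect_equal(unname(same["ACC"]), 1)
  flipped <- evaluate_vs_truth(!truth, truth)
  expect_equal(unname(flipped["ACC"]), 0)
  set.seed(47)
  rnd <- matrix(sample(c(TRUE, FALSE), 10000, replace = TRUE), 100, 100)
  tr <- matrix(rep(c(TRUE, FALSE), each = 5000), 100, 100)
  expect_equal(unname(evaluate_vs_truth(rnd, tr)["ACC"]), 0.5,
               tolerance = 0.03)
  expect_error(evaluate_vs_truth(rnd, tr[1:50, ]), "shape")
})
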