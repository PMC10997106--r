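# Shared fixtures: the gain-100 reference chip and helpers used across tests.

ref_chip <- function() chip_params(g = 18.82, f = 35.17, r = 1.45,
                                   delta = 26.37)

ref_chip_off <- function() chip_params(f = 35.17, r = 1.45, delta = 26.37,
                                       gain_on = FALSE)

# mean/variance of a count_distribution, from its PMF
dist_moments <- function(dist) {
  mu <- sum(dist$support * dist$pmf)
  c(mean = mu, variance = sum(dist$support^2 * dist$pmf) - mu^2)
}

dist_cdf_for_test <- function(dist, n) emccdpia:::dist_cdf(dist, n)

# one bead-scene thresholding experiment: simulate, fit the background on
# the whole image, threshold at p_binarize, and report a priori vs observed
# misclassification rates
scene_experiment <- function(snr, seed, chip = ref_chip(),
                             shape = c(256, 256), lam_bg = 20,
                             signal_fraction = 0.15, radius = 5,
                             p_binarize = 0.01) {
  sc <- random_bead_scene(shape, lam_bg = lam_bg, snr = snr,
                          radius = radius,
                          signal_fraction = signal_fraction,
                          chip = chip, seed = seed)
  fit <- suppressWarnings(fit_background(as.vector(sc$image), chip,
                                         on_no_pass = "accept-best"))
  model <- noise_model(chip, fit$lam_bg)
  th <- threshold_from_pvalue(p_binarize, model)
  mask <- binarize(sc$image, th$n_icr_thresh)
  list(scene = sc, fit = fit, model = model, threshold = th, mask = mask,
       observed = evaluate_vs_truth(mask, sc$truth),
       apriori = suppressWarnings(
         apriori_rates(as.vector(sc$image), model, th$n_icr_thresh,
                       fit$n_icr_bg, p_binarize))$rates)
}

# total-variation distance between a sample and a count_distribution
sample_tv <- function(x, dist) {
  inside <- x %in% dist$support
  emp <- tabulate(match(x[inside], dist$support),
                  nbins = length(dist$support)) / length(x)
  0.5 * sum(abs(emp - dist$pmf)) + mean(!inside)
}
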