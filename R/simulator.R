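#' Draw rounded image counts from the EMCCD noise chain
#'
#' Forward-simulates the physical chain one pixel exposure at a time:
#' photoelectrons `n_ie ~ Poisson(lam)`; with the gain on and `n_ie >= 1`,
#' output electrons `n_oe ~ Gamma(shape = n_ie, scale = g)` (zero electrons
#' stay zero); with the gain off `n_oe = n_ie`; the digitised count
#' `n_ic ~ Normal(n_oe/f + delta, r^2)`; and the stored value is `n_ic`
#' rounded to the nearest integer (ties away from zero).
#'
#' @param lam Poisson parameter (non-negative).
#' @param chip A [chip_params()].
#' @param n Number of samples.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return Integer vector of length `n`.
#' @examples
#' chip <- chip_params(18.82, 35.17, 1.45, 26.37)
#' x <- draw_counts(22, chip, n = 5, seed = 1)
#' @export
draw_counts <- function(lam, chip, n, seed = NULL) {
  stopifnot(is_chip_params(chip))
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("`lam` must be a single non-negative number")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_ie <- stats::rpois(n, lam)
  if (chip$gain_on) {
    n_oe <- numeric(n)
    pos <- n_ie > 0L
    if (any(pos))
      n_oe[pos] <- stats::rgamma(sum(pos), shape = n_ie[pos], scale = chip$g)
  } else {
    n_oe <- n_ie
  }
  n_ic <- stats::rnorm(n, mean = n_oe / chip$f + chip$delta, sd = chip$r)
  round_half_away(n_ic)
}

# round to nearest integer, ties away from zero (base round() ties to even)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Convert a signal-to-noise ratio to a signal Poisson parameter
#'
#' Uses the shot-noise definition
#' \eqn{\mathrm{SNR} = \lambda_{sig} / \sqrt{\lambda_{sig} + \lambda_{bg}}}:
#' a signal pixel carries `lam_bg + lam_sig` expected photoelectrons, so the
#' denominator is the Poisson standard deviation at the signal pixel.
#' `snr_literal = TRUE` instead interprets the number as the plain ratio
#' \eqn{\lambda_{sig} / (\lambda_{sig} + \lambda_{bg})}.
#'
#' @param snr Target signal-to-noise ratio (> 0; must be < 1 in literal mode).
#' @param lam_bg Background Poisson parameter.
#' @param snr_literal Use the plain-ratio definition instead.
#' @return The signal Poisson parameter `lam_sig`.
#' @export
snr_to_lam_sig <- function(snr, lam_bg, snr_literal = FALSE) {
  stopifnot(snr > 0, lam_bg >= 0)
  if (snr_literal) {
    if (snr >= 1) stop("literal-ratio SNR must be < 1")
    return(snr * lam_bg / (1 - snr))
  }
  (snr^2 + snr * sqrt(snr^2 + 4 * lam_bg)) / 2
}

#' Specify a synthetic microscopy scene
#'
#' A scene is a uniform Poisson background of strength `lam_bg` with
#' hard-edged signal objects (disks by default, or arbitrary binary
#' templates) whose pixels receive `lam_bg + lam_sig` expected
#' photoelectrons. The signal strength may be given directly or through a
#' signal-to-noise ratio (see [snr_to_lam_sig()]).
#'
#' @param shape Integer `c(height, width)` in pixels.
#' @param objects List of objects; each is `list(center = c(row, col),
#'   radius = r)` for a disk, or `list(origin = c(row, col), template = M)`
#'   for a logical matrix stamped with its `[1,1]` element at `origin`.
#' @param lam_bg Background Poisson parameter.
#' @param lam_sig Signal Poisson parameter (additive over background).
#' @param snr Alternative to `lam_sig`.
#' @param snr_literal Passed to [snr_to_lam_sig()].
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape, objects = list(), lam_bg, lam_sig = NULL,
                       snr = NULL, snr_literal = FALSE) {
  stopifnot(length(shape) == 2L, all(shape >= 1), lam_bg >= 0)
  if (is.null(lam_sig)) {
    if (is.null(snr)) stop("give either `lam_sig` or `snr`")
    lam_sig <- snr_to_lam_sig(snr, lam_bg, snr_literal)
  } else if (!is.null(snr)) {
    stop("give only one of `lam_sig` and `snr`")
  }
  stopifnot(lam_sig >= 0)
  structure(list(shape = as.integer(shape), objects = objects,
                 lam_bg = lam_bg, lam_sig = lam_sig, snr = snr),
            class = "scene_spec")
}

# logical signal mask of a scene spec (union of objects)
scene_mask <- function(spec) {
  h <- spec$shape[1L]; w <- spec$shape[2L]
  mask <- matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (obj in spec$objects) {
    if (!is.null(obj$radius)) {
      if (obj$radius <= 0) stop("zero-area object in scene spec")
      ctr <- obj$center
      if (ctr[1L] < 1 || ctr[1L] > h || ctr[2L] < 1 || ctr[2L] > w)
        stop("object center outside the image")
      mask <- mask |
        ((rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= obj$radius^2)
    } else if (!is.null(obj$template)) {
      tm <- obj$template
      if (!any(tm)) stop("zero-area object in scene spec")
      o <- obj$origin
      ri <- o[1L] + seq_len(nrow(tm)) - 1L
      ci <- o[2L] + seq_len(ncol(tm)) - 1L
      if (min(ri) < 1 || max(ri) > h || min(ci) < 1 || max(ci) > w)
        stop("object template outside the image")
      mask[ri, ci] <- mask[ri, ci] | tm
    } else stop("each object needs a `radius` or a `template`")
  }
  mask
}

#' Render a synthetic scene through the EMCCD noise chain
#'
#' @param spec A [scene_spec()].
#' @param chip A [chip_params()].
#' @param seed Optional integer seed.
#' @return A list with `image` (integer matrix), and `truth`, itself a list
#'   with the logical signal `mask` and the per-pixel Poisson `lam_map`.
#' @examples
#' chip <- chip_params(18.82, 35.17, 1.45, 26.37)
#' spec <- scene_spec(c(64, 64), list(list(center = c(32, 32), radius = 5)),
#'                    lam_bg = 20, snr = 3)
#' sc <- render_scene(spec, chip, seed = 7)
#' mean(sc$truth$mask)
#' @export
render_scene <- function(spec, chip, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"), is_chip_params(chip))
  if (!is.null(seed)) set.seed(seed)
  mask <- scene_mask(spec)
  lam_map <- matrix(spec$lam_bg, spec$shape[1L], spec$shape[2L])
  lam_map[mask] <- spec$lam_bg + spec$lam_sig
  img <- matrix(0L, spec$shape[1L], spec$shape[2L])
  img[!mask] <- draw_counts(spec$lam_bg, chip, sum(!mask))
  if (any(mask))
    img[mask] <- draw_counts(spec$lam_bg + spec$lam_sig, chip, sum(mask))
  list(image = img, truth = list(mask = mask, lam_map = lam_map))
}

#' Random bead scene covering a target signal fraction
#'
#' Convenience generator: drops disks of fixed radius at uniformly random
#' centers until the union of signal pixels reaches `signal_fraction` of the
#' image (or `max_beads` is hit), then renders the scene.
#'
#' @param shape `c(height, width)`.
#' @param lam_bg,snr,snr_literal Scene illumination, as in [scene_spec()].
#' @param radius Bead radius in pixels.
#' @param signal_fraction Target fraction of signal pixels.
#' @param chip A [chip_params()].
#' @param seed Optional integer seed.
#' @param max_beads Safety cap on the number of disks.
#' @return As [render_scene()], plus the `spec` used.
#' @export
random_bead_scene <- function(shape, lam_bg, snr, radius = 5,
                              signal_fraction = 0.15, chip, seed = NULL,
                              snr_literal = FALSE, max_beads = 2000) {
  if (!is.null(seed)) set.seed(seed)
  h <- shape[1L]; w <- shape[2L]
  objects <- list()
  mask <- matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  pad <- ceiling(radius)
  while (mean(mask) < signal_fraction && length(objects) < max_beads) {
    ctr <- c(sample(seq(1 + pad, h - pad), 1L),
             sample(seq(1 + pad, w - pad), 1L))
    objects[[length(objects) + 1L]] <- list(center = ctr, radius = radius)
    mask <- mask | ((rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= radius^2)
  }
  spec <- scene_spec(shape, objects, lam_bg = lam_bg, snr = snr,
                     snr_literal = snr_literal)
  out <- render_scene(spec, chip)
  out$spec <- spec
  out
}

#' Simulate calibration image stacks
#'
#' Produces, for each illumination level, a stack of independent frames at
#' constant per-pixel Poisson parameter, in both gain-on and gain-off mode —
#' the raw material of the mean-variance calibration.
#'
#' @param chip A [chip_params()] (its `g` is used for the gain-on stacks).
#' @param lam_levels Numeric vector of Poisson parameters, one per level.
#' @param n_frames Frames per stack (>= 2).
#' @param shape `c(height, width)` of each frame.
#' @param seed Optional integer seed.
#' @param lam_profile Optional matrix of multiplicative per-pixel factors
#'   (e.g. a smooth illumination profile); default uniform.
#' @return A list with `levels` and two lists of `height x width x n_frames`
#'   arrays, `gain_on` and `gain_off`.
#' @export
make_calibration_stacks <- function(chip, lam_levels, n_frames, shape,
                                    seed = NULL, lam_profile = NULL) {
  stopifnot(is_chip_params(chip), n_frames >= 2)
  if (length(lam_levels) == 0L) stop("`lam_levels` must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  h <- shape[1L]; w <- shape[2L]
  if (is.null(lam_profile)) lam_profile <- matrix(1, h, w)
  stopifnot(nrow(lam_profile) == h, ncol(lam_profile) == w)
  chip_off <- chip_params(f = chip$f, r = chip$r, delta = chip$delta,
                          gain_on = FALSE)
  one_stack <- function(lam, which_chip) {
    arr <- array(0L, dim = c(h, w, n_frames))
    lam_px <- lam * lam_profile
    uniform <- all(lam_px == lam_px[1L])
    for (k in seq_len(n_frames)) {
      arr[, , k] <- if (uniform) {
        matrix(draw_counts(lam_px[1L], which_chip, h * w), h, w)
      } else {
        # group pixels by identical lambda to keep the draw vectorised
        out <- matrix(0L, h, w)
        for (lv in unique(as.vector(lam_px))) {
          sel <- lam_px == lv
          out[sel] <- draw_counts(lv, which_chip, sum(sel))
        }
        out
      }
    }
    arr
  }
  list(levels = lam_levels,
       gain_on = lapply(lam_levels, one_stack, which_chip = chip),
       gain_off = lapply(lam_levels, one_stack, which_chip = chip_off))
}
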