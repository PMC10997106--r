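#' Camera chip parameters
#'
#' Bundle the four constants that characterise an EMCCD camera chip: the
#' electron-multiplication gain `g` (mean electrons out per input electron),
#' the analog-to-digital conversion factor `f` (electrons per image count),
#' the readout noise standard deviation `r` (image counts) and the camera
#' offset `delta` (image counts). A flag records whether the
#' electron-multiplication register is active; with the gain off the
#' multiplication stage is skipped entirely and `g` is ignored.
#'
#' @param g Electron-multiplication gain, dimensionless. Must be positive
#'   when `gain_on = TRUE`.
#' @param f Analog-to-digital conversion factor, electrons per image count
#'   (strictly positive).
#' @param r Readout noise standard deviation in image counts (non-negative).
#' @param delta Camera offset in image counts.
#' @param gain_on Logical; is the electron-multiplication register active?
#' @return An object of class `chip_params`.
#' @examples
#' chip <- chip_params(g = 18.82, f = 35.17, r = 1.45, delta = 26.37)
#' chip
#' @export
chip_params <- function(g = NA_real_, f, r, delta, gain_on = !is.na(g)) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f), f > 0)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  stopifnot(is.logical(gain_on), length(gain_on) == 1L, !is.na(gain_on))
  if (gain_on) {
    stopifnot(is.numeric(g), length(g) == 1L, is.finite(g), g > 0)
  }
  structure(
    list(g = as.numeric(g), f = as.numeric(f), r = as.numeric(r),
         delta = as.numeric(delta), gain_on = gain_on),
    class = "chip_params")
}

#' @export
print.chip_params <- function(x, ...) {
  cat("EMCCD chip parameters (gain",
      if (x$gain_on) "on):" else "off):", "\n")
  cat(sprintf("  g     = %s\n", if (x$gain_on) format(x$g) else "-"))
  cat(sprintf("  f     = %s e-/count\n", format(x$f)))
  cat(sprintf("  r     = %s counts\n", format(x$r)))
  cat(sprintf("  delta = %s counts\n", format(x$delta)))
  invisible(x)
}

is_chip_params <- function(x) inherits(x, "chip_params")

#' EMCCD noise model
#'
#' A noise model is a chip parameter set together with a Poisson illumination
#' parameter `lam` (the expected number of photoelectrons per pixel per
#' exposure). It is the full parameter vector of every count-distribution
#' evaluation in the package.
#'
#' @param chip A [chip_params()] object.
#' @param lam Poisson parameter, non-negative.
#' @return An object of class `noise_model`.
#' @examples
#' m <- noise_model(chip_params(18.82, 35.17, 1.45, 26.37), lam = 22)
#' emccd_moments(m)
#' @export
noise_model <- function(chip, lam) {
  stopifnot(is_chip_params(chip))
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam >= 0)
  structure(list(chip = chip, lam = as.numeric(lam)), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("EMCCD noise model: lambda = %s\n", format(x$lam)))
  print(x$chip)
  invisible(x)
}

is_noise_model <- function(x) inherits(x, "noise_model")

#' Read or write a noise model / chip as JSON
#'
#' The on-disk format is a flat JSON object
#' `{"g":..., "f":..., "r":..., "delta":..., "lambda":..., "gain_on":true}`;
#' `lambda` may be absent, in which case only the chip is recovered.
#'
#' @param x A `chip_params` or `noise_model` object.
#' @param path File path.
#' @return `read_chip_json()` returns a `noise_model` when the file carries a
#'   `lambda` field and a `chip_params` otherwise.
#' @export
write_chip_json <- function(x, path) {
  if (is_noise_model(x)) {
    obj <- c(x$chip[c("g", "f", "r", "delta")],
             list(lambda = x$lam, gain_on = x$chip$gain_on))
  } else if (is_chip_params(x)) {
    obj <- c(x[c("g", "f", "r", "delta")], list(gain_on = x$gain_on))
  } else stop("`x` must be a chip_params or noise_model object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chip_json
#' @export
read_chip_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- if (is.null(obj$g) || !isTRUE(obj$gain_on)) NA_real_ else obj$g
  chip <- chip_params(g = g, f = obj$f, r = obj$r, delta = obj$delta,
                      gain_on = isTRUE(obj$gain_on))
  if (!is.null(obj$lambda)) noise_model(chip, obj$lambda) else chip
}
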