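#' Read a grayscale image preserving integer counts
#'
#' Reads 8/16-bit grayscale TIFF (single frame or stack) or PNG. TIFF data
#' are read with `as.is = TRUE` so the stored integer counts come back
#' bit-exactly; PNG values (always scaled to `[0, 1]` by the reader) are
#' mapped back to 8- or 16-bit integers from the file's bit depth. RGB or
#' floating-point input is rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer matrix (or list of matrices for a multi-frame TIFF).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE)
    check1 <- function(m) {
      if (identical(attr(m, "bits.per.sample"), 32L))
        stop("unsupported format: 32-bit (floating-point) TIFF sample ",
             "data; 8/16-bit integer grayscale required")
      if (length(dim(m)) == 3L)
        stop("unsupported format: multi-channel (RGB) TIFF with ",
             dim(m)[3L], " channels; grayscale required")
      if (is.double(m) && any(m != round(m)))
        stop("unsupported format: floating-point TIFF sample data; ",
             "integer grayscale required")
      m <- matrix(as.integer(m), nrow(m), ncol(m))
      m
    }
    img <- lapply(img, check1)
    if (length(img) == 1L) img[[1L]] else img
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L)
      stop("unsupported format: multi-channel (RGB) PNG; grayscale required")
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    m <- round_half_away(img * (2^depth - 1))
    matrix(m, nrow(img), ncol(img))
  } else stop("unsupported image format: .", ext)
}

#' Write an integer image as 16-bit grayscale TIFF (or 8-bit PNG)
#'
#' @param image Integer matrix; values must fit the bit depth.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @export
write_image <- function(image, path, bits = 16) {
  ext <- tolower(tools::file_ext(path))
  if (any(image < 0)) stop("negative counts cannot be written")
  if (ext %in% c("tif", "tiff")) {
    maxv <- 2^bits - 1
    if (any(image > maxv)) stop("counts exceed the ", bits, "-bit range")
    tiff::writeTIFF(image / maxv, path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (any(image > 255)) stop("counts exceed the 8-bit PNG range")
    png::writePNG(image / 255, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Split an image into tiles
#'
#' Row-major tiling into `tile_size` x `tile_size` tiles (labels `{row,
#' column}` starting at 1). Edge remainders at least `min_edge` pixels wide
#' become their own (smaller) tiles; thinner remainders are merged into the
#' neighbouring tile. An image smaller than `tile_size` is one tile.
#'
#' @param image Integer matrix.
#' @param tile_size Tile side in pixels.
#' @param min_edge Minimal width of a standalone edge tile.
#' @return An object of class `tile_grid`: data frame with `row`, `col`,
#'   `r0`, `r1`, `c0`, `c1` plus attributes `shape` and `tile_size`.
#' @export
tile_image <- function(image, tile_size = 64, min_edge = 16) {
  tile_size <- as.integer(tile_size)
  min_edge <- as.integer(min_edge)
  cuts <- function(extent) {
    if (extent <= tile_size) return(data.frame(lo = 1L, hi = extent))
    starts <- seq.int(1L, extent, by = tile_size)
    ends <- pmin(starts + tile_size - 1L, extent)
    k <- length(starts)
    if (k > 1L && (ends[k] - starts[k] + 1L) < min_edge) {
      ends[k - 1L] <- extent
      starts <- starts[-k]; ends <- ends[-k]
    }
    data.frame(lo = starts, hi = ends)
  }
  rc <- cuts(nrow(image)); cl <- cuts(ncol(image))
  grid <- expand.grid(row = seq_len(nrow(rc)), col = seq_len(nrow(cl)))
  grid <- grid[order(grid$row, grid$col), ]
  grid$r0 <- rc$lo[grid$row]; grid$r1 <- rc$hi[grid$row]
  grid$c0 <- cl$lo[grid$col]; grid$c1 <- cl$hi[grid$col]
  rownames(grid) <- NULL
  structure(grid, class = c("tile_grid", "data.frame"),
            shape = dim(image), tile_size = tile_size)
}

#' Pipeline configuration
#'
#' Defaults follow the method's standard operating point: goodness-of-fit
#' and binarization p-value thresholds of 0.01, 64-pixel tiles, and a
#' region-size gap of 1.
#'
#' @param p_gof Goodness-of-fit acceptance level for the background scan.
#' @param p_binarize Target false-positive probability of the binarization.
#' @param tile_size Tile side in pixels.
#' @param allowed_gap_length Segmentation gap parameter.
#' @param min_edge Minimal standalone edge-tile width.
#' @return A list of class `pia_config`.
#' @export
pia_config <- function(p_gof = 0.01, p_binarize = 0.01, tile_size = 64,
                       allowed_gap_length = 1, min_edge = 16) {
  stopifnot(p_gof > 0, p_gof < 1, p_binarize > 0, p_binarize < 1,
            tile_size >= 1)
  structure(list(p_gof = p_gof, p_binarize = p_binarize,
                 tile_size = tile_size,
                 allowed_gap_length = allowed_gap_length,
                 min_edge = min_edge),
            class = "pia_config")
}

#' Run the full photophysical analysis pipeline on one image
#'
#' Tiles the image, fits the background strength per tile (truncated MLE
#' with goodness-of-fit truncation selection), converts the target
#' false-positive probability into a per-tile count threshold, binarizes,
#' books per-tile a priori misclassification rates, stitches the global
#' mask, and segments it with per-region background p-values scored against
#' the per-tile background strengths. Tiles where no truncation passes the
#' goodness-of-fit test are flagged; their threshold and background
#' strength are borrowed from the nearest passing tile and they are
#' excluded from the aggregated rates.
#'
#' @param image Integer matrix of counts, or a path readable by
#'   [read_image()].
#' @param chip A [chip_params()] object or a path to a chip JSON.
#' @param config A [pia_config()].
#' @return An object of class `pia_result`: per-tile table `tiles`, global
#'   `mask`, `segmentation` (with `p_seg` per region), aggregated
#'   `rates` (pixel-weighted over passing tiles), the `lam_map`, `config`
#'   and failed-tile count.
#' @export
run_pipeline <- function(image, chip, config = pia_config()) {
  if (is.character(image)) image <- read_image(image)
  if (is.character(chip)) {
    chip <- read_chip_json(chip)
    if (is_noise_model(chip)) chip <- chip$chip
  }
  stopifnot(is.matrix(image), is_chip_params(chip),
            inherits(config, "pia_config"))
  grid <- tile_image(image, config$tile_size, config$min_edge)
  nt <- nrow(grid)
  tiles <- data.frame(row = grid$row, col = grid$col,
                      lambda_bg = NA_real_, n_icr_bg = NA_integer_,
                      gof_pvalue = NA_real_, n_icr_thresh = NA_integer_,
                      p_white_given_bg = NA_real_, n_bg = NA_integer_,
                      n_s = NA_integer_, passed = FALSE,
                      FPR = NA_real_, FNR = NA_real_, ACC = NA_real_,
                      FDR = NA_real_, FOR = NA_real_)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  lam_map <- matrix(NA_real_, nrow(image), ncol(image))
  reports <- vector("list", nt)
  for (i in seq_len(nt)) {
    px <- image[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]]
    fit <- tryCatch(fit_background(as.vector(px), chip,
                                   p_gof = config$p_gof),
                    pia_no_fit = function(e) e)
    if (inherits(fit, "pia_no_fit")) next
    tiles$passed[i] <- TRUE
    tiles$lambda_bg[i] <- fit$lam_bg
    tiles$n_icr_bg[i] <- fit$n_icr_bg
    tiles$gof_pvalue[i] <-
      fit$scan$gof_pvalue[fit$scan$truncation_point == fit$n_icr_bg]
    model <- noise_model(chip, fit$lam_bg)
    th <- threshold_from_pvalue(config$p_binarize, model)
    rep_i <- apriori_rates(as.vector(px), model, th$n_icr_thresh,
                           fit$n_icr_bg, p_binarize = config$p_binarize)
    tiles$n_icr_thresh[i] <- th$n_icr_thresh
    tiles$p_white_given_bg[i] <- th$p_white_given_bg
    tiles$n_bg[i] <- rep_i$n_bg
    tiles$n_s[i] <- rep_i$n_s
    tiles[i, c("FPR", "FNR", "ACC", "FDR", "FOR")] <- as.list(rep_i$rates)
    reports[[i]] <- rep_i
    mask[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]] <-
      px > th$n_icr_thresh
    lam_map[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]] <- fit$lam_bg
  }
  n_failed <- sum(!tiles$passed)
  if (all(!tiles$passed))
    stop("no tile passed the goodness-of-fit test; cannot threshold")
  if (n_failed > 0) {
    ctr_r <- (grid$r0 + grid$r1) / 2
    ctr_c <- (grid$c0 + grid$c1) / 2
    for (i in which(!tiles$passed)) {
      ok <- which(tiles$passed)
      j <- ok[which.min((ctr_r[ok] - ctr_r[i])^2 + (ctr_c[ok] - ctr_c[i])^2)]
      px <- image[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]]
      mask[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]] <-
        px > tiles$n_icr_thresh[j]
      lam_map[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]] <-
        tiles$lambda_bg[j]
      tiles$n_icr_thresh[i] <- tiles$n_icr_thresh[j]
    }
  }
  attr(lam_map, "chip") <- chip
  seg <- clean_mask(mask, image, config$allowed_gap_length)
  seg <- score_regions(seg, image, lam_map = lam_map)
  w <- (grid$r1 - grid$r0 + 1) * (grid$c1 - grid$c0 + 1) * tiles$passed
  agg <- vapply(c("FPR", "FNR", "ACC", "FDR", "FOR"), function(nm)
    stats::weighted.mean(tiles[[nm]], w, na.rm = TRUE), numeric(1))
  structure(
    list(tiles = tiles, grid = grid, mask = mask, lam_map = lam_map,
         segmentation = seg, rates = agg, reports = reports,
         n_failed_tiles = n_failed, config = config, chip = chip),
    class = "pia_result")
}

#' @export
print.pia_result <- function(x, ...) {
  cat("Photophysical image analysis result\n")
  cat(sprintf("  tiles          = %d (%d failed goodness-of-fit)\n",
              nrow(x$tiles), x$n_failed_tiles))
  cat(sprintf("  lambda_bg      : median %.3f (range %.3f - %.3f)\n",
              stats::median(x$tiles$lambda_bg, na.rm = TRUE),
              min(x$tiles$lambda_bg, na.rm = TRUE),
              max(x$tiles$lambda_bg, na.rm = TRUE)))
  cat(sprintf("  white fraction = %.4f\n", mean(x$mask)))
  cat(sprintf("  regions        = %d\n", length(x$segmentation$regions)))
  cat("  aggregated a priori rates (pixel-weighted over passing tiles):\n")
  print(round(x$rates, 5))
  invisible(x)
}

#' @export
summary.pia_result <- function(object, ...) {
  print(object)
  cat("Per-tile table:\n")
  print(object$tiles, row.names = FALSE)
  invisible(object$tiles)
}

#' Export a pipeline result as a JSON report
#'
#' @param result A [run_pipeline()] result.
#' @param path Output path; when NULL the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_pia_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pia_result"))
  obj <- list(
    config = unclass(result$config),
    chip = result$chip[c("g", "f", "r", "delta", "gain_on")],
    n_failed_tiles = result$n_failed_tiles,
    rates = as.list(result$rates),
    tiles = result$tiles,
    regions = region_table(result$segmentation))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows", na = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
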