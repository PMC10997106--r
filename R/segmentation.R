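#' Connected components of one color of a binary mask
#'
#' Labels the connected components of the white (`TRUE`) or black (`FALSE`)
#' pixels of a mask. The default connectivities form the standard
#' complementary pair — 8-connectivity for white objects, 4-connectivity for
#' black background — which avoids the topological paradox of both colors
#' being diagonally connected. Labels are assigned in row-major order of
#' each region's first pixel.
#'
#' @param mask Logical matrix (TRUE = white).
#' @param color `"white"` or `"black"`.
#' @param connectivity 4 or 8; default 8 for white, 4 for black.
#' @return A list of regions, each a list with `label`, `pixels` (two-column
#'   row/col matrix), `size` and `color`. The label matrix (0 = other color)
#'   is attached as attribute `labels`.
#' @export
label_components <- function(mask, color = c("white", "black"),
                             connectivity = NULL) {
  color <- match.arg(color)
  if (is.null(connectivity)) connectivity <- if (color == "white") 8L else 4L
  stopifnot(connectivity %in% c(4L, 8L))
  target <- if (color == "white") mask else !mask
  h <- nrow(target); w <- ncol(target)
  idx <- which(target)                       # column-major linear indices
  labmat <- matrix(0L, h, w)
  if (!length(idx)) return(structure(list(), labels = labmat))
  # edges between adjacent target pixels, built by shifted comparisons
  edges <- list()
  pair <- function(a, b) cbind(a, b)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  in_target <- function(r, c) {
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    lin <- (c - 1L) * h + r
    ok[ok] <- target[lin[ok]]
    ok
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  for (o in offs) {
    r2 <- rr + o[1L]; c2 <- cc + o[2L]
    ok <- in_target(r2, c2)
    if (any(ok))
      edges[[length(edges) + 1L]] <- pair(idx[ok], (c2[ok] - 1L) * h + r2[ok])
  }
  vid <- match(idx, idx)                     # vertices 1..n in idx order
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(match(e[, 1L], idx),
                                    match(e[, 2L], idx)))
  }
  comp <- igraph::components(g)$membership
  # order components by row-major position of their first pixel
  rowmajor <- (rr - 1L) * w + cc
  first_pos <- tapply(rowmajor, comp, min)
  relabel <- match(comp, as.integer(names(sort(first_pos))))
  labmat[idx] <- relabel
  regions <- lapply(sort(unique(relabel)), function(k) {
    sel <- relabel == k
    list(label = k, pixels = cbind(row = rr[sel], col = cc[sel]),
         size = sum(sel), color = color)
  })
  structure(regions, labels = labmat)
}

#' Gap-rule size cut for one color's regions
#'
#' Walks the ascending list of unique region sizes and stops at the first
#' gap between consecutive sizes that exceeds `allowed_gap_length`; the size
#' just before that gap is the cut — regions at or below it are treated as
#' noise and flipped. When no gap qualifies, the whole size list is one
#' noise cluster and `Inf` (flip everything) is returned.
#'
#' @param sizes Region sizes (any order).
#' @param allowed_gap_length Size gap that separates noise from objects.
#' @return The cut size, or `Inf` for flip-all.
#' @export
gap_size_threshold <- function(sizes, allowed_gap_length = 1) {
  if (!length(sizes)) stop("empty size list")
  u <- sort(unique(sizes))
  if (length(u) == 1L) return(Inf)
  gaps <- diff(u)
  hit <- which(gaps > allowed_gap_length)
  if (!length(hit)) return(Inf)
  u[hit[1L]]
}

#' Clean a binary mask by the gap-rule size filter
#'
#' Labels white regions (8-connectivity) and black regions
#' (4-connectivity) of the input mask, derives both size cuts with
#' [gap_size_threshold()] from the input mask, and flips all sub-cut
#' regions of both colors simultaneously in a single pass (no iteration).
#' A color with a single region is left untouched: with nothing to compare
#' against, the gap rule cannot distinguish noise from object, and flipping
#' an image's only background (or only object) region is never intended.
#'
#' @param mask Logical matrix (TRUE = white), e.g. from [binarize()].
#' @param image Optional integer matrix of the underlying counts; when given,
#'   each surviving white region records its summed counts.
#' @param allowed_gap_length Gap parameter of the size rule.
#' @return An object of class `segmentation_result`: the cleaned `mask`, the
#'   surviving white `regions` (relabeled, with `sum_counts` if `image` was
#'   given), the label matrix `labels`, and the cuts `w_white`, `w_black`.
#' @export
clean_mask <- function(mask, image = NULL, allowed_gap_length = 1) {
  white <- label_components(mask, "white")
  black <- label_components(mask, "black")
  cleaned <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  flip <- function(regions, cut) {
    for (rg in regions)
      if (rg$size <= cut)
        cleaned[rg$pixels] <<- !cleaned[rg$pixels]
  }
  w_white <- w_black <- NA_real_
  if (length(white) > 1L) {
    w_white <- gap_size_threshold(vapply(white, `[[`, 0, "size"),
                                  allowed_gap_length)
    flip(white, w_white)
  }
  if (length(black) > 1L) {
    w_black <- gap_size_threshold(vapply(black, `[[`, 0, "size"),
                                  allowed_gap_length)
    flip(black, w_black)
  }
  relab <- label_components(cleaned, "white")
  if (!is.null(image)) {
    relab <- lapply(relab, function(rg) {
      rg$sum_counts <- sum(image[rg$pixels])
      rg
    })
  }
  structure(
    list(mask = cleaned, regions = relab,
         labels = attr(label_components(cleaned, "white"), "labels"),
         w_white = w_white, w_black = w_black,
         allowed_gap_length = allowed_gap_length),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation result\n")
  cat(sprintf("  white regions  = %d (size cut w_white = %s)\n",
              length(x$regions), format(x$w_white)))
  cat(sprintf("  black size cut = %s, gap = %s\n", format(x$w_black),
              format(x$allowed_gap_length)))
  if (length(x$regions)) {
    sz <- vapply(x$regions, `[[`, 0, "size")
    cat(sprintf("  region sizes   : %s\n",
                paste(utils::head(sort(sz), 10), collapse = " ")))
  }
  invisible(x)
}

#' Background p-values for segmented regions
#'
#' Attaches to every surviving white region the p-value that its summed
#' image counts could have arisen from pure background pixels
#' ([region_sum_pvalue()]). With a per-pixel `lam_map` (tiled pipelines),
#' a region's background strength is the mean of the map over its pixels
#' (area-weighted across tiles); regions touching more than one distinct
#' value are flagged `spans_tiles`.
#'
#' @param result A [clean_mask()] result.
#' @param image Integer matrix of image counts.
#' @param model Background [noise_model()] (uniform illumination), or NULL
#'   when `lam_map` is given.
#' @param lam_map Optional per-pixel background-strength matrix.
#' @return `result` with `p_seg` (and `sum_counts`) filled in per region.
#' @export
score_regions <- function(result, image, model = NULL, lam_map = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  if (is.null(model) && is.null(lam_map))
    stop("give a background `model` or a `lam_map`")
  chip <- if (!is.null(model)) model$chip else attr(lam_map, "chip")
  result$regions <- lapply(result$regions, function(rg) {
    rg$sum_counts <- sum(image[rg$pixels])
    if (is.null(lam_map)) {
      rg_model <- model
      rg$spans_tiles <- FALSE
    } else {
      lams <- lam_map[rg$pixels]
      rg$spans_tiles <- length(unique(lams)) > 1L
      rg_model <- noise_model(chip, mean(lams))
    }
    rg$p_seg <- region_sum_pvalue(rg$sum_counts, rg$size, rg_model)
    rg
  })
  result
}

#' Region table of a segmentation result
#'
#' @param result A `segmentation_result` (ideally after [score_regions()]).
#' @return Data frame with label, size, centroid, summed counts and `p_seg`.
#' @export
region_table <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  do.call(rbind, lapply(result$regions, function(rg) {
    data.frame(label = rg$label, size = rg$size,
               centroid_row = mean(rg$pixels[, "row"]),
               centroid_col = mean(rg$pixels[, "col"]),
               sum_counts = if (!is.null(rg$sum_counts)) rg$sum_counts
                            else NA_real_,
               p_seg = if (!is.null(rg$p_seg)) rg$p_seg else NA_real_)
  }))
}
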