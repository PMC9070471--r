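.as_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) stop("expected a height x width x 3 RGB array", call. = FALSE)
  if (min(image) < 0 || max(image) > 255) stop("channel values must be in [0, 255]", call. = FALSE)
  image
}

#' Tissue mask from the blue channel
#'
#' The blue channel has the highest contrast between stained tissue and the
#' blank slide. The modal blue value corresponds to the bright blank slide,
#' so every pixel strictly below the mode is tissue. The raw mask is then
#' cleaned morphologically: connected components smaller than
#' `min_fragment_px` (stray fragments off the section) are removed and
#' interior holes smaller than `max_hole_px` are filled. Modal ties are
#' broken towards the brightest value, since the background is the bright
#' blank slide.
#'
#' @param image RGB array (0-255).
#' @param min_fragment_px Smallest tissue fragment kept, in pixels.
#' @param max_hole_px Largest interior hole filled, in pixels.
#' @return Logical matrix, `TRUE` = tissue. An image of a single colour has
#'   no sub-modal pixels and yields an empty mask with a warning.
#' @export
tissue_mask <- function(image, min_fragment_px = 64, max_hole_px = 256) {
  image <- .as_rgb(image)
  b <- image[, , 3]
  counts <- tabulate(as.integer(b) + 1L, nbins = 256L)
  mode_b <- max(which(counts == max(counts))) - 1L  # ties -> brightest
  mask <- b < mode_b
  if (!any(mask)) {
    warning("no pixels below the modal blue value; empty tissue mask")
    return(mask)
  }
  # drop small fragments
  lab <- EBImage::bwlabel(mask * 1)
  sz <- tabulate(lab[lab > 0])
  mask <- matrix(lab > 0 & sz[pmax(lab, 1)] >= min_fragment_px,
                 nrow(mask), ncol(mask))
  # fill small interior holes: background components not touching the border
  inv <- EBImage::bwlabel((!mask) * 1)
  border_labels <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
  isz <- tabulate(inv[inv > 0])
  hole <- inv > 0 & !(inv %in% border_labels) & isz[pmax(inv, 1)] <= max_hole_px
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Collagen index map
#'
#' Weighted-RGB figure of merit discriminating collagen (light pink through
#' magenta to dark red under van Gieson) from other tissue:
#' `R/50 - G/20 + B/30`, evaluated on raw 8-bit channel values. Stained
#' collagen hues score above 1; non-collagen tissue scores below. A pure
#' per-pixel function: permuting pixels permutes the map identically.
#'
#' @param image RGB array (0-255).
#' @return Numeric matrix of indices.
#' @export
collagen_index_map <- function(image) {
  image <- .as_rgb(image)
  image[, , 1] / 50 - image[, , 2] / 20 + image[, , 3] / 30
}

#' Elastin index map
#'
#' Elastin stains grey-to-black under Verhoeff-van Gieson, so the three
#' channels are equally weighted into a darkness index on [0, 1]:
#' `1 - (R + G + B) / 765`. Black scores 1, white 0; the nominal
#' elastin/non-elastin boundary is 0.5.
#'
#' @param image RGB array (0-255).
#' @return Numeric matrix of indices in [0, 1].
#' @export
elastin_index_map <- function(image) {
  image <- .as_rgb(image)
  1 - (image[, , 1] + image[, , 2] + image[, , 3]) / 765
}

#' Stained-area fraction from an index map
#'
#' The stained fraction is the count of masked pixels whose index strictly
#' exceeds the threshold, divided by the count of pixels in the tissue
#' mask. Ratios of pixel counts need no spatial calibration. Boundary
#' pixels (index exactly at the threshold) count as unstained.
#'
#' @param index_map Numeric matrix from [collagen_index_map()] or
#'   [elastin_index_map()].
#' @param mask Logical tissue mask of the same shape.
#' @param threshold Index threshold (1.0 nominal for collagen, 0.5 for
#'   elastin).
#' @param kind Optional label stored in the result.
#' @return Object of class `stain_quantification`: `fraction`,
#'   `threshold_used`, `kind`, `n_tissue_px`.
#' @export
quantify_stain <- function(index_map, mask, threshold, kind = NA_character_) {
  stopifnot(all(dim(index_map) == dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty tissue mask", call. = FALSE)
  structure(list(fraction = sum(index_map[mask] > threshold) / n,
                 threshold_used = threshold, kind = kind, n_tissue_px = n),
            class = "stain_quantification")
}

#' Collagen fraction of a Picrosirius-Red section
#'
#' PSR-stained collagen is saturated red; a masked pixel is classified
#' collagen when its red channel dominates both green and blue by at least
#' `margin`.
#'
#' @param psr_image RGB array (0-255).
#' @param mask Logical tissue mask.
#' @param margin Red-dominance margin in 8-bit counts (default 30).
#' @return Fraction of masked pixels classified red-dominant.
#' @export
psr_collagen_fraction <- function(psr_image, mask, margin = 30) {
  psr_image <- .as_rgb(psr_image)
  if (sum(mask) == 0) stop("empty tissue mask", call. = FALSE)
  r <- psr_image[, , 1]; g <- psr_image[, , 2]; b <- psr_image[, , 3]
  red <- r > g + margin & r > b + margin
  sum(red[mask]) / sum(mask)
}

#' Calibrate the collagen threshold against a target fraction
#'
#' The collagen threshold is nominally 1.0 but is calibrated per tissue so
#' the VVG collagen area agrees with the area measured on the adjacent
#' Picrosirius-Red section. The threshold is searched on a grid around the
#' nominal value; the returned threshold minimizes the absolute gap to
#' `target_fraction`, with ties resolved towards the nominal value and then
#' towards the smallest threshold.
#'
#' @param vvg_image RGB array of the VVG section.
#' @param mask Logical tissue mask.
#' @param target_fraction Target collagen fraction (from PSR), in (0, 1).
#' @param nominal Nominal threshold (default 1.0).
#' @param span Half-width of the search grid (default 0.75).
#' @param step Grid step (default 0.01).
#' @return The calibrated threshold. If the index map is flat the target is
#'   unreachable and the nominal threshold is returned with a warning.
#' @export
calibrate_collagen_threshold <- function(vvg_image, mask, target_fraction,
                                         nominal = 1.0, span = 0.75,
                                         step = 0.01) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  imap <- collagen_index_map(vvg_image)
  vals <- imap[mask]
  if (length(vals) == 0) stop("empty tissue mask", call. = FALSE)
  if (diff(range(vals)) == 0) {
    warning("flat collagen index map; target unreachable, returning nominal")
    return(nominal)
  }
  grid <- seq(nominal - span, nominal + span, by = step)
  frac <- vapply(grid, function(t) mean(vals > t), 0)
  gap <- abs(frac - target_fraction)
  cand <- which(gap <= min(gap) + 1e-12)
  cand <- cand[abs(grid[cand] - nominal) <= min(abs(grid[cand] - nominal)) + 1e-12]
  grid[cand[1]]
}

#' Threshold-variation error of a stained-area fraction
#'
#' Errors are estimated by varying the threshold either side of its
#' calibrated value by `delta`: regions whose index histogram is dense near
#' the threshold are sensitive and get large errors, sparse ones small
#' errors. Since the fraction is non-increasing in the threshold, both
#' errors are non-negative: `err_high = fraction(threshold - delta) -
#' fraction(threshold)` and `err_low = fraction(threshold) -
#' fraction(threshold + delta)`.
#'
#' @param index_map,mask,threshold As in [quantify_stain()].
#' @param delta Threshold variation (default 0.05).
#' @return Named numeric vector `c(err_low, err_high)`.
#' @export
threshold_sensitivity_error <- function(index_map, mask, threshold, delta = 0.05) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  f <- function(t) quantify_stain(index_map, mask, t)$fraction
  c(err_low = f(threshold) - f(threshold + delta),
    err_high = f(threshold - delta) - f(threshold))
}

#' Quantify collagen and elastin on one section
#'
#' Convenience wrapper running the full per-section chain: tissue mask,
#' collagen and elastin index maps, optional threshold calibration against
#' a paired PSR section, fraction estimates and threshold-variation errors.
#'
#' @param vvg_image RGB array of the VVG section.
#' @param psr_image Optional paired Picrosirius-Red RGB array; when given,
#'   the collagen threshold is calibrated so the VVG fraction matches the
#'   PSR red-dominant fraction.
#' @param collagen_threshold,elastin_threshold Nominal thresholds.
#' @param delta Threshold variation for the error estimate.
#' @param ... Passed to [tissue_mask()].
#' @return List with `collagen` and `elastin` (`stain_quantification`s with
#'   `err_low`/`err_high` attached), `psr_fraction` (or NA), the calibrated
#'   `collagen_threshold` and the mask pixel count.
#' @export
quantify_section <- function(vvg_image, psr_image = NULL,
                             collagen_threshold = 1.0,
                             elastin_threshold = 0.5, delta = 0.05, ...) {
  mask <- tissue_mask(vvg_image, ...)
  cmap <- collagen_index_map(vvg_image)
  emap <- elastin_index_map(vvg_image)
  psr_frac <- NA_real_
  if (!is.null(psr_image)) {
    psr_frac <- psr_collagen_fraction(psr_image, mask)
    if (psr_frac > 0 && psr_frac < 1)
      collagen_threshold <- calibrate_collagen_threshold(
        vvg_image, mask, psr_frac, nominal = collagen_threshold)
  }
  col <- quantify_stain(cmap, mask, collagen_threshold, "collagen")
  ela <- quantify_stain(emap, mask, elastin_threshold, "elastin")
  col_err <- threshold_sensitivity_error(cmap, mask, collagen_threshold, delta)
  ela_err <- threshold_sensitivity_error(emap, mask, elastin_threshold, delta)
  col$err_low <- col_err[["err_low"]]; col$err_high <- col_err[["err_high"]]
  ela$err_low <- ela_err[["err_low"]]; ela$err_high <- ela_err[["err_high"]]
  list(collagen = col, elastin = ela, psr_fraction = psr_frac,
       collagen_threshold = collagen_threshold, n_tissue_px = sum(mask))
}
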