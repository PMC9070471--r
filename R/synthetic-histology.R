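# Stain palettes (8-bit RGB). Chosen so that, under the weighted-RGB stain
# indices used by the quantification module:
#   * collagen hues (pink/magenta/plum) score > 1.0 on the collagen index
#     R/50 - G/20 + B/30 while staying bright enough to score < 0.5 on the
#     darkness-based elastin index;
#   * elastin hues (grey-to-black) score > 0.5 on the elastin index and
#     < 1.0 on the collagen index;
#   * the van Gieson-like counterstain and the blank slide score below both
#     thresholds.
.vvg_palette <- list(
  collagen = rbind(c(230, 40, 160), c(255, 150, 180), c(210, 70, 140)),
  elastin = rbind(c(40, 40, 40), c(90, 90, 90), c(15, 15, 15)),
  counterstain = rbind(c(235, 200, 170)),
  background = c(250, 250, 250)
)
.psr_palette <- list(
  collagen = rbind(c(210, 40, 40), c(180, 30, 50)),
  counterstain = rbind(c(245, 225, 185)),
  background = c(250, 250, 250)
)

# smooth irregular elliptical tissue footprint, guaranteed contiguous
.tissue_footprint <- function(width, height) {
  cx <- width / 2; cy <- height / 2
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  theta <- atan2(ys - cy, xs - cx)
  k <- stats::runif(3, 1, 4); ph <- stats::runif(3, 0, 2 * pi)
  a <- stats::runif(3, 0.02, 0.06)
  wobble <- 1 + a[1] * sin(k[1] * theta + ph[1]) +
    a[2] * sin(k[2] * theta + ph[2]) + a[3] * sin(k[3] * theta + ph[3])
  r <- sqrt(((xs - cx) / (0.42 * width))^2 + ((ys - cy) / (0.40 * height))^2)
  r < wobble
}

.paint <- function(img, idx, palette_rows, noise = 5) {
  n <- length(idx)
  if (n == 0) return(img)
  rows <- palette_rows[sample.int(nrow(palette_rows), n, replace = TRUE), , drop = FALSE]
  if (noise > 0) rows <- rows + matrix(sample(-noise:noise, 3 * n, TRUE), n, 3)
  rows <- pmin(pmax(rows, 0), 255)
  npx <- dim(img)[1] * dim(img)[2]
  for (ch in 1:3) img[idx + (ch - 1) * npx] <- rows[, ch]
  img
}

#' Simulate a Verhoeff-van Gieson stained section
#'
#' Paints an 8-bit RGB image with a contiguous tissue region on a
#' near-white slide background. Within the tissue, an exact pixel count
#' (`round(fraction * tissue_pixels)`) is painted in collagen-like hues
#' (light pink through magenta to plum), elastin-like grey-to-black hues,
#' and a neutral counterstain for the remainder, so the painted fractions
#' are the exact ground truth for the stain-quantification chain. Painted
#' pixel positions are randomized; each painted pixel gets small
#' per-channel colour noise that cannot cross the index thresholds.
#'
#' The background blue channel is held constant so it is the modal blue
#' value of the image, as the tissue-masking algorithm assumes.
#'
#' @param width,height Image size in pixels.
#' @param collagen_fraction,elastin_fraction Target area fractions within
#'   the tissue mask; non-negative, summing to at most 1.
#' @param seed Integer seed.
#' @return List with `image` (height x width x 3 integer array, 0-255) and
#'   `truth` (painted collagen/elastin fractions, tissue footprint mask and
#'   painted pixel indices).
#' @export
simulate_vvg_image <- function(width = 192, height = 192,
                               collagen_fraction = 0.3, elastin_fraction = 0.2,
                               seed = 1) {
  if (collagen_fraction < 0 || elastin_fraction < 0)
    stop("fractions must be >= 0", call. = FALSE)
  if (collagen_fraction + elastin_fraction > 1)
    stop("collagen + elastin fractions must not exceed 1", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)

  tissue <- .tissue_footprint(width, height)
  img <- array(0L, c(height, width, 3))
  npx <- height * width
  bg <- .vvg_palette$background
  for (ch in 1:3) img[, , ch] <- bg[ch]
  # slight R/G mottle on the slide; blue stays exactly modal
  img[, , 1] <- pmin(255, img[, , 1] + sample(0:5, npx, TRUE))
  img[, , 2] <- pmin(255, img[, , 2] + sample(0:5, npx, TRUE))

  tidx <- sample(which(tissue))  # random spatial arrangement, exact counts
  nt <- length(tidx)
  n_col <- round(collagen_fraction * nt)
  n_ela <- round(elastin_fraction * nt)
  col_idx <- tidx[seq_len(n_col)]
  ela_idx <- tidx[n_col + seq_len(n_ela)]
  rest_idx <- tidx[-seq_len(n_col + n_ela)]

  img <- .paint(img, col_idx, .vvg_palette$collagen)
  img <- .paint(img, ela_idx, .vvg_palette$elastin)
  img <- .paint(img, rest_idx, .vvg_palette$counterstain)

  list(image = img,
       truth = list(collagen_fraction = n_col / nt, elastin_fraction = n_ela / nt,
                    tissue = tissue, collagen_idx = col_idx, elastin_idx = ela_idx,
                    seed = seed))
}

#' Simulate the adjacent Picrosirius-Red stained section
#'
#' Builds the companion PSR image for a VVG ground truth: the same tissue
#' footprint, with collagen painted in saturated red hues at the VVG
#' collagen fraction plus a small section-adjacency jitter (adjacent 6 um
#' sections are near- but not exactly identical), and a pale yellow
#' counterstain elsewhere.
#'
#' @param vvg A result of [simulate_vvg_image()].
#' @param jitter Maximum absolute perturbation of the collagen fraction
#'   (uniform on +/- jitter); 0 reproduces the VVG fraction exactly.
#' @param seed Integer seed.
#' @return List with `image` and `truth` (`collagen_fraction` actually
#'   painted, plus the shared tissue footprint).
#' @export
simulate_psr_image <- function(vvg, jitter = 0.01, seed = 1) {
  tissue <- vvg$truth$tissue
  set.seed((seed + 7L) %% .Machine$integer.max)
  frac <- vvg$truth$collagen_fraction +
    if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
  frac <- min(max(frac, 0), 1)

  height <- nrow(tissue); width <- ncol(tissue)
  img <- array(0L, c(height, width, 3))
  bg <- .psr_palette$background
  for (ch in 1:3) img[, , ch] <- bg[ch]
  npx <- height * width
  img[, , 1] <- pmin(255, img[, , 1] + sample(0:5, npx, TRUE))
  img[, , 2] <- pmin(255, img[, , 2] + sample(0:5, npx, TRUE))

  tidx <- sample(which(tissue))
  n_col <- round(frac * length(tidx))
  img <- .paint(img, tidx[seq_len(n_col)], .psr_palette$collagen)
  img <- .paint(img, tidx[-seq_len(n_col)], .psr_palette$counterstain, noise = 4)

  list(image = img,
       truth = list(collagen_fraction = n_col / length(tidx), tissue = tissue))
}

#' Write an 8-bit RGB image array to PNG
#'
#' @param image height x width x 3 array of 0-255 values.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a PNG file as an 8-bit RGB array
#'
#' Alpha channels are dropped; grey-scale images are replicated across the
#' three channels.
#'
#' @param path PNG file path.
#' @return height x width x 3 integer array of 0-255 values.
#' @export
read_rgb_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim(x))
}
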