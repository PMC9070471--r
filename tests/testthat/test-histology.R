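test_that("index maps evaluate the printed weightings per pixel", {
  px <- function(r, g, b) array(rep(c(r, g, b), each = 4), c(2, 2, 3))
  expect_equal(collagen_index_map(px(0, 0, 0))[1, 1], 0)
  expect_equal(collagen_index_map(px(255, 255, 255))[1, 1], 0.85)
  expect_equal(collagen_index_map(px(255, 0, 255))[1, 1], 13.6)
  expect_equal(elastin_index_map(px(0, 0, 0))[1, 1], 1)
  expect_equal(elastin_index_map(px(255, 255, 255))[1, 1], 0)
  # equal mid-grey sits exactly on the 0.5 elastin boundary
  expect_equal(elastin_index_map(px(127.5, 127.5, 127.5))[1, 1], 0.5)
})

test_that("index maps are pure per-pixel functions", {
  set.seed(3)
  img <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
  perm <- sample(16)
  permuted <- array(0, c(4, 4, 3))
  for (ch in 1:3) permuted[, , ch][perm] <- img[, , ch]
  expect_equal(collagen_index_map(permuted)[perm], as.vector(collagen_index_map(img)))
  expect_equal(elastin_index_map(permuted)[perm], as.vector(elastin_index_map(img)))
})

test_that("tissue mask recovers a block, drops specks, fills holes", {
  img <- block_image()
  m <- tissue_mask(img, min_fragment_px = 10, max_hole_px = 10)
  want <- matrix(FALSE, 40, 40); want[11:30, 11:30] <- TRUE
  expect_identical(m, want)

  # 3-pixel speck outside is removed
  speck <- img
  for (ch in 1:3) speck[3, 3:5, ch] <- 50
  expect_identical(tissue_mask(speck, min_fragment_px = 10, max_hole_px = 10), want)

  # 5-pixel interior hole is filled
  holed <- img
  holed[20, 18:22, 1] <- 250; holed[20, 18:22, 2] <- 250; holed[20, 18:22, 3] <- 250
  expect_identical(tissue_mask(holed, min_fragment_px = 10, max_hole_px = 10), want)

  # holes larger than max_hole_px stay open
  big_hole <- img
  for (ch in 1:3) big_hole[15:26, 15:26, ch] <- 250
  m2 <- tissue_mask(big_hole, min_fragment_px = 10, max_hole_px = 10)
  expect_false(m2[20, 20])

  # single-colour image: empty mask with warning
  flat <- array(120L, c(8, 8, 3))
  expect_warning(m3 <- tissue_mask(flat), "empty")
  expect_false(any(m3))
})

test_that("mask matches the generator footprint almost exactly", {
  for (s in 1:3) {
    v <- simulate_vvg_image(96, 96, 0.4, 0.3, seed = s)
    m <- tissue_mask(v$image, min_fragment_px = 16, max_hole_px = 64)
    jac <- sum(m & v$truth$tissue) / sum(m | v$truth$tissue)
    expect_gte(jac, 0.98)
  }
})

test_that("stain fraction counts strictly-above pixels over the mask", {
  imap <- matrix(c(2, 2, 0, 0), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(quantify_stain(imap, mask, 1)$fraction, 0.5)
  expect_equal(quantify_stain(imap, mask, 5)$fraction, 0)
  # boundary pixels are unstained (strict inequality)
  expect_equal(quantify_stain(imap, mask, 2)$fraction, 0)
  expect_error(quantify_stain(imap, matrix(FALSE, 2, 2), 1), "mask")
})

test_that("fraction is monotonically non-increasing in the threshold", {
  v <- simulate_vvg_image(96, 96, 0.35, 0.25, seed = 4)
  m <- tissue_mask(v$image, 16, 64)
  imap <- collagen_index_map(v$image)
  fr <- vapply(seq(-1, 14, by = 0.25),
               function(t) quantify_stain(imap, m, t)$fraction, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("quantification recovers painted fractions within 0.02", {
  set.seed(11)
  for (s in 1:8) {
    cf <- runif(1, 0.05, 0.6); ef <- runif(1, 0.05, min(0.35, 1 - cf))
    v <- simulate_vvg_image(96, 96, cf, ef, seed = s)
    p <- simulate_psr_image(v, seed = s)
    q <- quantify_section(v$image, p$image, min_fragment_px = 16, max_hole_px = 64)
    expect_lt(abs(q$collagen$fraction - v$truth$collagen_fraction), 0.02)
    expect_lt(abs(q$elastin$fraction - v$truth$elastin_fraction), 0.02)
    expect_lt(abs(q$psr_fraction - p$truth$collagen_fraction), 0.02)
  }
})

test_that("PSR red-dominance fraction hits the painted extremes", {
  v <- simulate_vvg_image(96, 96, 0.4, 0.2, seed = 2)
  m <- v$truth$tissue
  # all-red tissue
  red <- v$image
  for (px in which(m)) {
    red[px] <- 220
    red[px + length(m)] <- 30
    red[px + 2 * length(m)] <- 30
  }
  expect_equal(psr_collagen_fraction(red, m), 1)
  # no red at all
  grey <- v$image
  for (ch in 1:3) grey[, , ch][m] <- 128
  expect_equal(psr_collagen_fraction(grey, m), 0)
})

test_that("threshold calibration tracks the PSR target", {
  v <- simulate_vvg_image(96, 96, 0.4, 0.2, seed = 6)
  m <- tissue_mask(v$image, 16, 64)
  imap <- collagen_index_map(v$image)
  f_nom <- quantify_stain(imap, m, 1)$fraction
  # target equal to the nominal fraction returns the nominal threshold
  expect_equal(calibrate_collagen_threshold(v$image, m, f_nom), 1.0)
  # monotone mismatch: larger target -> threshold moves down (and vice versa)
  t_hi <- calibrate_collagen_threshold(v$image, m, min(0.95, f_nom + 0.1))
  t_lo <- calibrate_collagen_threshold(v$image, m, max(0.05, f_nom - 0.1))
  expect_lte(t_hi, 1.0)
  expect_gte(t_lo, 1.0)
  # flat map: warning + nominal
  flat <- array(100L, c(8, 8, 3))
  expect_warning(t_flat <- calibrate_collagen_threshold(flat, matrix(TRUE, 8, 8), 0.3),
                 "flat")
  expect_equal(t_flat, 1.0)
})

test_that("threshold-variation errors reflect index density near the cut", {
  # bimodal far from the threshold: insensitive, zero error
  imap <- matrix(rep(c(0, 10), 50), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(unname(threshold_sensitivity_error(imap, mask, 5, 0.5)), c(0, 0))
  # uniform index density: errors proportional to delta (closed form: the
  # fraction drops linearly, slope 1/range)
  u <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  for (delta in c(0.05, 0.1)) {
    err <- threshold_sensitivity_error(u, matrix(TRUE, 100, 100), 0.5, delta)
    expect_equal(unname(err), c(delta, delta), tolerance = 0.01)
  }
  # delta spanning the whole range: errors bracket the full fraction range
  err_all <- threshold_sensitivity_error(u, matrix(TRUE, 100, 100), 0.5, 2)
  expect_equal(unname(err_all[1] + err_all[2]), 1, tolerance = 1e-3)
  expect_true(all(threshold_sensitivity_error(u, matrix(TRUE, 100, 100), 0.3, 0.2) >= 0))
})
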