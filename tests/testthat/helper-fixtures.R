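# Shared fixture builders. Everything is generated in code at test time.

# a minimal raw run with a hand-placed rectangular burn: `n_base` baseline
# scans, `n_burn` elevated scans, flat single-ion spectra so the TIC is
# exactly controllable
flat_run <- function(n_base = 10, n_burn = 12, baseline = 100, burn = 5000) {
  tics <- c(rep(baseline, n_base), rep(burn, n_burn), rep(baseline, n_base))
  scans <- lapply(tics, function(t) list(mz = 500, intensity = t))
  raw_run(scans, scan_times = seq_along(tics) - 1)
}

# three well-separated point clouds whose separation is spread over many
# features (one disjoint block per blob), so feature resampling preserves
# the blob structure the way it preserves a broad marker profile
blob_matrix <- function(n_per = 4, sep = 10, sd = 0.5, n_inf = 20, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per
  centres <- matrix(0, 3, 3 * n_inf)
  for (i in 1:3)
    centres[i, (i - 1) * n_inf + seq_len(n_inf)] <- sep / sqrt(n_inf)
  labs <- rep(1:3, each = n_per)
  centres[labs, ] + matrix(rnorm(n * ncol(centres), sd = sd), n)
}

blob_labels <- function(n_per = 4) rep(1:3, each = n_per)

# solid rectangle image on a white slide, plus optional speck and hole
block_image <- function(width = 40, height = 40, x0 = 11, x1 = 30,
                        y0 = 11, y1 = 30, colour = c(150, 60, 120)) {
  img <- array(0L, c(height, width, 3))
  img[, , 1] <- 250; img[, , 2] <- 250; img[, , 3] <- 250
  for (ch in 1:3) img[y0:y1, x0:x1, ch] <- colour[ch]
  img
}
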