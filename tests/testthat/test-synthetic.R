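test_that("identical seeds give bit-identical cohorts, spectra and runs", {
  cfg <- cohort_config(seed = 17)
  expect_identical(simulate_feature_table(cfg), simulate_feature_table(cfg))
  expect_identical(simulate_spectrum_set(cfg), simulate_spectrum_set(cfg))
  expect_identical(simulate_burn_run(seed = 17), simulate_burn_run(seed = 17))
  v <- simulate_vvg_image(64, 64, 0.3, 0.2, seed = 17)
  expect_identical(v, simulate_vvg_image(64, 64, 0.3, 0.2, seed = 17))
  expect_identical(simulate_psr_image(v, seed = 3), simulate_psr_image(v, seed = 3))
})

test_that("config validation rejects bad cohorts", {
  expect_error(cohort_config(n_fl = 0), "counts")
  expect_error(cohort_config(noise_cv = -1), "noise_cv")
  expect_error(cohort_config(class_effect = -0.1))
})

test_that("feature table encodes the false-lumen phenotype", {
  ft <- simulate_feature_table(cohort_config(seed = 2))
  tab <- ft$table
  expect_equal(nrow(tab), 26)
  expect_true(all(tab[, c("g_prime", "g_dprime", "collagen", "elastin",
                          "gag", "age", "indexed_aortic_size")] > 0))
  for (v in c("g_prime", "g_dprime", "gag"))
    expect_lt(median(tab[[v]][tab$tissue_type == "FL"]),
              median(tab[[v]][tab$tissue_type == "TL"]))
  # patient-level variables are shared across pieces of the same patient
  ages <- tapply(tab$age, tab$patient_id, function(a) length(unique(a)))
  expect_true(all(ages == 1))
  # minimal cohort still works
  mini <- simulate_feature_table(cohort_config(n_fl = 1, n_fp = 1, n_tl = 1))
  expect_equal(nrow(mini$table), 3)
  expect_true(all(is.finite(as.matrix(mini$table[, -(1:3)]))))
})

test_that("zero class effect makes groups exchangeable (KW at nominal rate)", {
  cfg0 <- cohort_config(class_effect = 0, subcluster_effect = 0, seed = 1)
  rej <- vapply(1:200, function(i) {
    cfg <- cohort_config(class_effect = 0, subcluster_effect = 0, seed = i)
    ft <- simulate_feature_table(cfg)
    kruskal_wallis(ft$table$g_prime, ft$table$tissue_type)$p_raw < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})

test_that("spectrum rows are simplex vectors with planted structure", {
  cfg <- cohort_config(seed = 5)
  ss <- simulate_spectrum_set(cfg)
  expect_equal(dim(ss$spectra), c(26, 1150))
  expect_true(all(ss$spectra >= 0))
  expect_equal(unname(rowSums(ss$spectra)), rep(1, 26), tolerance = 1e-12)
  expect_equal(sum(ss$labels$tissue_type == "FL"), 10)
  expect_equal(sort(unique(ss$labels$subcluster[ss$labels$tissue_type == "FL"])),
               1:3)
})

test_that("zero effects and zero noise collapse all samples to one template", {
  cfg <- cohort_config(class_effect = 0, subcluster_effect = 0, noise_cv = 0,
                       seed = 9)
  ss <- simulate_spectrum_set(cfg, n_bins = 200)
  expect_equal(max(apply(ss$spectra, 2, function(col) diff(range(col)))), 0)
})

test_that("zero noise, one sample per class gives distinct templates", {
  cfg <- cohort_config(n_fl = 1, n_fp = 1, n_tl = 1, noise_cv = 0, seed = 3)
  ss <- simulate_spectrum_set(cfg, n_bins = 300)
  d <- dist(ss$spectra)
  expect_true(all(d > 0))
})

test_that("burn run has the requested elevated span and clean flanks", {
  run <- simulate_burn_run(duration_s = 12, scan_rate_hz = 1, seed = 4)
  base <- median(run$tic)
  expect_equal(sum(run$tic > 5 * base), 12)
  expect_equal(attr(run, "event_end") - attr(run, "event_start") + 1, 12)
  # tic field always equals per-scan intensity sums
  expect_equal(run$tic, vapply(run$scans, function(s) sum(s$intensity), 0))
  # zero noise: TIC exactly baseline outside the event
  quiet <- simulate_burn_run(duration_s = 10, noise_cv = 0, seed = 1)
  ev <- attr(quiet, "event_start"):attr(quiet, "event_end")
  expect_equal(unique(quiet$tic[-ev]), 1000)
  expect_warning(simulate_burn_run(duration_s = 5, seed = 1), "10-30")
})

test_that("painted stain fractions are pixel-exact before jitter", {
  for (s in 1:5) {
    cf <- c(0.1, 0.25, 0.4, 0, 0.6)[s]
    ef <- c(0.3, 0.2, 0.1, 0, 0.25)[s]
    v <- simulate_vvg_image(96, 96, cf, ef, seed = s)
    nt <- sum(v$truth$tissue)
    expect_equal(v$truth$collagen_fraction, round(cf * nt) / nt)
    expect_equal(length(v$truth$collagen_idx), round(cf * nt))
    expect_equal(length(v$truth$elastin_idx), round(ef * nt))
  }
  expect_error(simulate_vvg_image(64, 64, 0.7, 0.5), "exceed 1")
  # 64 px minimal image is valid
  v <- simulate_vvg_image(64, 64, 0.4, 0.3, seed = 1)
  expect_true(sum(v$truth$tissue) > 0)
})

test_that("PSR companion matches VVG ground truth at zero jitter", {
  v <- simulate_vvg_image(96, 96, 0.35, 0.2, seed = 8)
  p0 <- simulate_psr_image(v, jitter = 0, seed = 1)
  expect_equal(p0$truth$collagen_fraction, v$truth$collagen_fraction)
  expect_identical(p0$truth$tissue, v$truth$tissue)
  pj <- simulate_psr_image(v, jitter = 0.01, seed = 2)
  expect_lte(abs(pj$truth$collagen_fraction - v$truth$collagen_fraction), 0.011)
  # zero collagen -> no red-dominant pixels in tissue
  v0 <- simulate_vvg_image(96, 96, 0, 0.3, seed = 3)
  p <- simulate_psr_image(v0, jitter = 0, seed = 1)
  expect_equal(psr_collagen_fraction(p$image, v0$truth$tissue), 0)
})

test_that("PNG round trip preserves the image", {
  v <- simulate_vvg_image(64, 64, 0.3, 0.2, seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_rgb_png(v$image, path)
  back <- read_rgb_png(path)
  expect_equal(as.integer(back), as.integer(v$image))
})
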