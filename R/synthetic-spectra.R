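#' Simulate a binned REIMS spectrum set for the cohort
#'
#' Builds TIC-normalized intensity vectors over a fixed m/z binning for
#' every sample in the cohort. Each tissue class has its own peak template:
#' a backbone of ~30 Gaussian peaks shared by all classes (mostly in the
#' lipid-rich 600-900 m/z region) plus class-specific marker peaks whose
#' height scales with `class_effect`. False-lumen samples additionally draw
#' from one of `n_subclusters` perturbed templates whose private marker
#' peaks scale with `subcluster_effect`. Per-bin multiplicative log-normal
#' noise with coefficient of variation `noise_cv` is applied before TIC
#' normalization, so every row is non-negative and sums to 1.
#'
#' With `class_effect = 0` and `subcluster_effect = 0` all samples are
#' exchangeable draws from the common backbone; with both effects and the
#' noise at 0, every sample of a class is the identical template vector.
#'
#' @param config A [cohort_config()].
#' @param n_bins Number of m/z bins (default 1150, i.e. 1 Da over 50-1200).
#' @param mz_lo,mz_hi m/z range covered by the binning.
#' @return A list of class `spectrum_set`: `spectra` (samples x bins matrix,
#'   rows sum to 1), `mz` (bin centres), `labels` (ground-truth data.frame)
#'   and `markers` (bin indices of the planted class and sub-cluster marker
#'   peaks, for validation).
#' @export
simulate_spectrum_set <- function(config, n_bins = 1150, mz_lo = 50, mz_hi = 1200) {
  stopifnot(inherits(config, "cohort_config"))
  if (!(mz_lo < mz_hi)) stop("mz_lo must be < mz_hi", call. = FALSE)
  if (n_bins < 10) stop("n_bins must be >= 10", call. = FALSE)
  truth <- .cohort_truth(config)
  set.seed(.derive_seed(config$seed, 23L))

  width <- (mz_hi - mz_lo) / n_bins
  mz <- mz_lo + (seq_len(n_bins) - 0.5) * width
  peak_sd <- 0.75 * max(1, width)  # Da; centroided peaks span ~2 bins at 1 Da

  add_peaks <- function(template, centres, heights) {
    for (i in seq_along(centres))
      template <- template + heights[i] * exp(-(mz - centres[i])^2 / (2 * peak_sd^2))
    template
  }
  draw_centres <- function(k, lo, hi) sort(stats::runif(k, lo, hi))

  lip_lo <- max(mz_lo, min(600, mz_hi - 1))
  lip_hi <- min(mz_hi, 900)
  backbone_mz <- c(draw_centres(20, lip_lo, lip_hi),
                   draw_centres(10, mz_lo + 0.05 * (mz_hi - mz_lo), lip_lo))
  backbone_h <- stats::rlnorm(30, 0, 0.5) + 0.3
  backbone <- add_peaks(rep(1e-3, n_bins), backbone_mz, backbone_h)

  # marker positions come from a minimum-spacing pool so that no two
  # classes (or sub-clusters) share overlapping marker peaks: the
  # sub-templates are then exactly equidistant by construction and only
  # noise distinguishes one pairing from another
  n_sub <- config$n_subclusters
  n_slots <- 24 + 5 * n_sub
  slot_step <- max(7, (lip_hi - lip_lo - 4) / n_slots)
  slots <- seq(lip_lo + 2, lip_hi - 2, by = slot_step)
  if (length(slots) < n_slots)
    stop("m/z range too narrow for the marker layout; widen mz range or bins",
         call. = FALSE)
  # snap to bin centres: every marker peak then has the identical discrete
  # profile, so inter-template distances are equal exactly, not just in
  # expectation
  picked <- sample(slots, n_slots)
  picked <- mz_lo + (floor((picked - mz_lo) / width) + 0.5) * width
  class_marker_mz <- lapply(1:3, function(i) sort(picked[(i - 1) * 8 + 1:8]))
  sub_marker_mz <- lapply(seq_len(n_sub),
                          function(i) sort(picked[24 + (i - 1) * 5 + 1:5]))
  class_marker_h <- lapply(1:3, function(i) stats::rlnorm(8, 0, 0.3))
  # equal-height sub-cluster markers keep the sub-templates exchangeable:
  # no pairing of sub-clusters is systematically closer than another
  sub_marker_h <- lapply(seq_len(config$n_subclusters), function(i) rep(1, 5))

  classes <- c("FL", "FP", "TL")
  class_templates <- lapply(1:3, function(i)
    add_peaks(backbone, class_marker_mz[[i]],
              config$class_effect * class_marker_h[[i]]))
  names(class_templates) <- classes
  sub_templates <- lapply(seq_len(config$n_subclusters), function(i)
    add_peaks(class_templates[["FL"]], sub_marker_mz[[i]],
              config$subcluster_effect * sub_marker_h[[i]]))

  sdlog <- .lnorm_sdlog(config$noise_cv)
  n <- nrow(truth)
  spectra <- matrix(NA_real_, n, n_bins,
                    dimnames = list(truth$sample_id, sprintf("mz_%.2f", mz)))
  for (i in seq_len(n)) {
    tmpl <- if (truth$tissue_type[i] == "FL")
      sub_templates[[truth$subcluster[i]]]
    else class_templates[[as.character(truth$tissue_type[i])]]
    x <- if (sdlog > 0) tmpl * stats::rlnorm(n_bins, -sdlog^2 / 2, sdlog) else tmpl
    spectra[i, ] <- x / sum(x)
  }

  mz_to_bin <- function(v) pmin(n_bins, pmax(1L, findInterval(v, mz_lo + 0:n_bins * width)))
  structure(list(
    spectra = spectra, mz = mz, labels = truth,
    markers = list(class = lapply(stats::setNames(class_marker_mz, classes), mz_to_bin),
                   subcluster = lapply(sub_marker_mz, mz_to_bin)),
    bin_width = width
  ), class = "spectrum_set")
}

#' Extract the false-lumen rows of a spectrum set
#'
#' Convenience accessor for the sub-cluster analyses: returns the FL
#' intensity matrix with its ground-truth sub-cluster labels.
#'
#' @param set A `spectrum_set`.
#' @return List with `spectra` (FL rows) and `subcluster` (integer labels).
#' @export
fl_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  keep <- set$labels$tissue_type == "FL"
  list(spectra = set$spectra[keep, , drop = FALSE],
       subcluster = set$labels$subcluster[keep])
}
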