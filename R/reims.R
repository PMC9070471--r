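#' Detect burn events in a raw run
#'
#' A burn event is a maximal contiguous window of scans whose total ion
#' current exceeds `threshold_factor` times the run baseline, where the
#' baseline is the median TIC of the whole run (cauterization occupies a
#' minority of scans, so the median tracks the quiescent level). Windows
#' shorter than `min_length` scans are discarded as spikes.
#'
#' @param run A [raw_run()].
#' @param threshold_factor Multiplier of the baseline defining the
#'   burn-level threshold (default 5).
#' @param min_length Minimum window length in scans (default 3).
#' @return List of `burn_window` objects (fields `start_scan`, `end_scan`,
#'   `peak_scan`, 1-based inclusive; `threshold`), ordered by scan,
#'   non-overlapping. Empty list if no event crosses the threshold.
#' @export
detect_burn_events <- function(run, threshold_factor = 5, min_length = 3) {
  stopifnot(inherits(run, "raw_run"))
  if (length(run$tic) < 3) stop("run must contain at least 3 scans", call. = FALSE)
  baseline <- stats::median(run$tic)
  threshold <- threshold_factor * baseline
  above <- run$tic > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_length
  lapply(which(keep), function(i) {
    s <- starts[i]; e <- ends[i]
    structure(list(start_scan = s, end_scan = e,
                   peak_scan = s + which.max(run$tic[s:e]) - 1L,
                   threshold = threshold),
              class = "burn_window")
  })
}

# sigma of the canonical 35-scan Gaussian: chosen so that exactly
# `span` of the 35 trace values exceed the absolute burn-level threshold.
# The centre sits at 17.51 so the integer-scan maximum is scan 18 while the
# above-threshold set is the even-sized contiguous block 12..23.
.canonical_sigma <- function(total_tic, threshold, span = 12L, len = 35L,
                             centre = 17.51) {
  k <- seq_len(len)
  grid <- seq(0.5, 14, by = 0.005)
  counts <- vapply(grid, function(s) {
    w <- exp(-(k - centre)^2 / (2 * s^2))
    sum(w / sum(w) * total_tic > threshold)
  }, 0L)
  hit <- which(counts == span)
  if (length(hit) == 0) {
    warning("no Gaussian width gives exactly ", span,
            " scans above threshold; using closest")
    hit <- which(abs(counts - span) == min(abs(counts - span)))
  }
  grid[hit[ceiling(length(hit) / 2)]]
}

#' Convert an uneven burn event into the canonical pseudo-Gaussian trace
#'
#' Redistributes a detected window's total ion current onto a fixed
#' 35-scan trace shaped as a Gaussian whose maximum falls at scan 18
#' (1-based) and which stays above the burn-level threshold for exactly 12
#' scans — the canonical representation that downstream classification
#' expects regardless of how ragged the real burn was. The trace conserves
#' TIC: its sum equals the window's total TIC. The same Gaussian weights,
#' resampled across the window, average the window's scans into a single
#' consensus spectrum (rescaled to the window TIC) retained for binning.
#'
#' @param run A [raw_run()].
#' @param window A `burn_window` from [detect_burn_events()].
#' @param threshold Absolute burn-level threshold; defaults to the one
#'   recorded in `window`.
#' @return An object of class `processed_trace`: `tic_trace` (length 35),
#'   `burn_span` (scans above threshold, 12 by construction), `peak_index`
#'   (1-based argmax, 18), `threshold`, `sigma`, `source_window` and
#'   `spectrum` (consensus m/z / intensity vectors).
#' @export
pseudo_gaussianize <- function(run, window, threshold = window$threshold) {
  stopifnot(inherits(run, "raw_run"), inherits(window, "burn_window"))
  n <- length(run$tic)
  if (window$start_scan < 1 || window$end_scan > n ||
      window$start_scan > window$end_scan)
    stop("window does not lie inside the run", call. = FALSE)

  idx <- window$start_scan:window$end_scan
  total <- sum(run$tic[idx])
  centre <- 17.51
  sigma <- .canonical_sigma(total, threshold, centre = centre)
  k <- 1:35
  w <- exp(-(k - centre)^2 / (2 * sigma^2))
  w <- w / sum(w)
  trace <- w * total

  # consensus spectrum: window scans weighted by the same Gaussian,
  # positions mapped linearly onto the canonical burn block 12..23
  m <- length(idx)
  x <- if (m == 1) centre else 12 + (seq_len(m) - 1) * (23 - 12) / (m - 1)
  g <- exp(-(x - centre)^2 / (2 * sigma^2))
  g <- g / sum(g)
  mzv <- unlist(lapply(run$scans[idx], `[[`, "mz"))
  inten <- unlist(lapply(seq_len(m), function(j)
    g[j] * run$scans[[idx[j]]]$intensity))
  ord <- order(mzv)
  mzv <- mzv[ord]; inten <- inten[ord]
  if (sum(inten) > 0) inten <- inten * (total / sum(inten))

  structure(list(
    tic_trace = trace,
    burn_span = sum(trace > threshold),
    peak_index = which.max(trace),
    threshold = threshold, sigma = sigma,
    source_window = window,
    spectrum = list(mz = mzv, intensity = inten)
  ), class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat("Pseudo-Gaussian burn trace: ", length(x$tic_trace), " scans, ",
      x$burn_span, " above threshold, maximum at scan ", x$peak_index,
      ", total TIC ", format(sum(x$tic_trace), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Lock-mass correction of a centroided spectrum
#'
#' Shifts every m/z value by a single constant so the most intense peak
#' found within `search_window` Da of the reference lands exactly on the
#' reference mass. The default reference is 554.2615 Da, the [M-H]- ion of
#' leucine-enkephalin, the standard negative-mode REIMS lock mass. If no
#' peak lies in the window the spectrum is returned unchanged with a
#' warning and a zero recorded shift, so the operation is idempotent.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param reference_mz Reference mass (Da).
#' @param search_window Half-width of the search window (Da).
#' @return List with corrected `mz`, unchanged `intensity`, and the applied
#'   `shift` (Da).
#' @export
lockmass_correct <- function(mz, intensity, reference_mz = 554.2615,
                             search_window = 0.5) {
  stopifnot(length(mz) == length(intensity))
  in_win <- which(abs(mz - reference_mz) <= search_window)
  if (length(in_win) == 0) {
    warning("no lockmass peak within ", search_window, " Da of ",
            reference_mz, "; spectrum left uncorrected")
    return(list(mz = mz, intensity = intensity, shift = 0))
  }
  observed <- mz[in_win[which.max(intensity[in_win])]]
  shift <- reference_mz - observed
  list(mz = mz + shift, intensity = intensity, shift = shift)
}

#' Bin a centroided spectrum onto a fixed m/z grid
#'
#' Sums ion intensities into half-open bins `[lo, lo + width)`; ions at or
#' above `mz_hi` or below `mz_lo` are dropped. Binning is mass-conserving
#' within the range: the binned total equals the total intensity of
#' in-range ions. Optional TIC normalization divides by the vector sum so
#' the result sums to 1.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param mz_lo,mz_hi Range covered (default 50-1200, the acquisition
#'   range).
#' @param bin_width Bin width in Da (default 1).
#' @param normalize `"tic"` (default) or `"raw"`.
#' @return Object of class `spectrum_vector`: `intensities`, `mz` (bin
#'   centres), `bin_width`, `normalization`.
#' @export
bin_spectrum <- function(mz, intensity, mz_lo = 50, mz_hi = 1200,
                         bin_width = 1, normalize = c("tic", "raw")) {
  normalize <- match.arg(normalize)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  n_bins <- ceiling((mz_hi - mz_lo) / bin_width)
  v <- numeric(n_bins)
  keep <- mz >= mz_lo & mz < mz_lo + n_bins * bin_width & mz < mz_hi
  if (any(keep)) {
    idx <- floor((mz[keep] - mz_lo) / bin_width) + 1
    agg <- rowsum(intensity[keep], idx)
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (normalize == "tic" && sum(v) > 0) v <- v / sum(v)
  structure(list(intensities = v,
                 mz = mz_lo + (seq_len(n_bins) - 0.5) * bin_width,
                 bin_width = bin_width, normalization = normalize),
            class = "spectrum_vector")
}

#' Process a raw run into one binned spectrum per burn event
#'
#' The full preprocessing chain: detect burn events, convert each to the
#' canonical pseudo-Gaussian trace and consensus spectrum, optionally
#' apply lock-mass correction, then bin and TIC-normalize. One
#' `spectrum_vector` per detected event, in scan order; a flat run yields
#' an empty list.
#'
#' @param run A [raw_run()].
#' @param threshold_factor,min_length Passed to [detect_burn_events()].
#' @param lockmass Apply lock-mass correction (default TRUE).
#' @param reference_mz,search_window Passed to [lockmass_correct()].
#' @param mz_lo,mz_hi,bin_width,normalize Passed to [bin_spectrum()].
#' @return List of `spectrum_vector`s with a `log` attribute recording the
#'   event windows and applied lock-mass shifts.
#' @export
process_run <- function(run, threshold_factor = 5, min_length = 3,
                        lockmass = TRUE, reference_mz = 554.2615,
                        search_window = 0.5, mz_lo = 50, mz_hi = 1200,
                        bin_width = 1, normalize = "tic") {
  events <- detect_burn_events(run, threshold_factor, min_length)
  shifts <- numeric(length(events))
  out <- vector("list", length(events))
  for (i in seq_along(events)) {
    tr <- pseudo_gaussianize(run, events[[i]])
    sp <- tr$spectrum
    if (lockmass) {
      sp <- lockmass_correct(sp$mz, sp$intensity, reference_mz, search_window)
      shifts[i] <- sp$shift
    }
    out[[i]] <- bin_spectrum(sp$mz, sp$intensity, mz_lo, mz_hi, bin_width,
                             normalize)
  }
  attr(out, "log") <- list(windows = events, lockmass_shifts = shifts)
  out
}
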