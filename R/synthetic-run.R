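#' Construct a raw REIMS run
#'
#' A raw run is an ordered collection of centroided scans, each an (m/z,
#' intensity) pair of vectors, with strictly increasing scan times. The
#' per-scan total ion current (TIC) — the sum of all intensities in the
#' scan, regardless of m/z — is computed on construction so it can never
#' drift out of sync with the scans.
#'
#' @param scans List of scans; each scan a list with numeric `mz` and
#'   `intensity` of equal length.
#' @param scan_times Numeric vector of acquisition times (s), strictly
#'   increasing, one per scan.
#' @return An object of class `raw_run` with elements `scans`, `scan_times`
#'   and `tic`.
#' @export
raw_run <- function(scans, scan_times) {
  if (length(scans) != length(scan_times))
    stop("one scan time per scan required", call. = FALSE)
  if (length(scan_times) > 1 && any(diff(scan_times) <= 0))
    stop("scan_times must be strictly increasing", call. = FALSE)
  for (s in scans)
    if (length(s$mz) != length(s$intensity) || any(s$intensity < 0))
      stop("each scan needs matching non-negative mz/intensity vectors", call. = FALSE)
  tic <- vapply(scans, function(s) sum(s$intensity), 0)
  structure(list(scans = scans, scan_times = scan_times, tic = tic),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat("REIMS raw run: ", length(x$scans), " scans, TIC range [",
      format(min(x$tic), digits = 4), ", ", format(max(x$tic), digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' Simulate a raw run containing one uneven burn event
#'
#' Emulates an iKnife cauterization burn recorded at a fixed scan rate:
#' the TIC sits at a noisy baseline, rises to an irregular ("uneven")
#' elevated plateau for approximately `duration_s * scan_rate_hz` scans and
#' falls back to baseline, with at least `flank_scans` baseline scans on
#' each side. Scans during the burn carry a lipid-like peak profile plus a
#' lockmass peak near 554.2615 Da (the deprotonated leucine-enkephalin
#' reference); `lockmass_error` offsets the observed lockmass position so
#' the mass-correction step has something to correct.
#'
#' @param duration_s Burn duration in seconds; the study instrument saw
#'   10-30 s burns, so values outside that range warn but still generate.
#' @param scan_rate_hz Scans per second (default 1).
#' @param flank_scans Baseline scans before and after the event (>= 5; the
#'   default keeps baseline scans in the majority so the median-TIC
#'   baseline estimate used in detection stays on the quiescent level).
#' @param baseline_tic Mean baseline TIC (arbitrary intensity units).
#' @param burn_fold Fold elevation of the burn TIC over baseline.
#' @param noise_cv CV of the multiplicative TIC irregularity; 0 gives a
#'   flat-topped event and exactly baseline TIC outside it.
#' @param lockmass_error Constant m/z offset (Da) applied to every ion, to
#'   be undone by lock-mass correction downstream.
#' @param seed Integer seed; identical seeds give identical runs.
#' @return A `raw_run`, with attributes `event_start`/`event_end` (1-based
#'   scan indices of the true burn) recording the ground truth.
#' @export
simulate_burn_run <- function(duration_s = 12, scan_rate_hz = 1,
                              flank_scans = max(20, ceiling(0.75 * duration_s * scan_rate_hz)),
                              baseline_tic = 1000,
                              burn_fold = 50, noise_cv = 0.15,
                              lockmass_error = 0, seed = 1) {
  if (duration_s < 10 || duration_s > 30)
    warning("burn duration outside the instrument's 10-30 s range; generating anyway")
  if (scan_rate_hz <= 0) stop("scan_rate_hz must be > 0", call. = FALSE)
  if (flank_scans < 5) stop("need >= 5 baseline scans on each side", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)

  n_burn <- max(1L, round(duration_s * scan_rate_hz))
  n <- 2L * flank_scans + n_burn
  ev <- flank_scans + seq_len(n_burn)

  sdlog <- .lnorm_sdlog(noise_cv)
  tic_target <- rep(baseline_tic, n)
  if (sdlog > 0) tic_target <- tic_target * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  # uneven burn plateau: independent log-normal roughness per scan
  burn_shape <- if (sdlog > 0) stats::rlnorm(n_burn, -sdlog^2 / 2, 2 * sdlog) else rep(1, n_burn)
  tic_target[ev] <- baseline_tic * burn_fold * burn_shape

  # lipid-like burn profile and a sparse chemical-noise baseline profile
  burn_mz <- sort(c(stats::runif(25, 600, 900), stats::runif(10, 100, 600), 554.2615))
  burn_h <- stats::rlnorm(36, 0, 0.5)
  burn_h[burn_mz == 554.2615] <- 2  # prominent lockmass reference peak
  base_mz <- sort(stats::runif(20, 50, 1200))
  base_h <- stats::rlnorm(20, 0, 0.5)

  scans <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %in% ev) { mzv <- burn_mz; h <- burn_h } else { mzv <- base_mz; h <- base_h }
    inten <- h * tic_target[i] / sum(h)
    scans[[i]] <- list(mz = mzv + lockmass_error, intensity = inten)
  }
  run <- raw_run(scans, scan_times = (seq_len(n) - 1) / scan_rate_hz)
  attr(run, "event_start") <- ev[1]
  attr(run, "event_end") <- ev[n_burn]
  run
}
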