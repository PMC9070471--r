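#' Configuration for the end-to-end workflow
#'
#' Collects every stage parameter of [run_all()] with one derived seed per
#' random stage. `fast = TRUE` shrinks the expensive stages (10 evaluation
#' repeats, 200 bootstrap replicates per scale, 64 px histology images) for
#' continuous-integration runs; the default matches the study-scale
#' parameters (50 repeats, 1000 replicates).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param fast Use reduced problem sizes.
#' @param cohort A [cohort_config()]; defaults to the study cohort layout
#'   with the given seed.
#' @param n_repeats,nboot,au_threshold,bin_width,image_px Stage overrides.
#' @return List of class `run_config` that round-trips losslessly through
#'   JSON.
#' @export
run_config <- function(seed = 1, fast = FALSE,
                       cohort = cohort_config(seed = seed),
                       n_repeats = if (fast) 10 else 50,
                       nboot = if (fast) 200 else 1000,
                       au_threshold = 0.90, bin_width = 1,
                       image_px = if (fast) 64 else 160) {
  structure(list(seed = as.integer(seed), fast = fast, cohort = cohort,
                 n_repeats = n_repeats, nboot = nboot,
                 au_threshold = au_threshold, bin_width = bin_width,
                 image_px = image_px),
            class = "run_config")
}

#' Run the full study analogue
#'
#' Executes the whole multi-modal workflow on a synthetic cohort with
#' known ground truth, in the order of the study it emulates:
#'
#' 1. simulate the cohort (feature table, spectrum set, one raw burn run);
#' 2. REIMS preprocessing contract on the raw run (pseudo-Gaussian trace);
#' 3. PCA of the biomechanical/biochemical table and Dunn Kruskal-Wallis
#'    tests of the important loadings across tissue types;
#' 4. PLS-DA with repeated 80/20 evaluation, VIP refinement, a refined
#'    re-evaluation and a pooled FL-vs-rest ROC;
#' 5. Ward clustering of the FL spectra with multiscale-bootstrap AU
#'    support and stable-cluster extraction;
#' 6. histology quantification of per-FL-sample VVG/PSR image pairs and
#'    Mann-Whitney comparison of collagen/elastin between the two largest
#'    recovered clusters.
#'
#' Every stage draws its seed from the master seed, so the same config
#' yields an identical report. If `out_dir` is given the report is also
#' written as a JSON/CSV tree.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return Nested report list (class `dissection_report`) with one element
#'   per stage plus the echoed `config`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  report <- list(config = unclass(config))

  # 1. simulate ------------------------------------------------------------
  ft <- simulate_feature_table(config$cohort)
  ss <- simulate_spectrum_set(config$cohort)
  run <- simulate_burn_run(duration_s = 12, seed = .derive_seed(seed, 31L))
  report$simulate <- list(n_samples = nrow(ft$table),
                          n_bins = ncol(ss$spectra))

  # 2. REIMS preprocessing -------------------------------------------------
  events <- detect_burn_events(run)
  if (length(events) == 0) stop("reims_preprocess: no burn event detected")
  tr <- pseudo_gaussianize(run, events[[1]])
  vec <- process_run(run)[[1]]
  report$reims <- list(n_events = length(events),
                       trace_length = length(tr$tic_trace),
                       burn_span = tr$burn_span, peak_index = tr$peak_index,
                       tic_conserved = abs(sum(tr$tic_trace) -
                                             sum(run$tic[events[[1]]$start_scan:events[[1]]$end_scan])) < 1e-6,
                       binned_sum = sum(vec$intensities))

  # 3. PCA + Dunn/KW on the feature table ---------------------------------
  num <- as.matrix(ft$table[, c("g_prime", "g_dprime", "collagen", "elastin",
                                "gag", "age", "indexed_aortic_size")])
  pca <- pca_explore(num)
  vars <- important_loadings(pca)
  dunn <- do.call(rbind, lapply(vars, function(v) {
    d <- dunn_posthoc(ft$table[[v]], ft$table$tissue_type)
    d$variable <- v
    d
  }))
  report$biomech <- list(explained = pca$explained_variance_ratio[1:2],
                         important_vars = vars, dunn = dunn)

  # 4. PLS-DA --------------------------------------------------------------
  ev_full <- repeated_evaluation(ss$spectra, ss$labels$tissue_type,
                                 n_repeats = config$n_repeats,
                                 seed = .derive_seed(seed, 32L))
  sel <- refine_by_vip(ev_full)
  ev_ref <- repeated_evaluation(ss$spectra[, sel, drop = FALSE],
                                ss$labels$tissue_type,
                                n_repeats = config$n_repeats,
                                seed = .derive_seed(seed, 33L))
  roc <- pooled_roc(ss$spectra, ss$labels$tissue_type, features = sel,
                    positive_class = "FL", n_repeats = config$n_repeats,
                    seed = .derive_seed(seed, 34L))
  report$classification <- list(full = ev_full$means, refined = ev_ref$means,
                                n_selected = length(sel), auc = roc$auc)

  # 5. FL sub-cluster stability --------------------------------------------
  fl <- fl_spectra(ss)
  sup <- multiscale_bootstrap(fl$spectra, n_boot = config$nboot,
                              seed = .derive_seed(seed, 35L))
  cl <- stable_clusters(sup, config$au_threshold)
  report$fl_clusters <- list(n_clusters = cl$n_clusters,
                             n_singletons = cl$n_singletons,
                             assignment = cl$assignment,
                             support = sup$support)

  # 6. histology + Mann-Whitney across clusters ---------------------------
  frac <- list(`1` = c(0.50, 0.05), `2` = c(0.15, 0.45), `3` = c(0.30, 0.08))
  truth_sub <- fl$subcluster
  set.seed(.derive_seed(seed, 37L))  # per-sample fraction jitter below
  jit <- matrix(stats::runif(2 * length(truth_sub), 0.8, 1.2), ncol = 2)
  hist_rows <- lapply(seq_along(truth_sub), function(i) {
    f <- frac[[min(truth_sub[i], 3)]]
    im_seed <- .derive_seed(seed, 36L) + i
    vvg <- simulate_vvg_image(config$image_px, config$image_px,
                              collagen_fraction = min(0.95, f[1] * jit[i, 1]),
                              elastin_fraction = min(0.5, f[2] * jit[i, 2]),
                              seed = im_seed)
    psr <- simulate_psr_image(vvg, seed = im_seed)
    qs <- quantify_section(vvg$image, psr$image,
                           min_fragment_px = 16, max_hole_px = 64)
    data.frame(sample = i, cluster = cl$assignment[i],
               collagen = qs$collagen$fraction, elastin = qs$elastin$fraction,
               collagen_true = vvg$truth$collagen_fraction,
               elastin_true = vvg$truth$elastin_fraction)
  })
  hist_df <- do.call(rbind, hist_rows)
  top2 <- as.integer(names(sort(table(hist_df$cluster), decreasing = TRUE)[1:2]))
  a <- hist_df$cluster == top2[1]; b <- hist_df$cluster == top2[2]
  mw <- rbind(
    cbind(variable = "collagen", mann_whitney(hist_df$collagen[a], hist_df$collagen[b])),
    cbind(variable = "elastin", mann_whitney(hist_df$elastin[a], hist_df$elastin[b])))
  mw$p_adjusted <- holm_adjust(mw$p_raw)
  report$histology <- list(per_sample = hist_df, clusters_compared = top2,
                           mann_whitney = mw)

  class(report) <- "dissection_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.dissection_report <- function(x, ...) {
  cat("Aortic-dissection workflow report (seed ", x$config$seed, ")\n", sep = "")
  cat("  REIMS trace: ", x$reims$trace_length, " scans, ",
      x$reims$burn_span, " above threshold, max at scan ",
      x$reims$peak_index, "\n", sep = "")
  cat(sprintf("  PLS-DA mean accuracy: full %.3f | VIP-refined %.3f | pooled FL AUC %.3f\n",
              x$classification$full["accuracy"],
              x$classification$refined["accuracy"], x$classification$auc))
  cat("  FL stable clusters (AU > ", x$fl_clusters$support$threshold %||%
        x$config$au_threshold, "): ", x$fl_clusters$n_clusters, "\n", sep = "")
  invisible(x)
}

#' Write a workflow report to disk
#'
#' Flat JSON summary plus CSVs of the tabular stages.
#'
#' @param report A `dissection_report`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    config = report$config[c("seed", "fast", "n_repeats", "nboot",
                             "au_threshold", "bin_width", "image_px")],
    reims = report$reims,
    pca_explained = report$biomech$explained,
    important_vars = report$biomech$important_vars,
    classification = report$classification,
    fl_n_clusters = report$fl_clusters$n_clusters
  )
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$biomech$dunn, file.path(out_dir, "dunn_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$fl_clusters$support,
                   file.path(out_dir, "fl_cluster_support.csv"), row.names = FALSE)
  utils::write.csv(report$histology$per_sample,
                   file.path(out_dir, "histology_fractions.csv"), row.names = FALSE)
  utils::write.csv(report$histology$mann_whitney,
                   file.path(out_dir, "histology_tests.csv"), row.names = FALSE)
  invisible(out_dir)
}
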