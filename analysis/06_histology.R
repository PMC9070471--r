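#!/usr/bin/env Rscript
# Histological quantification of the FL sub-groups: VVG/PSR image pairs are
# generated per FL sample with cluster-dependent collagen/elastin content,
# quantified by the weighted-RGB index chain, and compared between the two
# largest recovered clusters with Mann-Whitney U (Holm-adjusted).

suppressPackageStartupMessages(library(aortadissect))

seed <- 42
out <- "results"
assign_df <- read.csv(file.path(out, "fl_cluster_assignment.csv"))

# cluster phenotypes: 1 collagen-rich/elastin-poor, 2 elastin-rich,
# 3 depleted in both (fractions of tissue area)
frac <- list(c(0.50, 0.05), c(0.15, 0.45), c(0.30, 0.08))
set.seed(seed)
jit <- matrix(runif(2 * nrow(assign_df), 0.8, 1.2), ncol = 2)

rows <- lapply(seq_len(nrow(assign_df)), function(i) {
  f <- frac[[min(assign_df$true_subcluster[i], 3)]]
  vvg <- simulate_vvg_image(160, 160,
                            collagen_fraction = min(0.95, f[1] * jit[i, 1]),
                            elastin_fraction = min(0.5, f[2] * jit[i, 2]),
                            seed = seed + i)
  psr <- simulate_psr_image(vvg, seed = seed + i)
  q <- quantify_section(vvg$image, psr$image,
                        min_fragment_px = 16, max_hole_px = 64)
  data.frame(sample_id = assign_df$sample_id[i],
             cluster = assign_df$cluster[i],
             collagen = q$collagen$fraction,
             collagen_err_low = q$collagen$err_low,
             collagen_err_high = q$collagen$err_high,
             elastin = q$elastin$fraction,
             elastin_err_low = q$elastin$err_low,
             elastin_err_high = q$elastin$err_high,
             collagen_true = vvg$truth$collagen_fraction,
             elastin_true = vvg$truth$elastin_fraction)
})
hist_df <- do.call(rbind, rows)
write.csv(hist_df, file.path(out, "histology_fractions.csv"), row.names = FALSE)

top2 <- as.integer(names(sort(table(hist_df$cluster), decreasing = TRUE)[1:2]))
a <- hist_df$cluster == top2[1]; b <- hist_df$cluster == top2[2]
mw <- rbind(cbind(variable = "collagen",
                  mann_whitney(hist_df$collagen[a], hist_df$collagen[b])),
            cbind(variable = "elastin",
                  mann_whitney(hist_df$elastin[a], hist_df$elastin[b])))
mw$p_adjusted <- holm_adjust(mw$p_raw)
write.csv(mw, file.path(out, "histology_tests.csv"), row.names = FALSE)

message("clusters compared: ", top2[1], " vs ", top2[2])
print(mw[, c("variable", "statistic", "p_raw", "p_adjusted")], row.names = FALSE)
message("max |recovered - painted| fraction: ",
        round(max(abs(hist_df$collagen - hist_df$collagen_true),
                  abs(hist_df$elastin - hist_df$elastin_true)), 4))
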