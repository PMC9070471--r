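#!/usr/bin/env Rscript
# Unsupervised exploration of the biomechanical/biochemical table (PCA on
# centred and scaled data) followed by Dunn Kruskal-Wallis tests with Holm
# adjustment for the variables that drive the separation.

suppressPackageStartupMessages(library(aortadissect))

out <- "results"
ft <- read.csv(file.path(out, "feature_table.csv"))
num <- as.matrix(ft[, c("g_prime", "g_dprime", "collagen", "elastin", "gag",
                        "age", "indexed_aortic_size")])

pca <- pca_explore(num)
message("PC1/PC2 explain ",
        paste(round(100 * pca$explained_variance_ratio[1:2], 1), collapse = "% / "),
        "% of the variance")
vars <- important_loadings(pca)
message("important contributors: ", paste(vars, collapse = ", "))

scores <- data.frame(sample_id = ft$sample_id, tissue_type = ft$tissue_type,
                     pca$scores[, 1:2])
write.csv(scores, file.path(out, "pca_scores.csv"), row.names = FALSE)
write.csv(data.frame(variable = rownames(pca$loadings), pca$loadings[, 1:2]),
          file.path(out, "pca_loadings.csv"), row.names = FALSE)

dunn <- do.call(rbind, lapply(vars, function(v) {
  kw <- kruskal_wallis(ft[[v]], ft$tissue_type)
  d <- dunn_posthoc(ft[[v]], ft$tissue_type)
  d$variable <- v
  d$kw_h <- kw$statistic
  d
}))
write.csv(dunn, file.path(out, "dunn_tests.csv"), row.names = FALSE)
message("pairwise tests written; adjusted P < 0.05 for:")
print(dunn[dunn$p_adjusted < 0.05, c("variable", "groups", "p_adjusted")],
      row.names = FALSE)
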