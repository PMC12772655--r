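#!/usr/bin/env Rscript
# Stage 4: PCA of the radiomics feature matrix (fitted jointly on both
# scanners), within-cluster distances per lesion type and per-scanner
# separability in the retained principal-component space.

suppressPackageStartupMessages(library(lungphantom))

feats <- read.csv("results/features.csv", check.names = FALSE)
meta_cols <- c("lesion_id", "lesion_type", "size_class", "scanner",
               "dose_mGy", "repetition")
X <- feats[, setdiff(names(feats), meta_cols)]

space <- fit_pca(X, variance_threshold = 0.95)
print(space)
pts <- project_pca(X, space)

dir.create("results", showWarnings = FALSE)
write.csv(cbind(feats[, meta_cols], as.data.frame(pts)),
          "results/pca_points.csv", row.names = FALSE)

per_scanner <- lapply(split(seq_len(nrow(feats)), feats$scanner), function(ii) {
  list(within = within_cluster_distance(pts[ii, , drop = FALSE],
                                        feats$lesion_type[ii]),
       separability = separability(pts[ii, , drop = FALSE],
                                   feats$lesion_type[ii]))
})

for (sc in names(per_scanner)) {
  cat("\n", sc, "- within-cluster distance (mean +/- SD) per lesion type:\n")
  print(per_scanner[[sc]]$within, row.names = FALSE, digits = 3)
  cat(sprintf("%s separability: %.2f\n", sc, per_scanner[[sc]]$separability))
}
cat(sprintf("\nnearest-centroid purity (all points): %.3f\n",
            cluster_purity(pts, feats$lesion_type)))

jsonlite::write_json(
  list(m = space$m, explained_variance = space$var_frac,
       purity = cluster_purity(pts, feats$lesion_type),
       per_scanner = lapply(per_scanner, function(s)
         list(within = s$within, separability = s$separability))),
  "results/cluster_report.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
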