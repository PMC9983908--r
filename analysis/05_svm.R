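#!/usr/bin/env Rscript
# SVM classification of weighted centroids.
#
# Polynomial kernel (degree 2, coefficient 0), stratified 50/50
# train/test splits, accuracy averaged over independent replicates.
# Reproduced analyses: accuracy versus number of included cell lines
# (nested subsets and exhaustive 2-line search), the MSC task, and an
# exemplar decision-boundary map.  300 replicates mirror the study
# protocol; drop to 10 for a quick look.

library(relaxcell)

seed <- 1L
out_dir <- "results"
cen <- read_centroids_csv(file.path(out_dir, "centroids.csv"))
cells <- cen[!grepl("MSC", cen$class_label), ]
msc <- cen[grepl("MSC", cen$class_label), ]

cfg <- svm_config(replicates = 300L, seed = seed)

# accuracy vs class count (10 replicates per k to keep the sweep quick)
sweep <- class_count_sweep(cells, ks = 2:10,
                           config = svm_config(replicates = 10L, seed = seed))
utils::write.csv(sweep, file.path(out_dir, "svm_class_count_sweep.csv"),
                 row.names = FALSE)
print(sweep[, c("k", "mean_accuracy", "sd_accuracy")], digits = 3)
message(sprintf("Spearman rho (k vs accuracy): %.2f",
                stats::cor(sweep$k, sweep$mean_accuracy, method = "spearman")))

# exhaustive 2-line search at the full replicate count
best2 <- combination_search(cells, 2, svm_config(replicates = 300L, seed = seed))
utils::write.csv(best2, file.path(out_dir, "svm_2line_search.csv"),
                 row.names = FALSE)
message(sprintf("best 2-line combination: %s at %.2f%%",
                best2$classes[1], 100 * best2$mean_accuracy[1]))

# the MSC task: undifferentiated vs differentiated on a single centroid
res_msc <- run_svm_replicates(msc, cfg)
message(sprintf("MSC SVM: %.2f%% +/- %.2f%% over %d replicates",
                100 * res_msc$mean, 100 * res_msc$sd, cfg$replicates))

# decision boundary of one fitted model over the centroid cloud
model <- fit_svm(cells, cfg)
t1g <- exp(seq(log(0.2), log(2), length.out = 60))
t2g <- exp(seq(log(0.01), log(0.4), length.out = 60))
bmap <- decision_boundary_map(model, t1g, t2g)
utils::write.csv(data.frame(t1 = rep(t1g, times = 60),
                            t2 = rep(t2g, each = 60),
                            class = as.vector(bmap)),
                 file.path(out_dir, "svm_decision_boundaries.csv"),
                 row.names = FALSE)

summary_json <- list(
  best_2_line = list(classes = best2$classes[1],
                     mean_accuracy_pct = 100 * best2$mean_accuracy[1]),
  ten_line_pct = 100 * sweep$mean_accuracy[sweep$k == 10],
  msc_pct = 100 * res_msc$mean)
jsonlite::write_json(summary_json, file.path(out_dir, "svm_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("SVM tables written to results/")
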