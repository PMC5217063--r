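#!/usr/bin/env Rscript
# Run the full chamber pipeline on the simulated field: rotation
# correction, segmentation, background subtraction, quadrant summaries
# and pattern classification. Compares the recovered boxes and labels
# with the simulation ground truth.

suppressMessages(library(minwaves))

movie <- read_movie("results/simulated/field.tif")
truth_boxes <- read.csv("results/simulated/true_boxes.csv")
meta <- yaml::read_yaml("results/simulated/field.yaml")

res <- run_pipeline(movie, out_dir = "results/pipeline")

cat(sprintf("estimated rotation: %.2f deg (applied: %.1f)\n",
            res$rotation_deg, -meta$field_rotation_deg))
cat(sprintf("chambers found: %d of %d\n",
            nrow(res$chambers), nrow(truth_boxes)))

got <- res$chambers[order(res$chambers$r0, res$chambers$c0), ]
truth_labels <- meta$patterns
truth_labels[truth_labels == "spiral"] <- "rotation"
# chambers are ordered row-major in the metadata, column-major by the
# segmentation; realign through the box origins
ord <- order(got$c0, got$r0)
got2 <- got[ord, ]
truth_sorted <- truth_labels[c(1, 4, 2, 5, 3, 6)]
agree <- mean(got2$label == truth_sorted)
cat(sprintf("label agreement with ground truth: %.0f%%\n", 100 * agree))
print(as.data.frame(got2[, c("chamber_id", "W_um", "L_um", "label",
                             "n_centers", "dominant_period_s")]))
cat("tables and quadrant PNGs under results/pipeline/\n")
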