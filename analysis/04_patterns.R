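#!/usr/bin/env Rscript
## Stage 4: generate and render defect patterns along every retained
## axis at -2 and +2 SD from the normal-cluster centroid, and score the
## cohort's severity along each glaucoma axis.

suppressPackageStartupMessages(library(perimix))
k_sd <- 2

cohort <- load_cohort("results/cohort.csv")
model <- read_vim_model("results/model_pruned.json")
labels <- cohort$records$fdt_label
Z <- standardize(cohort_matrix(cohort))$Z

model$cache <- perimix:::build_cache(model, Z)
model <- perimix:::finalize_projection_stats(model)
cs <- confusion(assign_clusters(responsibilities(model, Z)), labels)
ncl <- which(cs$cluster_labels == "normal")[1]
axes <- orient_axes(model, ncl, Z, labels)

masks <- region_masks_242()
rows <- list()
for (a in axes) {
  for (kk in c(-k_sd, k_sd)) {
    pg <- generate_axis_pattern(model, a, kk)
    render_pattern(pg, sprintf("results/pattern_c%d_axis%d_%+d.png",
                               a$cluster, a$axis, kk))
    rows[[length(rows) + 1]] <- data.frame(
      cluster = a$cluster, axis = a$axis, k = kk, age = pg$age,
      mean_dev = mean(pg$deviations),
      superior_dev = mean(pg$deviations[masks$superior]),
      inferior_dev = mean(pg$deviations[masks$inferior]),
      nasal_dev = mean(pg$deviations[masks$nasal]))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/pattern_regions.csv", row.names = FALSE)
print(tab, digits = 3)
cat("pattern grids rendered under results/\n")
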