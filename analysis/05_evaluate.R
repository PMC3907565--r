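#!/usr/bin/env Rscript
## Stage 5: confusion table of the pruned model and the age-ablation
## experiment (refit with the age input removed, same seeds).

suppressPackageStartupMessages(library(perimix))
cohort <- load_cohort("results/cohort.csv")
model <- read_vim_model("results/model_pruned.json")
labels <- cohort$records$fdt_label
Z <- standardize(cohort_matrix(cohort))$Z

cs <- confusion(assign_clusters(responsibilities(model, Z)), labels)
print(cs)
write_confusion(cs, "results/confusion.csv")

cfg <- model$config
cfg$n_iterations <- 150L
ab <- age_ablation(cohort, cfg)
cat("\nwith age:\n"); print(ab$with_age)
cat("\nwithout age:\n"); print(ab$without_age)
delta <- data.frame(
  metric = c("specificity", "sensitivity"),
  with_age = c(ab$with_age$specificity, ab$with_age$sensitivity),
  without_age = c(ab$without_age$specificity, ab$without_age$sensitivity))
write.csv(delta, "results/age_ablation.csv", row.names = FALSE)
if (!is.null(ab$axis_differences))
  write.csv(ab$axis_differences, "results/age_ablation_axes.csv",
            row.names = FALSE)
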