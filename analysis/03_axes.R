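#!/usr/bin/env Rscript
## Stage 3: knee-point axis selection, constrained retraining, and axis
## orientation.
##
## Ranks each cluster's axes by magnitude, keeps the axes before the
## knee of the magnitude curve (automatic detection; override by setting
## knee_override below, as published analyses chose knees by eye),
## retrains the constrained model, and orients every retained axis so
## its positive direction means greater defect severity.

suppressPackageStartupMessages(library(perimix))
knee_override <- NULL   # e.g. c(2, 2, 5) to pin per-cluster counts

cohort <- load_cohort("results/cohort.csv")
model <- read_vim_model("results/model_selected.json")
labels <- cohort$records$fdt_label
Z <- standardize(cohort_matrix(cohort))$Z

## refresh projection stats on the training data
resp <- responsibilities(model, Z)
fit <- list(model = model, responsibilities = resp)
class(fit) <- "vim_fit"
model$cache <- perimix:::build_cache(model, Z)
model <- perimix:::finalize_projection_stats(model)

mag_tab <- do.call(rbind, lapply(seq_len(model$K), function(k) {
  m <- axis_magnitudes(model, k)
  data.frame(cluster = k, rank = seq_len(nrow(m)), axis = m$axis,
             magnitude = m$magnitude)
}))
write.csv(mag_tab, "results/axis_magnitudes.csv", row.names = FALSE)

retained <- vapply(seq_len(model$K), function(k) {
  ov <- if (is.null(knee_override)) NULL else knee_override[k]
  knee_point(axis_magnitudes(model, k)$magnitude, override = ov)
}, integer(1))
cat("retained axes per cluster:", paste(retained, collapse = "/"), "\n")

fit2 <- prune_and_retrain(model, retained, Z, n_iterations = 150)
write_vim_model(fit2$model, "results/model_pruned.json")

cs <- confusion(assign_clusters(fit2$responsibilities), labels)
ncl <- which(cs$cluster_labels == "normal")[1]
axes <- orient_axes(fit2$model, ncl, Z, labels)
rep_tab <- as.data.frame(axes)
rep_tab$cluster_label <- cs$cluster_labels[rep_tab$cluster]
rep_tab$n_members <- NA_integer_
for (k in seq_len(fit2$model$K)) {
  na <- assign_to_nearest_axis(fit2$model, Z, k, axes)
  sizes <- table(na$axis)
  sel <- rep_tab$cluster == k
  rep_tab$n_members[sel] <- as.integer(sizes[as.character(rep_tab$axis[sel])])
}
write.csv(rep_tab, "results/axis_report.csv", row.names = FALSE)

library(ggplot2)
p <- ggplot(mag_tab, aes(rank, magnitude)) +
  geom_line() + geom_point() +
  facet_wrap(~cluster, labeller = label_both) +
  labs(title = "axis magnitude vs rank (knee marks the retained set)") +
  theme_minimal()
ggsave("results/axis_magnitudes.png", p, width = 7, height = 3, dpi = 150)
print(rep_tab)
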