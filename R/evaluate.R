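#' Label clusters by majority FDT status
#'
#' A cluster is labelled `"normal"` when strictly more than half of its
#' (argmax-assigned) members carry the FDT-normal label, otherwise
#' `"glaucoma"`.  Exact 50/50 ties go to `"glaucoma"` (conservative for a
#' screening context) and empty clusters are labelled `"glaucoma"` with a
#' warning.
#'
#' @param assignments Integer cluster assignments (or an N x K
#'   responsibility matrix, reduced by argmax).
#' @param labels Character vector, `"normal"`/`"abnormal"` per record.
#' @param K Number of clusters (inferred when `assignments` is a matrix).
#' @return Character vector of length K: `"normal"` or `"glaucoma"`.
#' @export
label_clusters <- function(assignments, labels, K = NULL) {
  if (is.matrix(assignments)) {
    K <- ncol(assignments)
    assignments <- assign_clusters(assignments)
  }
  if (is.null(K)) K <- max(assignments)
  vapply(seq_len(K), function(k) {
    memb <- labels[assignments == k]
    if (!length(memb)) {
      warning("cluster ", k, " is empty; labelled glaucoma")
      return("glaucoma")
    }
    if (mean(memb == "normal") > 0.5) "normal" else "glaucoma"
  }, character(1))
}

#' Confusion summary of a clustering against FDT labels
#'
#' Builds the cluster-by-label count table, labels each cluster by
#' majority, and computes specificity (fraction of FDT-normal fields in
#' normal-labelled clusters) and sensitivity (fraction of FDT-abnormal
#' fields in glaucoma-labelled clusters).
#'
#' `x` may be a vector of cluster assignments (with `labels`), an N x K
#' responsibility matrix (with `labels`), or a pre-tabulated 2 x K count
#' matrix with rows `normal` and `abnormal` -- the form printed in
#' published cluster tables.
#'
#' @param x Assignments, responsibilities, or a 2 x K count matrix.
#' @param labels FDT labels (ignored when `x` is a count matrix).
#' @return Object of class `confusion_summary`: `counts` (2 x K),
#'   `cluster_labels`, `specificity`, `sensitivity` (NA when the cohort
#'   has no abnormal fields), `n`.
#' @export
confusion <- function(x, labels = NULL) {
  if (is.matrix(x) && !is.null(rownames(x)) &&
      all(c("normal", "abnormal") %in% rownames(x))) {
    counts <- x[c("normal", "abnormal"), , drop = FALSE]
  } else {
    if (is.matrix(x)) x <- assign_clusters(x)
    stopifnot(length(x) == length(labels))
    K <- max(x)
    counts <- rbind(
      normal = tabulate(x[labels == "normal"], nbins = K),
      abnormal = tabulate(x[labels == "abnormal"], nbins = K)
    )
  }
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("C", seq_len(ncol(counts)))
  tot <- colSums(counts)
  clab <- vapply(seq_len(ncol(counts)), function(k) {
    if (tot[k] == 0) {
      warning("cluster ", k, " is empty; labelled glaucoma")
      return("glaucoma")
    }
    if (counts["normal", k] / tot[k] > 0.5) "normal" else "glaucoma"
  }, character(1))
  n_norm <- sum(counts["normal", ])
  n_abn <- sum(counts["abnormal", ])
  spec <- if (n_norm > 0)
    sum(counts["normal", clab == "normal"]) / n_norm else NA_real_
  sens <- if (n_abn > 0)
    sum(counts["abnormal", clab == "glaucoma"]) / n_abn else NA_real_
  structure(list(counts = counts, cluster_labels = clab,
                 specificity = spec, sensitivity = sens,
                 n = n_norm + n_abn),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("cluster-by-label counts:\n")
  print(x$counts)
  cat("cluster labels:", paste(x$cluster_labels, collapse = ", "), "\n")
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("specificity %s, sensitivity %s (n = %d)\n",
              fmt(x$specificity), fmt(x$sensitivity), x$n))
  invisible(x)
}

#' Write a confusion summary as a CSV table
#' @param x A `confusion_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(x, path) {
  tab <- rbind(x$counts, total = colSums(x$counts))
  df <- data.frame(row = rownames(tab), tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  cat(sprintf("# specificity,%.4f\n# sensitivity,%.4f\n",
              x$specificity, x$sensitivity),
      file = path, append = TRUE)
  invisible(path)
}

#' Age-ablation experiment
#'
#' Refits the selected pipeline with the age input removed (the constant
#' column is dropped before standardization rather than carried as a
#' degenerate dimension) under the same seed, and compares cluster
#' performance and generated axis patterns with the full model.
#'
#' @param cohort Labelled `fdt_cohort`.
#' @param config A [vim_config()] describing the selected model.
#' @param k_sd SD multiplier at which patterns are compared (default 2).
#' @return List of class `age_ablation`: `with_age` and `without_age`
#'   (each a `confusion_summary`), and `axis_differences` (data.frame:
#'   one row per glaucoma-cluster axis of the full model, its best-
#'   matching ablated axis by absolute cosine on the threshold
#'   dimensions, and the maximum absolute pointwise difference between
#'   the two generated deviation patterns, in dB).
#' @export
age_ablation <- function(cohort, config, k_sd = 2) {
  labels <- cohort$records$fdt_label
  run_one <- function(include_age) {
    fit <- fit_vim(cohort, config, include_age = include_age)
    asg <- assign_clusters(fit$responsibilities)
    list(fit = fit, cs = confusion(asg, labels),
         Z = standardize(cohort_matrix(cohort, include_age))$Z)
  }
  full <- run_one(TRUE)
  ablt <- run_one(FALSE)
  diffs <- tryCatch(
    compare_axis_patterns(full, ablt, labels, k_sd),
    error = function(e) {
      warning("axis pattern comparison failed: ", conditionMessage(e))
      NULL
    })
  structure(list(with_age = full$cs, without_age = ablt$cs,
                 axis_differences = diffs),
            class = "age_ablation")
}

compare_axis_patterns <- function(full, ablt, labels, k_sd) {
  axes_of <- function(run) {
    ncl <- which(run$cs$cluster_labels == "normal")[1L]
    if (is.na(ncl)) stop("no normal-labelled cluster")
    list(ncl = ncl,
         axes = orient_axes(run$fit$model, ncl, run$Z, labels))
  }
  af <- axes_of(full)
  aa <- axes_of(ablt)
  gf <- Filter(function(a) full$cs$cluster_labels[a$cluster] == "glaucoma",
               af$axes)
  ga <- Filter(function(a) ablt$cs$cluster_labels[a$cluster] == "glaucoma",
               aa$axes)
  if (!length(gf) || !length(ga)) stop("no glaucoma-cluster axes")
  rows <- lapply(gf, function(ax) {
    d52 <- ax$direction[1:52]
    cosims <- vapply(ga, function(bx) {
      e52 <- bx$direction[1:52]
      abs(sum(d52 * e52)) / sqrt(sum(d52^2) * sum(e52^2))
    }, numeric(1))
    best <- which.max(cosims)
    pf <- generate_axis_pattern(full$fit$model, ax, k_sd, af$ncl)
    pa <- generate_axis_pattern(ablt$fit$model, ga[[best]], k_sd, aa$ncl)
    data.frame(cluster = ax$cluster, axis = ax$axis,
               matched_cluster = ga[[best]]$cluster,
               matched_axis = ga[[best]]$axis,
               cosine = cosims[best],
               max_abs_diff_db = max(abs(pf$deviations - pa$deviations)))
  })
  do.call(rbind, rows)
}
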