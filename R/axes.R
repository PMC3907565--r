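#' Knee point of a sorted magnitude curve
#'
#' Finds the elbow of a descending magnitude curve as the interior
#' position with the largest discrete second difference
#' (`m[i-1] - 2 m[i] + m[i+1]`, the point of maximum upward curvature)
#' and retains the axes before it.  Axis counts in published analyses
#' were chosen by eye from such curves, so `override` bypasses detection
#' and is first-class.
#'
#' @param magnitudes Non-negative magnitudes sorted in decreasing order.
#' @param override Manually chosen retained count (bypasses detection).
#' @return Number of axes to retain (>= 1).
#' @export
knee_point <- function(magnitudes, override = NULL) {
  n <- length(magnitudes)
  if (n == 0L) stop("empty magnitude list")
  if (!is.null(override)) {
    stopifnot(override >= 1, override <= n)
    return(as.integer(override))
  }
  if (is.unsorted(rev(magnitudes), strictly = FALSE))
    stop("magnitudes must be sorted in decreasing order")
  if (n <= 2L || length(unique(magnitudes)) == 1L) {
    if (length(unique(magnitudes)) == 1L && n > 1L)
      warning("no knee in an all-equal magnitude curve; retaining all axes")
    else if (n == 2L)
      warning("need at least 3 magnitudes to locate a knee; retaining all")
    return(n)
  }
  i <- 2:(n - 1L)
  d2 <- magnitudes[i - 1L] - 2 * magnitudes[i] + magnitudes[i + 1L]
  as.integer(i[which.max(d2)] - 1L)
}

## Subset one cluster's variational factors to the retained axes.  The
## stored q(A) row-covariance parameterisation is cut to the kept rows of
## Ubig (still a valid PSD parameterisation); its entropy is recomputed
## from the actual log-determinants since the eigen shortcut no longer
## applies.
prune_cluster <- function(cl, keep) {
  D <- length(cl$mu_mean)
  cl$A_mean <- cl$A_mean[, keep, drop = FALSE]
  cl$VarA <- cl$VarA[, keep, drop = FALSE]
  aux <- cl$A_aux
  Ubig <- aux$Ubig[keep, , drop = FALSE]
  f <- 1 / (outer(aux$psi_used, aux$lam) + 1)
  logdets <- vapply(seq_len(D), function(d) {
    S <- Ubig %*% (f[d, ] * t(Ubig))
    determinant(S, logarithm = TRUE)$modulus
  }, numeric(1))
  Lnew <- length(keep)
  cl$A_aux <- list(Ubig = Ubig, lam = aux$lam, psi_used = aux$psi_used,
                   entropy = 0.5 * D * Lnew * (LOG2PI + 1) +
                     0.5 * sum(logdets))
  cl$alpha_a <- cl$alpha_a[keep]
  cl$alpha_b <- cl$alpha_b[keep]
  cl$beta_a <- cl$beta_a[keep]
  cl$beta_b <- cl$beta_b[keep]
  cl$w_conc <- cl$w_conc[keep, , drop = FALSE]
  cl$eta_mean <- cl$eta_mean[keep, , drop = FALSE]
  cl$eta_var <- cl$eta_var[keep, , drop = FALSE]
  cl$src_sd <- cl$src_sd[keep]
  cl
}

#' Prune axes and retrain the constrained model
#'
#' Drops each cluster's lowest-magnitude axes so that `retained[k]`
#' remain, then continues training (warm start from the pruned
#' posterior, preserving the selected basin) for up to `n_iterations`
#' further sweeps with the axis counts fixed.
#'
#' @param fit A `vim_fit` (or a `vim_model` with projection stats).
#' @param retained Integer vector, retained axis count per cluster
#'   (every entry >= 1).
#' @param Z The standardized training data.
#' @param n_iterations Retraining sweep cap (default 500).
#' @return A `vim_fit` for the constrained model; its `model$elbo_trace`
#'   covers only the retraining phase.
#' @export
prune_and_retrain <- function(fit, retained, Z, n_iterations = 500L) {
  model <- if (inherits(fit, "vim_fit")) fit$model else fit
  stopifnot(length(retained) == model$K)
  if (any(retained < 1)) stop("retained axis count must be >= 1 per cluster")
  for (k in seq_len(model$K)) {
    mag <- axis_magnitudes(model, k)
    if (retained[k] > nrow(mag))
      stop("cluster ", k, " has only ", nrow(mag), " axes")
    keep <- sort(mag$axis[seq_len(retained[k])])
    if (length(keep) == ncol(model$clusters[[k]]$A_mean)) next
    model$clusters[[k]] <- prune_cluster(model$clusters[[k]], keep)
  }
  model$cache <- NULL   # per-observation factors are rebuilt on resume
  model$elbo_trace <- numeric(0)
  cfg <- model$config
  cfg$n_iterations <- as.integer(n_iterations)
  std <- model$standardization
  out <- fit_vbica_mm(Z, cfg, model = model)
  out$model$standardization <- std
  out
}

#' Orient cluster axes by defect severity
#'
#' Fixes the sign of every axis so that movement in the positive
#' direction means greater abnormality: the mean projection of
#' abnormal-labelled member fields must exceed that of normal-labelled
#' members.  In clusters carrying a single label class the fallback
#' convention is used: the positive direction must decrease mean field
#' sensitivity (in dB, via the model's standardization).  Projection SDs
#' are computed over each axis's cluster members.
#'
#' @param model Fitted `vim_model` (or `vim_fit`).
#' @param normal_cluster_index Index of the majority-normal cluster
#'   (from [label_clusters()]); stored on each spec as the severity
#'   reference.
#' @param Z Standardized training data.
#' @param labels FDT labels aligned with `Z` rows.
#' @return List of axis specs (class `vim_axes`); each spec holds
#'   `cluster`, `axis`, `direction` (oriented unit D-vector),
#'   `magnitude`, `projection_sd`, `orientation_sign`, `ref_cluster`,
#'   `oriented = TRUE`.
#' @export
orient_axes <- function(model, normal_cluster_index, Z, labels) {
  if (inherits(model, "vim_fit")) model <- model$model
  resp <- responsibilities(model, Z)
  asg <- assign_clusters(resp)
  specs <- list()
  for (k in seq_len(model$K)) {
    cl <- model$clusters[[k]]
    memb <- which(asg == k)
    mag <- axis_magnitudes(model, k)
    mag <- mag[order(mag$axis), , drop = FALSE]
    for (l in seq_len(ncol(cl$A_mean))) {
      col <- cl$A_mean[, l]
      nrm <- sqrt(sum(col^2))
      dir <- if (nrm > 0) col / nrm else {
        v <- numeric(model$D); v[1L] <- 1; v
      }
      proj <- as.numeric(sweep(Z[memb, , drop = FALSE], 2L, cl$mu_mean) %*% dir)
      ml <- labels[memb]
      sign_flip <- 1
      if (length(unique(ml)) == 2L) {
        if (mean(proj[ml == "abnormal"]) < mean(proj[ml == "normal"]))
          sign_flip <- -1
      } else {
        ## single-label cluster: positive direction must lose sensitivity
        eff <- dir[1:52]
        if (!is.null(model$standardization))
          eff <- eff * model$standardization$scale[1:52]
        if (sum(eff) > 0) sign_flip <- -1
      }
      dir <- sign_flip * dir
      psd <- stats::sd(sign_flip * proj)
      if (!is.finite(psd) || psd == 0) psd <- cl$src_sd[l] * 1
      specs[[length(specs) + 1L]] <- structure(list(
        cluster = k, axis = l, direction = dir,
        magnitude = mag$magnitude[l],
        projection_sd = psd, orientation_sign = sign_flip,
        ref_cluster = normal_cluster_index, oriented = TRUE
      ), class = "axis_spec")
    }
  }
  structure(specs, class = "vim_axes")
}

#' @export
as.data.frame.vim_axes <- function(x, ...) {
  do.call(rbind, lapply(x, function(a)
    data.frame(cluster = a$cluster, axis = a$axis, magnitude = a$magnitude,
               projection_sd = a$projection_sd,
               orientation_sign = a$orientation_sign)))
}

#' Assign each cluster member to its nearest axis
#'
#' Members (argmax responsibility) of the cluster are assigned to the
#' retained axis whose direction has the largest absolute cosine
#' similarity with the member's cluster-centered field, partitioning the
#' cluster into per-axis sets.
#'
#' @param model Fitted `vim_model` (or `vim_fit`).
#' @param Z Standardized data.
#' @param cluster_index Cluster to partition.
#' @param axes Optional `vim_axes` (restricts to these axes of the
#'   cluster); defaults to all of the cluster's axes, unoriented.
#' @return data.frame with columns `record` (row index into `Z`) and
#'   `axis` (assigned axis index).
#' @export
assign_to_nearest_axis <- function(model, Z, cluster_index, axes = NULL) {
  if (inherits(model, "vim_fit")) model <- model$model
  cl <- model$clusters[[cluster_index]]
  dirs <- if (!is.null(axes)) {
    sel <- Filter(function(a) a$cluster == cluster_index, axes)
    if (!length(sel)) stop("no axes supplied for cluster ", cluster_index)
    list(mat = vapply(sel, `[[`, numeric(model$D), "direction"),
         idx = vapply(sel, `[[`, numeric(1), "axis"))
  } else {
    A <- cl$A_mean
    nrms <- sqrt(colSums(A^2))
    list(mat = sweep(A, 2L, pmax(nrms, .Machine$double.eps), "/"),
         idx = seq_len(ncol(A)))
  }
  resp <- responsibilities(model, Z)
  memb <- which(assign_clusters(resp) == cluster_index)
  Zc <- sweep(Z[memb, , drop = FALSE], 2L, cl$mu_mean)
  nrm <- sqrt(rowSums(Zc^2))
  cosim <- abs(Zc %*% dirs$mat) / pmax(nrm, .Machine$double.eps)
  best <- max.col(cosim, ties.method = "first")
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " member(s) coincide with the cluster mean; ",
            "assigned to the first axis")
    best[zero] <- 1L
  }
  data.frame(record = memb, axis = dirs$idx[best])
}
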