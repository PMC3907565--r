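#' Candidate-model search grid
#'
#' The candidate space explored before selection: every combination of
#' cluster count, axis maximum and source mixture-component count, each
#' refitted from `n_restarts` random initialisations.  Defaults mirror
#' the full design (4 x 2 x 3 x 30 = 720 candidates); reduced grids are
#' used for fast demonstrations.
#'
#' @param cluster_counts Integer set of cluster counts (default 2:5).
#' @param axis_maxima Integer set of per-cluster axis maxima (default
#'   c(10, 20)).
#' @param mixture_components Integer set of source mixture-component
#'   counts (default c(3, 6, 8)).
#' @param n_restarts Random initialisations per configuration (default 30).
#' @param n_iterations,convergence_tol Passed to each [vim_config()].
#' @param master_seed Seed from which every candidate's seed is derived.
#' @param priors Prior overrides passed to [vim_config()].
#' @return List of class `search_grid`.
#' @export
search_grid <- function(cluster_counts = 2:5, axis_maxima = c(10L, 20L),
                        mixture_components = c(3L, 6L, 8L),
                        n_restarts = 30L, n_iterations = 500L,
                        convergence_tol = 1e-8, master_seed = 1L,
                        priors = list()) {
  stopifnot(length(cluster_counts) >= 1, length(axis_maxima) >= 1,
            length(mixture_components) >= 1, n_restarts >= 1)
  structure(list(
    cluster_counts = sort(unique(as.integer(cluster_counts))),
    axis_maxima = sort(unique(as.integer(axis_maxima))),
    mixture_components = sort(unique(as.integer(mixture_components))),
    n_restarts = as.integer(n_restarts),
    n_iterations = as.integer(n_iterations),
    convergence_tol = convergence_tol,
    master_seed = master_seed, priors = priors
  ), class = "search_grid")
}

#' Enumerate a search grid
#'
#' Cartesian product of the grid sets, restarts innermost, in a fixed
#' deterministic order (K, then L_max, then m, then restart).  Each
#' candidate receives a seed derived by hashing (master seed, K, L_max,
#' m, restart); seeds are pairwise distinct so the grid is reproducible
#' and restartable in any execution order.
#'
#' @param grid A [search_grid()].
#' @return data.frame with columns `candidate`, `K`, `L_max`, `m`,
#'   `restart`, `seed`.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  g <- expand.grid(restart = seq_len(grid$n_restarts),
                   m = grid$mixture_components,
                   L_max = grid$axis_maxima,
                   K = grid$cluster_counts)
  g <- g[, c("K", "L_max", "m", "restart")]
  g$seed <- mapply(function(K, L, m, r) derive_seed(grid$master_seed, K, L, m, r),
                   g$K, g$L_max, g$m, g$restart)
  while (anyDuplicated(g$seed))   # hash collisions are bumped deterministically
    g$seed[duplicated(g$seed)] <-
      (g$seed[duplicated(g$seed)] + 1) %% 2147483647
  data.frame(candidate = seq_len(nrow(g)), g, row.names = NULL)
}

#' Fit a mixture model to a cohort
#'
#' Convenience wrapper: builds the N x 53 input (52 thresholds + age),
#' standardizes it, fits, and stores the standardization in the model so
#' axis patterns and severities can be mapped back to dB and years.
#' Labels never enter this function.
#'
#' @param cohort An `fdt_cohort`.
#' @param config A [vim_config()].
#' @param include_age Set `FALSE` to fit on thresholds alone (52 dims).
#' @return A `vim_fit`.
#' @export
fit_vim <- function(cohort, config, include_age = TRUE) {
  std <- standardize(cohort_matrix(cohort, include_age = include_age))
  fit <- fit_vbica_mm(std$Z, config)
  fit$model$standardization <- std[c("center", "scale")]
  fit
}

#' Run the candidate-model search
#'
#' Fits one model per grid candidate and scores each against the cohort's
#' FDT labels (labels are used only for this post-hoc scoring, never
#' inside fitting).  Candidate seeds come from [enumerate_grid()], so
#' results do not depend on execution order.
#'
#' @param cohort Labelled `fdt_cohort`.
#' @param grid A [search_grid()].
#' @param keep_fits Keep every fitted model (memory permitting); the
#'   selected candidate can otherwise be refitted from its seed.
#' @param verbose Print one line per candidate.
#' @return List of class `vim_search`: `table` (one row per candidate:
#'   config, seed, elbo, converged, specificity, sensitivity) and `fits`
#'   (list, `NULL` entries unless `keep_fits`).
#' @export
run_search <- function(cohort, grid, keep_fits = TRUE, verbose = FALSE) {
  cand <- enumerate_grid(grid)
  labels <- cohort$records$fdt_label
  fits <- vector("list", nrow(cand))
  res <- data.frame(cand, elbo = NA_real_, converged = NA,
                    specificity = NA_real_, sensitivity = NA_real_,
                    error = NA_character_)
  for (i in seq_len(nrow(cand))) {
    cfg <- vim_config(K = cand$K[i], L_max = cand$L_max[i], m = cand$m[i],
                      n_iterations = grid$n_iterations,
                      convergence_tol = grid$convergence_tol,
                      seed = cand$seed[i], priors = grid$priors)
    fit <- tryCatch(fit_vim(cohort, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      res$error[i] <- conditionMessage(fit)
      warning("candidate ", i, " failed: ", res$error[i])
      next
    }
    cs <- confusion(assign_clusters(fit$responsibilities), labels)
    res$elbo[i] <- fit$elbo
    res$converged[i] <- fit$converged
    res$specificity[i] <- cs$specificity
    res$sensitivity[i] <- cs$sensitivity
    if (keep_fits) fits[[i]] <- fit
    if (verbose)
      message(sprintf(
        "candidate %d/%d K=%d L=%d m=%d restart=%d: spec %.3f sens %.3f",
        i, nrow(cand), cand$K[i], cand$L_max[i], cand$m[i],
        cand$restart[i], cs$specificity, cs$sensitivity))
  }
  structure(list(table = res, fits = fits, grid = grid),
            class = "vim_search")
}

#' Select the best candidate at a specificity goal
#'
#' Among candidates meeting the specificity goal, picks the one with
#' maximal sensitivity; ties broken by higher ELBO, then lower K, then
#' lower candidate index.  If no candidate meets the goal, falls back to
#' the highest-specificity candidate under the same tie-breaks.  A pure
#' function of the candidate table.
#'
#' @param candidates A `vim_search` or its `table` data.frame.
#' @param spec_goal Specificity goal (default 0.90).
#' @return The selected row of the table (single-row data.frame).
#' @export
select_best <- function(candidates, spec_goal = 0.90) {
  tab <- if (inherits(candidates, "vim_search")) candidates$table else candidates
  tab <- tab[!is.na(tab$specificity), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no successful candidates to select from")
  feasible <- tab$specificity >= spec_goal
  pool <- if (any(feasible)) tab[feasible, , drop = FALSE] else tab
  key1 <- if (any(feasible)) pool$sensitivity else pool$specificity
  ord <- order(-key1, -pool$elbo, pool$K, pool$candidate)
  pool[ord[1L], , drop = FALSE]
}
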