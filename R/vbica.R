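#' Configuration of a variational Bayesian ICA mixture model
#'
#' @param K Number of Gaussian clusters (>= 1).
#' @param L_max Maximum axes per cluster (1 <= L_max < D); automatic
#'   relevance determination shrinks surplus axes during fitting.
#' @param m Gaussian components per source (>= 1); the grid used for
#'   model search draws from \{3, 6, 8\}.
#' @param n_iterations Training sweeps cap (default 500).
#' @param convergence_tol Relative ELBO change below which training stops
#'   early (default 1e-8).
#' @param seed Seed controlling initialisation.
#' @param priors Named list of prior hyperparameters; any subset of
#'   `alpha0` (cluster-weight Dirichlet), `d0` (source-component
#'   Dirichlet), `tau_mu` (cluster-mean precision), `a_alpha`/`b_alpha`
#'   (ARD Gamma), `a_psi`/`b_psi` (noise Gamma), `a_beta`/`b_beta`
#'   (source-precision Gamma), `tau_eta` (component-mean precision).
#' @return List of class `vim_config`.
#' @export
vim_config <- function(K, L_max, m = 3L, n_iterations = 500L,
                       convergence_tol = 1e-8, seed = 1L,
                       priors = list()) {
  stopifnot(K >= 1, L_max >= 1, m >= 1, n_iterations >= 1,
            convergence_tol >= 0)
  p <- list(alpha0 = 1, d0 = 1, tau_mu = 1e-2,
            a_alpha = 1e-2, b_alpha = 1e-2,
            a_psi = 1e-2, b_psi = 1e-2,
            a_beta = 2, b_beta = 2, tau_eta = 1)
  unknown <- setdiff(names(priors), names(p))
  if (length(unknown)) stop("unknown prior hyperparameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(priors)] <- priors
  if (any(unlist(p) <= 0)) stop("prior hyperparameters must be positive")
  structure(list(K = as.integer(K), L_max = as.integer(L_max),
                 m = as.integer(m), n_iterations = as.integer(n_iterations),
                 convergence_tol = convergence_tol, seed = seed, priors = p),
            class = "vim_config")
}

#' Standardize a data matrix column-wise
#'
#' Centers and scales every column to zero mean / unit variance and keeps
#' the parameters for the inverse transform.  The mixture model is always
#' fitted in this space: thresholds (dB) and age (years) enter one vector,
#' and z-scoring keeps either from dominating by units alone.
#'
#' @param X Numeric matrix, N >= 2 rows, no missing values.
#' @return List with `Z` (standardized matrix), `center`, `scale`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("standardize needs at least 2 rows")
  if (any(!is.finite(X))) stop("standardize: missing or non-finite values")
  if (!is.null(colnames(X)) && any(colnames(X) == "fdt_label"))
    stop("labels must not enter the model input")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zv <- which(scl == 0)
  if (length(zv)) {
    nm <- if (is.null(colnames(X))) as.character(zv) else colnames(X)[zv]
    stop("zero-variance column: ", paste(nm, collapse = ", "))
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  list(Z = Z, center = ctr, scale = scl)
}

#' Invert a standardization
#' @param Z Matrix (or vector, taken as one row) in standardized space.
#' @param std The list returned by [standardize()] (or the
#'   `standardization` element of a fitted model).
#' @return Matrix in original units.
#' @export
destandardize <- function(Z, std) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  sweep(sweep(Z, 2L, std$scale, "*"), 2L, std$center, "+")
}

#' Initialise a variational Bayesian ICA mixture model
#'
#' Cluster means start from a seeded k-means partition of `Z` (plus a
#' small seeded jitter so distinct seeds give distinct starts); mixing
#' matrices start from small random entries; every other variational
#' factor starts at its prior.  The returned model carries a consistent
#' per-observation cache, so its ELBO is finite before any sweep.
#'
#' @param Z Standardized data matrix.
#' @param config A [vim_config()].
#' @param init `"kmeans"` (default) or `"random"` cluster-mean start.
#' @return An object of class `vim_model`.
#' @export
init_model <- function(Z, config, init = c("kmeans", "random")) {
  init <- match.arg(init)
  Z <- as.matrix(Z)
  n <- nrow(Z); D <- ncol(Z)
  K <- config$K; L <- config$L_max; m <- config$m
  if (K > n) stop("more clusters than observations")
  if (L >= D) stop("L_max must be below the data dimension")
  model <- with_seed(config$seed, {
    centers <- if (K == 1L) {
      matrix(colMeans(Z), 1L, D)
    } else if (init == "kmeans") {
      stats::kmeans(Z, centers = K, nstart = 3L, iter.max = 50L)$centers
    } else {
      Z[sample.int(n, K), , drop = FALSE]
    }
    centers <- centers + matrix(stats::rnorm(K * D, 0, 0.01), K, D)
    d2 <- vapply(seq_len(K), function(k)
      rowSums(sweep(Z, 2L, centers[k, ])^2), numeric(n))
    hard <- max.col(-matrix(d2, n, K), ties.method = "first")
    clusters <- lapply(seq_len(K), function(k) {
      eta0 <- if (m == 1L) matrix(0, L, 1L) else
        matrix(rep(seq(-1, 1, length.out = m), each = L), L, m) +
          matrix(stats::rnorm(L * m, 0, 0.05), L, m)
      ## principal directions of the cluster's members, scaled by the
      ## spread above the trailing-eigenvalue floor, start the mixing
      ## matrix close to the dominant local subspace; the seeded jitter
      ## keeps restarts distinct
      memb <- Z[hard == k, , drop = FALSE]
      if (nrow(memb) > L + 1L) {
        eig <- eigen(stats::cov(memb), symmetric = TRUE)
        ev <- pmax(eig$values, 0)
        floorv <- stats::median(ev)
        sc <- sqrt(pmax(ev[seq_len(L)] - floorv, 0.01))
        A0 <- eig$vectors[, seq_len(L), drop = FALSE] * rep(sc, each = D)
        ## rotate the clearly supra-noise directions by a fixed-point ICA
        ## pass on the whitened scores: coordinate ascent rotates the
        ## mixing matrix only very slowly, so starting near the
        ## independent basis (not an arbitrary principal one) matters
        r <- sum(ev[seq_len(L)] - floorv > 0.1 * max(ev[1L] - floorv, 1e-12))
        if (r >= 2L && nrow(memb) > 5L * r) {
          Tm <- sweep(memb, 2L, colMeans(memb)) %*%
            eig$vectors[, seq_len(r), drop = FALSE]
          Tm <- sweep(Tm, 2L, pmax(sqrt(ev[seq_len(r)]), 1e-8), "/")
          Wrot <- fastica_rotation(Tm, seed_matrix =
                                     matrix(stats::rnorm(r * r), r, r))
          A0[, seq_len(r)] <- eig$vectors[, seq_len(r), drop = FALSE] %*%
            (sc[seq_len(r)] * t(Wrot))
        }
      } else {
        A0 <- matrix(0, D, L)
      }
      A0 <- A0 + matrix(stats::rnorm(D * L, 0, 0.05), D, L)
      list(
        mu_mean = as.numeric(centers[k, ]), mu_var = rep(0.01, D),
        A_mean = A0,
        VarA = matrix(0.01, D, L),
        A_aux = list(Ubig = diag(sqrt(0.02), L), lam = rep(1, L),
                     psi_used = rep(1, D),
                     entropy = 0.5 * D * L * (LOG2PI + 1) +
                       0.5 * D * L * log(0.01)),
        alpha_a = rep(config$priors$a_alpha, L),
        alpha_b = rep(config$priors$b_alpha, L),
        psi_a = rep(config$priors$a_psi, D),
        psi_b = rep(config$priors$b_psi, D),
        beta_a = rep(config$priors$a_beta, L),
        beta_b = rep(config$priors$b_beta, L),
        w_conc = matrix(config$priors$d0, L, m),
        eta_mean = eta0, eta_var = matrix(0.1, L, m),
        src_sd = rep(NA_real_, L)
      )
    })
    structure(list(
      config = config, priors = config$priors, K = K, D = D,
      pi_conc = rep(config$priors$alpha0, K),
      clusters = clusters, standardization = NULL,
      elbo_trace = numeric(0), cache = NULL
    ), class = "vim_model")
  })
  model$cache <- build_cache(model, Z)
  model
}

#' @export
print.vim_model <- function(x, ...) {
  L <- vapply(x$clusters, function(cl) ncol(cl$A_mean), integer(1))
  cat(sprintf("<vim_model> K = %d clusters, D = %d, axes per cluster: %s\n",
              x$K, x$D, paste(L, collapse = "/")))
  if (length(x$elbo_trace))
    cat(sprintf("  %d sweeps, final ELBO %.4f\n",
                length(x$elbo_trace), utils::tail(x$elbo_trace, 1L)))
  invisible(x)
}

#' One coordinate-ascent sweep of the variational posterior
#'
#' Updates, in fixed order: cluster responsibilities; per-cluster source
#' posteriors and source-component responsibilities; mixing-matrix
#' posteriors; ARD precisions; cluster means; noise precisions;
#' source-mixture parameters (weights, component means, precisions); and
#' cluster proportions.  The returned ELBO never falls below the previous
#' sweep's value by more than 1e-6 relative (coordinate ascent on a
#' single objective).
#'
#' @param model A `vim_model`.
#' @param Z The standardized data the model is being fitted to.
#' @return List with elements `model` and `elbo`.
#' @export
vb_sweep <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model$D) stop("data dimension does not match model")
  cache <- ensure_cache(model, Z)
  ## 1. cluster responsibilities
  cache$r <- softmax_rows(sweep(cache$F, 2L, dir_logmean(model$pi_conc), "+"))
  ## 2. source posteriors and component responsibilities
  for (k in seq_len(model$K)) {
    cl <- model$clusters[[k]]
    es <- e_step_cluster(cl, Z, cache$cl[[k]]$rho)
    es$rho <- rho_update(cl, es$M, es$Sigma)
    cache$cl[[k]] <- es
  }
  ## 3. global factors
  for (k in seq_len(model$K)) {
    es <- cache$cl[[k]]
    model$clusters[[k]] <- m_step_cluster(model$clusters[[k]], Z,
                                          cache$r[, k], es$M, es$Sigma,
                                          es$rho, model$priors)
  }
  ## 4. cluster proportions
  model$pi_conc <- model$priors$alpha0 + colSums(cache$r)
  ## 5. objective at the current parameters
  cache$F <- compute_F(model, Z, cache)
  elbo <- elbo_value(model, Z, cache)
  if (!is.finite(elbo)) stop("non-finite ELBO after sweep ",
                             length(model$elbo_trace) + 1L)
  model$cache <- cache
  model$elbo_trace <- c(model$elbo_trace, elbo)
  list(model = model, elbo = elbo)
}

#' Fit a variational Bayesian ICA mixture model
#'
#' Runs up to `config$n_iterations` coordinate-ascent sweeps, stopping
#' early once the relative ELBO change drops below
#' `config$convergence_tol`.  Deterministic given `config$seed`.
#'
#' @param Z Standardized data matrix (use [standardize()]).
#' @param config A [vim_config()].
#' @param model Optional warm start (a `vim_model`); when supplied the
#'   initialisation step is skipped.
#' @param init Passed to [init_model()].
#' @return A `vim_fit` list: `model`, `converged`, `n_sweeps`, `elbo`
#'   (final value, equal to the last trace entry), and `responsibilities`
#'   on the training data.
#' @export
fit_vbica_mm <- function(Z, config, model = NULL,
                         init = c("kmeans", "random")) {
  Z <- as.matrix(Z)
  if (is.null(model)) model <- init_model(Z, config, match.arg(init))
  model$cache <- ensure_cache(model, Z)
  prev <- elbo_value(model, Z, model$cache)
  n_sweeps <- 0L
  converged <- FALSE
  for (it in seq_len(config$n_iterations)) {
    sw <- vb_sweep(model, Z)
    model <- sw$model
    n_sweeps <- it
    if (is.finite(prev) &&
        abs(sw$elbo - prev) <= config$convergence_tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- sw$elbo
  }
  model <- finalize_projection_stats(model)
  structure(list(
    model = model, converged = converged, n_sweeps = n_sweeps,
    elbo = utils::tail(model$elbo_trace, 1L),
    responsibilities = model$cache$r
  ), class = "vim_fit")
}

## Per-cluster source-projection spread (posterior SD of each source's
## projections over the cluster's members, responsibility-weighted);
## feeds axis magnitudes and pattern scaling.
finalize_projection_stats <- function(model) {
  cache <- model$cache
  for (k in seq_len(model$K)) {
    es <- cache$cl[[k]]
    rk <- cache$r[, k]
    Nk <- max(sum(rk), .Machine$double.eps)
    m1 <- colSums(rk * es$M) / Nk
    m2 <- colSums(rk * es$M^2) / Nk + diag(es$Sigma)
    model$clusters[[k]]$src_sd <- sqrt(pmax(m2 - m1^2, .Machine$double.eps))
  }
  model
}

#' Posterior cluster membership probabilities
#'
#' Runs the held-out E-step (source posteriors and component
#' responsibilities iterated to a fixed point) under the fitted global
#' posterior and returns `softmax(E[log pi] + F)` per observation.
#'
#' @param model A fitted `vim_model` (or a `vim_fit`).
#' @param Z_new Matrix in the model's standardized space.
#' @param n_inner E-step refinement passes (default 10).
#' @return N x K matrix; rows sum to 1.
#' @export
responsibilities <- function(model, Z_new, n_inner = 10L) {
  if (inherits(model, "vim_fit")) model <- model$model
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != model$D)
    stop("Z_new has ", ncol(Z_new), " columns; model expects ", model$D)
  n <- nrow(Z_new)
  cache <- list(cl = vector("list", model$K))
  for (k in seq_len(model$K)) {
    cl <- model$clusters[[k]]
    L <- ncol(cl$A_mean); m <- ncol(cl$eta_mean)
    rho <- rep(list(matrix(1 / m, n, m)), L)
    es <- NULL
    for (i in seq_len(max(1L, n_inner))) {
      es <- e_step_cluster(cl, Z_new, rho)
      rho <- rho_update(cl, es$M, es$Sigma)
    }
    es$rho <- rho
    cache$cl[[k]] <- es
  }
  Fm <- compute_F(model, Z_new, cache)
  softmax_rows(sweep(Fm, 2L, dir_logmean(model$pi_conc), "+"))
}

#' Hard cluster assignment
#'
#' Argmax of the responsibilities; ties broken toward the lowest cluster
#' index.
#'
#' @param resp N x K responsibility matrix.
#' @return Integer vector of cluster indices.
#' @export
assign_clusters <- function(resp) max.col(resp, ties.method = "first")

#' Axis magnitudes of one cluster
#'
#' The magnitude of axis `l` is the Euclidean norm of the posterior-mean
#' mixing column times the posterior SD of source `l`'s projections over
#' the cluster's members -- the effective data-space spread the axis
#' carries.  Shrunk (irrelevant) axes get magnitudes near zero.
#'
#' @param model Fitted `vim_model` (or `vim_fit`).
#' @param cluster_index Cluster to inspect.
#' @return data.frame with columns `axis` (original index) and
#'   `magnitude`, sorted by decreasing magnitude.
#' @export
axis_magnitudes <- function(model, cluster_index) {
  if (inherits(model, "vim_fit")) model <- model$model
  if (cluster_index < 1 || cluster_index > model$K)
    stop("invalid cluster index")
  cl <- model$clusters[[cluster_index]]
  if (anyNA(cl$src_sd))
    stop("projection stats missing; fit the model before ranking axes")
  mag <- sqrt(colSums(cl$A_mean^2)) * cl$src_sd
  out <- data.frame(axis = seq_along(mag), magnitude = mag)
  out[order(-out$magnitude), , drop = FALSE]
}
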