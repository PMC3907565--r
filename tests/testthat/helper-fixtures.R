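## Shared fixtures, built in code and memoised for the test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

## minimal hand-built cohort records (values independent of the generator)
make_records <- function(n, label = "normal", eye = "right",
                         base = 28, age = 50) {
  th <- matrix(base, n, 52)
  colnames(th) <- sprintf("p%02d", 1:52)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), eye = eye, th,
    age = age, fp_rate = 0.01, fl_rate = 0.02, fn_rate = 0.01,
    fdt_label = label, stringsAsFactors = FALSE
  )
}

## single-cluster bimodal-source ICA ground truth
one_cluster_truth <- function(D, L, A_scale = 2, noise_sd = 0.3,
                              seed = 99) {
  set.seed(seed)
  A <- matrix(stats::rnorm(D * L), D, L) * A_scale
  ica_mixture_truth(
    weights = 1,
    clusters = list(list(
      mean = rep(0, D), A = A,
      sources = rep(list(list(weights = c(0.5, 0.5), means = c(-1.2, 1.2),
                              sds = c(0.4, 0.4))), L),
      noise_sd = noise_sd)))
}

## K well-separated bimodal-source ICA clusters
separated_truth <- function(K = 3, D = 10, L = 2, sep = 8, seed = 31,
                            A_scale = 0.6) {
  set.seed(seed)
  ## cluster means in generic directions so that standardization cannot
  ## compress the separation onto a handful of coordinates
  mus <- matrix(stats::rnorm(K * D), K, D)
  mus <- sep * mus / sqrt(rowSums(mus^2))
  clusters <- lapply(seq_len(K), function(k) {
    mu <- mus[k, ]
    list(mean = mu, A = A_scale * matrix(stats::rnorm(D * L), D, L),
         sources = rep(list(list(weights = c(0.5, 0.5), means = c(-1, 1),
                                 sds = c(0.4, 0.4))), L),
         noise_sd = 0.3)
  })
  ica_mixture_truth(weights = rep(1 / K, K), clusters = clusters)
}

## small synthetic FDT cohort + fitted 3-cluster model, reused by the
## axis, pattern and serialization tests
get_small_fit <- function() {
  memo("small_fit", {
    co <- generate_study_cohort(400, 260, seed = 101)
    cfg <- vim_config(K = 3, L_max = 8, m = 3, n_iterations = 80, seed = 17)
    fit <- fit_vim(co, cfg)
    Z <- standardize(cohort_matrix(co))$Z
    labels <- co$records$fdt_label
    cs <- confusion(assign_clusters(fit$responsibilities), labels)
    list(cohort = co, fit = fit, Z = Z, labels = labels, cs = cs)
  })
}

## pruned + retrained version with oriented axes
get_small_axes <- function() {
  memo("small_axes", {
    sf <- get_small_fit()
    retained <- vapply(1:3, function(k)
      knee_point(axis_magnitudes(sf$fit, k)$magnitude), integer(1))
    fit2 <- prune_and_retrain(sf$fit, retained, sf$Z, n_iterations = 40)
    cs2 <- confusion(assign_clusters(fit2$responsibilities), sf$labels)
    ncl <- which(cs2$cluster_labels == "normal")[1]
    axes <- orient_axes(fit2$model, ncl, sf$Z, sf$labels)
    list(fit = fit2, axes = axes, ncl = ncl, cs = cs2,
         Z = sf$Z, labels = sf$labels, cohort = sf$cohort)
  })
}

## single-cluster fit with surplus axes (true L = 2, fitted L_max = 10),
## shared by the ARD/knee tests and the recovery acceptance checks
get_ard_fit <- function() {
  memo("ard_fit", {
    truth <- one_cluster_truth(D = 12, L = 2, A_scale = 2, noise_sd = 0.3)
    sam <- sample_ica_mixture(truth, 1200, seed = 14)
    std <- standardize(sam$X)
    fit <- fit_vbica_mm(std$Z, vim_config(K = 1, L_max = 10, m = 3,
                                          n_iterations = 250, seed = 9))
    list(truth = truth, sam = sam, std = std, fit = fit)
  })
}

elbo_monotone <- function(trace, tol = 1e-6) {
  if (length(trace) < 2) return(TRUE)
  prev <- trace[-length(trace)]
  all(diff(trace) >= -tol * abs(prev))
}
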