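## Versioned, human-readable model serialization.  Every numeric is
## written as a 17-significant-digit decimal string, which round-trips
## IEEE doubles exactly, so a reloaded model is bit-identical to the
## saved one.  Per-observation caches (responsibilities, source
## posteriors) are data-sized and deliberately not serialized; they are
## rebuilt on demand from the data.

pack_num <- function(x) {
  if (is.null(x)) return(NULL)
  list(dim = dim(x), v = sprintf("%.17g", as.numeric(x)))
}

unpack_num <- function(p) {
  if (is.null(p)) return(NULL)
  v <- as.numeric(p$v)
  if (!is.null(p$dim) && length(p$dim)) array(v, dim = unlist(p$dim)) else v
}

CLUSTER_NUM_FIELDS <- c("mu_mean", "mu_var", "A_mean", "VarA",
                        "alpha_a", "alpha_b", "psi_a", "psi_b",
                        "beta_a", "beta_b", "w_conc",
                        "eta_mean", "eta_var", "src_sd")
AUX_NUM_FIELDS <- c("Ubig", "lam", "psi_used", "entropy")

#' Serialize a fitted mixture model to JSON
#'
#' Writes all posterior parameters, the standardization, the
#' configuration and the ELBO trace in a structured text format that
#' reloads bit-exactly via [read_vim_model()].
#'
#' @param model A `vim_model` (or `vim_fit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vim_model <- function(model, path) {
  if (inherits(model, "vim_fit")) model <- model$model
  cfg <- model$config
  doc <- list(
    format = "perimix-vim", version = 1L,
    config = list(K = cfg$K, L_max = cfg$L_max, m = cfg$m,
                  n_iterations = cfg$n_iterations,
                  convergence_tol = pack_num(cfg$convergence_tol),
                  seed = cfg$seed,
                  priors = lapply(cfg$priors, pack_num)),
    K = model$K, D = model$D,
    pi_conc = pack_num(model$pi_conc),
    standardization = if (is.null(model$standardization)) NULL else
      lapply(model$standardization, pack_num),
    elbo_trace = pack_num(model$elbo_trace),
    clusters = lapply(model$clusters, function(cl) {
      out <- lapply(cl[CLUSTER_NUM_FIELDS], pack_num)
      out$A_aux <- lapply(cl$A_aux[AUX_NUM_FIELDS], pack_num)
      out
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' Reload a serialized mixture model
#' @param path Path written by [write_vim_model()].
#' @return A `vim_model` (without per-observation caches; they are
#'   rebuilt automatically when the model is used).
#' @export
read_vim_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "perimix-vim"))
    stop("not a serialized perimix model: ", path)
  cfg <- vim_config(
    K = doc$config$K, L_max = doc$config$L_max, m = doc$config$m,
    n_iterations = doc$config$n_iterations,
    convergence_tol = unpack_num(doc$config$convergence_tol),
    seed = doc$config$seed,
    priors = lapply(doc$config$priors, unpack_num))
  clusters <- lapply(doc$clusters, function(cl) {
    out <- lapply(cl[CLUSTER_NUM_FIELDS], unpack_num)
    out$A_aux <- lapply(cl$A_aux, unpack_num)
    out
  })
  structure(list(
    config = cfg, priors = cfg$priors, K = doc$K, D = doc$D,
    pi_conc = unpack_num(doc$pi_conc),
    clusters = clusters,
    standardization = if (is.null(doc$standardization)) NULL else
      lapply(doc$standardization, unpack_num),
    elbo_trace = if (is.null(doc$elbo_trace)) numeric(0) else
      unpack_num(doc$elbo_trace),
    cache = NULL
  ), class = "vim_model")
}
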