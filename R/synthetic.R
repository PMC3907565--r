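## Synthetic FDT cohort generator.
##
## Emulates the statistical structure the mixture analysis assumes: a
## smooth normal hill of vision with between-subject and per-point noise,
## an age structure that differs between labelled-normal and
## labelled-abnormal eyes, and archetypal glaucomatous defects applied
## with graded severity.  Also provides a generic mixture-of-ICA sampler
## used as a ground-truth oracle in recovery tests.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Glaucomatous defect archetypes on the 24-2 layout
#'
#' Region-wise loss templates, one 52-vector per archetype, expressed as
#' dB of loss per unit severity (entries are non-positive).  Each template
#' is normalised so its mean over the 52 points is -1 dB, making one unit
#' of severity one dB of mean deviation before threshold clipping.
#' Altitudinal templates load one hemifield; nasal-step templates load one
#' nasal quadrant; `arrowhead` is the union of the two nasal steps;
#' `diffuse` is uniform loss and `diffuse_superior` is diffuse loss
#' weighted toward the superior hemifield.
#'
#' @param layout Layout from [layout_242()].
#' @return Named list of numeric 52-vectors.
#' @export
defect_archetypes <- function(layout = layout_242()) {
  m <- region_masks_242(layout)
  unitize <- function(v) v / abs(mean(v))
  tpl <- list(
    superior_altitudinal = unitize(-1 * m$superior),
    inferior_altitudinal = unitize(-1 * m$inferior),
    superior_nasal       = unitize(-1 * m$superior_nasal),
    inferior_nasal       = unitize(-1 * m$inferior_nasal),
    arrowhead            = unitize(-1 * (m$superior_nasal | m$inferior_nasal)),
    diffuse              = unitize(rep(-1, nrow(layout))),
    diffuse_superior     = unitize(-(1.5 * m$superior + 0.5 * m$inferior))
  )
  lapply(tpl, function(v) { stopifnot(all(v <= 0), any(v < 0)); v })
}

#' Default parameters of the synthetic FDT generator
#'
#' The defaults encode the study conditions the generator emulates:
#' labelled-normal eyes with mean deviation (MD) averaging -1.00 dB
#' (SD 2.80 dB) and ages 50.0 (14.7) years; labelled-abnormal eyes with
#' MD averaging -5.57 dB (SD 5.09 dB) and ages 55.9 (15.3) years.
#'
#' * `normal_mean_surface`: normative hill of vision, ~30.5 dB centrally
#'   with a gentle radial decline; the MD reference surface.
#' * `subject_md_mean`, `subject_sd`: between-subject global offset,
#'   N(-1.00, 2.769^2) dB, so normal-arm MD averages -1.00 dB with SD
#'   2.80 dB once per-point noise is included.
#' * `point_noise_sd`: iid per-point measurement noise, 3.0 dB.
#' * `archetype_weights`: mixture over [defect_archetypes()], weighted
#'   toward altitudinal defects.
#' * `severity_shape`, `severity_means`: per-archetype gamma severity
#'   (shape 1.5; means in dB of MD loss per the template normalisation),
#'   right-skewed because instrument-flagged abnormal fields rarely carry
#'   near-zero defects.
#' * `severity_scale`: single calibration factor (from
#'   `tools/calibrate_generator.R`, fixed seed) compensating the MD lost
#'   to clipping thresholds at 0 dB so the abnormal arm hits its MD
#'   target.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `fdt_generator_params`.
#' @export
generator_params <- function(...) {
  layout <- layout_242()
  ecc <- sqrt(layout$x_deg^2 + layout$y_deg^2)
  p <- list(
    layout = layout,
    normal_mean_surface = 31 - 0.08 * ecc,
    subject_md_mean = -1.00,
    subject_sd = sqrt(2.80^2 - 3.0^2 / 52),
    point_noise_sd = 3.0,
    age_normal = c(mean = 50.0, sd = 14.7),
    age_abnormal = c(mean = 55.9, sd = 15.3),
    age_range = c(18, 95),
    archetype_weights = c(
      superior_altitudinal = 0.30, inferior_altitudinal = 0.28,
      superior_nasal = 0.08, inferior_nasal = 0.08,
      arrowhead = 0.10, diffuse = 0.10, diffuse_superior = 0.06),
    severity_shape = 1.5,
    severity_means = c(
      superior_altitudinal = 4.4, inferior_altitudinal = 4.4,
      superior_nasal = 2.2, inferior_nasal = 2.2,
      arrowhead = 5.5, diffuse = 7.5, diffuse_superior = 6.0),
    severity_scale = 1.031,
    reliability_beta = list(fp = c(1, 10.54), fl = c(1, 5.0), fn = c(1, 19.5)),
    seed = 101
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown generator parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$subject_sd > 0, p$point_noise_sd >= 0,
            abs(sum(p$archetype_weights) - 1) < 1e-8,
            all(p$severity_means >= 0), p$severity_shape > 0)
  class(p) <- "fdt_generator_params"
  p
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_reliability <- function(n, params) {
  b <- params$reliability_beta
  data.frame(
    fp_rate = 0.33 * stats::rbeta(n, b$fp[1], b$fp[2]),
    fl_rate = 0.33 * stats::rbeta(n, b$fl[1], b$fl[2]),
    fn_rate = 0.33 * stats::rbeta(n, b$fn[1], b$fn[2])
  )
}

build_records <- function(th, age, rel, label, prefix, archetype = NA_character_,
                          severity = NA_real_) {
  n <- nrow(th)
  colnames(th) <- threshold_cols()
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    eye = sample(c("right", "left"), n, replace = TRUE),
    th,
    age = age,
    rel,
    fdt_label = label,
    archetype = archetype,
    severity = severity,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic FDT-normal fields
#'
#' Each field is `normal_mean_surface + subject offset + per-point noise`,
#' clipped at 0 dB; ages are truncated-normal; reliability indices are
#' drawn below the 33% cut-off; all records are labelled `"normal"`.
#' Deterministic given `seed`.
#'
#' @param n Number of fields (>= 1).
#' @param params [generator_params()].
#' @param seed RNG seed; defaults to `params$seed`.
#' @return An `fdt_cohort`.
#' @export
generate_normal_fields <- function(n, params = generator_params(),
                                   seed = params$seed) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    offset <- stats::rnorm(n, params$subject_md_mean, params$subject_sd)
    noise <- matrix(stats::rnorm(n * 52, 0, params$point_noise_sd), n, 52)
    th <- pmax(outer(rep(1, n), params$normal_mean_surface) + offset + noise, 0)
    age <- rtrunc_norm(n, params$age_normal["mean"], params$age_normal["sd"],
                       params$age_range[1], params$age_range[2])
    rec <- build_records(th, age, draw_reliability(n, params), "normal", "N")
    fdt_cohort(rec, provenance = "synthetic", layout = params$layout)
  })
}

#' Generate synthetic FDT-abnormal (glaucomatous) fields
#'
#' Starts from the normal-field model and subtracts `severity x template`
#' for an archetype drawn from `archetype_weights`, with severity drawn
#' from the per-archetype gamma distribution scaled by `severity_scale`.
#' The generating archetype and severity are recorded per field as ground
#' truth.  All records are labelled `"abnormal"`.
#'
#' @inheritParams generate_normal_fields
#' @return An `fdt_cohort` with `archetype` and `severity` columns.
#' @export
generate_glaucoma_fields <- function(n, params = generator_params(),
                                     seed = params$seed) {
  if (n < 1) stop("n must be >= 1")
  tpl <- defect_archetypes(params$layout)
  stopifnot(setequal(names(tpl), names(params$archetype_weights)))
  with_seed(seed, {
    arch <- sample(names(params$archetype_weights), n, replace = TRUE,
                   prob = params$archetype_weights)
    sev <- stats::rgamma(
      n, shape = params$severity_shape,
      scale = params$severity_scale *
        params$severity_means[arch] / params$severity_shape)
    offset <- stats::rnorm(n, params$subject_md_mean, params$subject_sd)
    noise <- matrix(stats::rnorm(n * 52, 0, params$point_noise_sd), n, 52)
    loss <- t(vapply(seq_len(n), function(i) sev[i] * tpl[[arch[i]]],
                     numeric(52)))
    th <- pmax(outer(rep(1, n), params$normal_mean_surface) +
                 offset + loss + noise, 0)
    age <- rtrunc_norm(n, params$age_abnormal["mean"], params$age_abnormal["sd"],
                       params$age_range[1], params$age_range[2])
    rec <- build_records(th, age, draw_reliability(n, params), "abnormal", "G",
                         archetype = arch, severity = sev)
    fdt_cohort(rec, provenance = "synthetic", layout = params$layout)
  })
}

#' Generate a full synthetic study cohort
#'
#' Concatenates the normal and abnormal generators (default counts: 1,190
#' normal + 786 abnormal = 1,976 fields) and shuffles record order.
#'
#' @param n_normal,n_abnormal Arm sizes; either may be 0.
#' @param params [generator_params()].
#' @param seed Master seed; arm seeds are derived from it.
#' @return An `fdt_cohort`.
#' @export
generate_study_cohort <- function(n_normal = 1190, n_abnormal = 786,
                                  params = generator_params(),
                                  seed = params$seed) {
  if (n_normal + n_abnormal < 1) stop("cohort must contain at least 1 record")
  parts <- list()
  if (n_normal > 0)
    parts$normal <- generate_normal_fields(n_normal, params,
                                           seed = derive_seed(seed, 1))
  if (n_abnormal > 0)
    parts$abnormal <- generate_glaucoma_fields(n_abnormal, params,
                                               seed = derive_seed(seed, 2))
  rec <- do.call(rbind, lapply(parts, function(co) {
    r <- co$records
    if (is.null(r$archetype)) { r$archetype <- NA_character_; r$severity <- NA_real_ }
    r
  }))
  rownames(rec) <- NULL
  rec <- with_seed(derive_seed(seed, 3),
                   rec[sample.int(nrow(rec)), , drop = FALSE])
  rownames(rec) <- NULL
  fdt_cohort(rec, provenance = "synthetic", layout = params$layout)
}

## deterministic small-integer seed derivation (kept below 2^31)
derive_seed <- function(master, ...) {
  ks <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in ks) h <- (h * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  as.integer(h)
}

#' Ground truth for a mixture of ICA models
#'
#' Constructor and validator for the sampler's ground truth: `K` clusters,
#' each with a mean, a full-column-rank D x L mixing matrix, per-source
#' Gaussian-mixture distributions and diagonal noise SDs.
#'
#' @param weights Cluster mixing weights (sum to 1).
#' @param clusters List of `K` lists with elements `mean` (D), `A` (D x L),
#'   `sources` (list of `L` lists with `weights`, `means`, `sds`), and
#'   `noise_sd` (scalar or D-vector).
#' @return Object of class `ica_mixture_truth`.
#' @export
ica_mixture_truth <- function(weights, clusters) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(weights) == length(clusters))
  for (cl in clusters) {
    A <- cl$A
    stopifnot(is.matrix(A), length(cl$mean) == nrow(A),
              length(cl$sources) == ncol(A))
    if (qr(A)$rank < ncol(A)) stop("mixing matrix is rank deficient")
    for (s in cl$sources)
      stopifnot(abs(sum(s$weights) - 1) < 1e-8,
                length(s$means) == length(s$weights),
                all(s$sds > 0))
  }
  structure(list(weights = weights, clusters = clusters),
            class = "ica_mixture_truth")
}

#' Sample from a mixture of ICA models
#'
#' Draws a cluster per observation from the mixture weights, sources from
#' each cluster's Gaussian-mixture source distributions, and observations
#' as `mean + A sources + noise`.  Returns everything a recovery test
#' needs to score an estimate against the truth.
#'
#' @param truth An [ica_mixture_truth()].
#' @param n Number of observations.
#' @param seed RNG seed.
#' @return List with `X` (n x D), `cluster` (integer n), and `sources`
#'   (n x max(L); columns beyond a cluster's own L are zero).
#' @export
sample_ica_mixture <- function(truth, n, seed = 1L) {
  K <- length(truth$weights)
  D <- length(truth$clusters[[1]]$mean)
  Lmax <- max(vapply(truth$clusters, function(cl) ncol(cl$A), integer(1)))
  with_seed(seed, {
    z <- sample.int(K, n, replace = TRUE, prob = truth$weights)
    X <- matrix(0, n, D)
    S <- matrix(0, n, Lmax)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (!length(idx)) next
      cl <- truth$clusters[[k]]
      L <- ncol(cl$A)
      s <- vapply(cl$sources, function(sp) {
        j <- sample.int(length(sp$weights), length(idx), replace = TRUE,
                        prob = sp$weights)
        stats::rnorm(length(idx), sp$means[j], sp$sds[j])
      }, numeric(length(idx)))
      s <- matrix(s, nrow = length(idx), ncol = L)
      nsd <- rep(cl$noise_sd, length.out = D)
      eps <- matrix(stats::rnorm(length(idx) * D), length(idx), D) *
        rep(nsd, each = length(idx))
      X[idx, ] <- rep(cl$mean, each = length(idx)) + s %*% t(cl$A) + eps
      S[idx, seq_len(L)] <- s
    }
    list(X = X, cluster = z, sources = S)
  })
}
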