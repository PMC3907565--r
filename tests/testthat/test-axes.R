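test_that("knee detection matches worked examples and handles boundaries", {
  expect_equal(knee_point(c(10, 9, 1, 0.5, 0.2)), 2L)
  expect_equal(knee_point(c(10, 8, 6, 5.5, 1, 0.4)), 4L)
  expect_equal(knee_point(5), 1L)
  expect_warning(k <- knee_point(c(3, 3, 3, 3)), "all-equal")
  expect_equal(k, 4L)
  expect_warning(k2 <- knee_point(c(4, 1)), "at least 3")
  expect_equal(k2, 2L)
  expect_equal(knee_point(c(10, 9, 1, 0.5, 0.2), override = 4), 4L)
  expect_error(knee_point(c(1, 5, 2)), "decreasing")
  expect_error(knee_point(numeric(0)), "empty")
})

test_that("knee detection agrees with an exhaustive second-difference search", {
  set.seed(20)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    mags <- sort(rgamma(n, 2, 0.5), decreasing = TRUE)
    ## independent oracle: brute-force loop over interior positions
    best <- NA; bestval <- -Inf
    for (i in 2:(n - 1)) {
      d2 <- mags[i - 1] - 2 * mags[i] + mags[i + 1]
      if (d2 > bestval) { bestval <- d2; best <- i - 1 }
    }
    expect_equal(knee_point(mags), best)
  }
})

test_that("pruning drops the weakest axes, retrains monotonically, and keeps counts", {
  sa <- get_small_axes()
  counts <- vapply(sa$fit$model$clusters,
                   function(cl) ncol(cl$A_mean), integer(1))
  retained <- vapply(1:3, function(k)
    knee_point(axis_magnitudes(get_small_fit()$fit, k)$magnitude),
    integer(1))
  expect_identical(counts, retained)
  expect_true(elbo_monotone(sa$fit$model$elbo_trace))
  ## no-op pruning continues training without losing ELBO
  fit0 <- get_small_fit()$fit
  same <- vapply(fit0$model$clusters, function(cl) ncol(cl$A_mean),
                 integer(1))
  fit_noop <- prune_and_retrain(fit0, same, get_small_fit()$Z,
                                n_iterations = 5)
  expect_identical(vapply(fit_noop$model$clusters,
                          function(cl) ncol(cl$A_mean), integer(1)), same)
  expect_true(elbo_monotone(fit_noop$model$elbo_trace))
  expect_gte(tail(fit_noop$model$elbo_trace, 1), fit0$elbo - 1e-6 * abs(fit0$elbo))
  expect_error(prune_and_retrain(fit0, c(0, 2, 2), get_small_fit()$Z),
               ">= 1")
})

test_that("surplus axes are pruned back to the generating pair with accurate mixing", {
  af <- get_ard_fit()
  truth <- af$truth; std <- af$std; fit <- af$fit
  mag <- axis_magnitudes(fit, 1)
  ## ARD: surplus axes carry under 10% of total magnitude
  expect_lt(sum(mag$magnitude[-(1:2)]) / sum(mag$magnitude), 0.10)
  k <- knee_point(mag$magnitude)
  expect_equal(k, 2L)
  fit2 <- prune_and_retrain(fit, k, std$Z, n_iterations = 30)
  A_true_std <- truth$clusters[[1]]$A / std$scale
  expect_lt(amari_distance(A_true_std, fit2$model$clusters[[1]]$A_mean),
            0.15)
})

test_that("axis orientation enforces the severity convention and is sign-idempotent", {
  sa <- get_small_axes()
  model <- sa$fit$model
  ## flipping a stored mixing column must not change the oriented output
  flipped <- model
  gcl <- which(sa$cs$cluster_labels == "glaucoma")[1]
  flipped$clusters[[gcl]]$A_mean[, 1] <- -flipped$clusters[[gcl]]$A_mean[, 1]
  ax1 <- orient_axes(model, sa$ncl, sa$Z, sa$labels)
  ax2 <- orient_axes(flipped, sa$ncl, sa$Z, sa$labels)
  pick <- function(axes) Filter(function(a)
    a$cluster == gcl && a$axis == 1, axes)[[1]]
  expect_equal(pick(ax1)$direction, pick(ax2)$direction, tolerance = 1e-12)
  ## oriented positive direction decreases total field sensitivity for
  ## glaucoma-cluster axes (loss patterns)
  scl <- model$standardization$scale[1:52]
  for (a in Filter(function(a) sa$cs$cluster_labels[a$cluster] == "glaucoma",
                   ax1))
    expect_lt(sum(a$direction[1:52] * scl), 0)
  for (a in ax1) {
    expect_equal(sqrt(sum(a$direction^2)), 1, tolerance = 1e-10)
    expect_gt(a$projection_sd, 0)
  }
})

test_that("ground-truth severity increases along matched glaucoma axes", {
  sa <- get_small_axes()
  rec <- sa$cohort$records
  resp <- responsibilities(sa$fit$model, sa$Z)
  asg <- assign_clusters(resp)
  gcl <- which(sa$cs$cluster_labels == "glaucoma")
  tpls <- defect_archetypes()
  scl <- sa$fit$model$standardization$scale[1:52]
  ## for each glaucoma cluster, take its most common generating
  ## archetype, find the axis best matched to that template, and check
  ## severity ordering along it
  cors <- c()
  for (k in gcl) {
    memb_all <- which(asg == k & rec$fdt_label == "abnormal")
    if (length(memb_all) < 40) next
    arch <- names(which.max(table(rec$archetype[memb_all])))
    memb <- memb_all[rec$archetype[memb_all] == arch]
    ax <- Filter(function(a) a$cluster == k, sa$axes)
    mags <- vapply(ax, `[[`, numeric(1), "magnitude")
    ax <- ax[mags > 0.2 * max(mags)]
    cosims <- vapply(ax, function(a) {
      eff <- a$direction[1:52] * scl
      abs(sum(eff * tpls[[arch]])) /
        sqrt(sum(eff^2) * sum(tpls[[arch]]^2))
    }, numeric(1))
    a1 <- ax[[which.max(cosims)]]
    proj <- as.numeric(
      sweep(sa$Z[memb, , drop = FALSE], 2,
            sa$fit$model$clusters[[k]]$mu_mean) %*% a1$direction)
    cors <- c(cors, cor(rec$severity[memb], proj, method = "spearman"))
  }
  expect_gt(length(cors), 0)
  expect_gt(max(cors), 0.6)
})

test_that("nearest-axis assignment follows absolute cosine similarity", {
  sa <- get_small_axes()
  model <- sa$fit$model
  gcl <- which(vapply(model$clusters, function(cl) ncol(cl$A_mean),
                      integer(1)) >= 2)[1]
  skip_if(is.na(gcl), "no multi-axis cluster in fixture")
  axes_g <- Filter(function(a) a$cluster == gcl, sa$axes)
  ## synthetic members exactly along each axis direction
  mu <- model$clusters[[gcl]]$mu_mean
  Zsyn <- do.call(rbind, lapply(axes_g, function(a)
    rbind(mu + 3 * a$direction, mu - 1.7 * a$direction)))
  ## force these points into the cluster by construction: they sit at the
  ## cluster mean plus a pure axis displacement
  asg <- assign_to_nearest_axis(model, rbind(sa$Z, Zsyn), gcl, sa$axes)
  syn_rows <- nrow(sa$Z) + seq_len(nrow(Zsyn))
  got <- asg$axis[match(syn_rows, asg$record)]
  want <- rep(vapply(axes_g, `[[`, numeric(1), "axis"), each = 2)
  keep <- !is.na(got)   # only rows actually claimed by the cluster
  expect_gt(mean(got[keep] == want[keep]), 0.9)
  ## scaling invariance on the real members
  base <- assign_to_nearest_axis(model, sa$Z, gcl, sa$axes)
  Zscaled <- sa$Z
  memb <- base$record
  Zscaled[memb, ] <- sweep(
    sweep(sa$Z[memb, , drop = FALSE], 2, mu), 1, 2.5, "*") +
    matrix(mu, length(memb), length(mu), byrow = TRUE)
  again <- assign_to_nearest_axis(model, Zscaled, gcl, sa$axes)
  common <- intersect(base$record, again$record)
  expect_gt(mean(base$axis[match(common, base$record)] ==
                 again$axis[match(common, again$record)]), 0.95)
})
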