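test_that("the zero pattern is exactly zero and anchored at the normal mean", {
  sa <- get_small_axes()
  ax <- Filter(function(a) a$cluster != sa$ncl, sa$axes)[[1]]
  pg0 <- generate_axis_pattern(sa$fit$model, ax, 0)
  expect_equal(pg0$deviations, rep(0, 52))
  mu_age <- destandardize(sa$fit$model$clusters[[sa$ncl]]$mu_mean,
                          sa$fit$model$standardization)[1, 53]
  expect_equal(pg0$age, unname(mu_age))
})

test_that("patterns are affine in k and symmetric about the centroid", {
  sa <- get_small_axes()
  ax <- Filter(function(a) a$cluster != sa$ncl, sa$axes)[[1]]
  p0 <- generate_axis_pattern(sa$fit$model, ax, 0)
  p1 <- generate_axis_pattern(sa$fit$model, ax, 1)
  for (k in c(-2, -0.5, 2, 3)) {
    pk <- generate_axis_pattern(sa$fit$model, ax, k)
    expect_equal(pk$deviations - p0$deviations,
                 k * (p1$deviations - p0$deviations), tolerance = 1e-10)
  }
  pp <- generate_axis_pattern(sa$fit$model, ax, 2)
  pm <- generate_axis_pattern(sa$fit$model, ax, -2)
  expect_equal(pp$deviations, -pm$deviations, tolerance = 1e-10)
})

test_that("severity scores a pattern back to its own k", {
  sa <- get_small_axes()
  for (ax in sa$axes[c(1, length(sa$axes))]) {
    for (k in c(-3, -2, 0, 2, 3)) {
      pg <- generate_axis_pattern(sa$fit$model, ax, k)
      expect_equal(severity(pg, ax, sa$fit$model), k, tolerance = 1e-8)
    }
  }
  unor <- sa$axes[[1]]
  unor$oriented <- FALSE
  expect_error(generate_axis_pattern(sa$fit$model, unor, 2), "oriented")
  expect_error(severity(rep(0, 10), sa$axes[[1]], sa$fit$model), "length")
})

test_that("a single-archetype glaucoma cluster yields a matching, severity-ordered axis", {
  w <- c(superior_altitudinal = 1, inferior_altitudinal = 0,
         superior_nasal = 0, inferior_nasal = 0, arrowhead = 0,
         diffuse = 0, diffuse_superior = 0)
  p <- generator_params(archetype_weights = w)
  co <- generate_study_cohort(300, 300, params = p, seed = 88)
  cfg <- vim_config(K = 2, L_max = 6, m = 3, n_iterations = 80, seed = 3)
  fit <- fit_vim(co, cfg)
  labels <- co$records$fdt_label
  Z <- standardize(cohort_matrix(co))$Z
  cs <- confusion(assign_clusters(fit$responsibilities), labels)
  ncl <- which(cs$cluster_labels == "normal")[1]
  gcl <- which(cs$cluster_labels == "glaucoma")[1]
  skip_if(is.na(ncl) || is.na(gcl), "fixture failed to separate")
  axes <- orient_axes(fit$model, ncl, Z, labels)
  gx <- Filter(function(a) a$cluster == gcl, axes)
  ## matched-archetype axis: among non-degenerate axes, the one whose dB
  ## effect direction is most parallel to the generating template
  mags <- vapply(gx, `[[`, numeric(1), "magnitude")
  gx <- gx[mags > 0.2 * max(mags)]
  tpl <- defect_archetypes()$superior_altitudinal
  scl <- fit$model$standardization$scale[1:52]
  cosims <- vapply(gx, function(a) {
    eff <- a$direction[1:52] * scl
    abs(sum(eff * tpl)) / sqrt(sum(eff^2) * sum(tpl^2))
  }, numeric(1))
  a1 <- gx[[which.max(cosims)]]
  expect_gt(max(cosims), 0.9)
  ## the +2 SD pattern depresses the superior hemifield more than the
  ## inferior one, matching the generating archetype
  pg <- generate_axis_pattern(fit$model, a1, 2)
  masks <- region_masks_242()
  expect_lt(mean(pg$deviations[masks$superior]),
            mean(pg$deviations[masks$inferior]))
  ## severity along the axis tracks ground-truth severity
  memb <- which(assign_clusters(responsibilities(fit$model, Z)) == gcl &
                  labels == "abnormal")
  sev_hat <- vapply(memb, function(i)
    severity(cohort_matrix(co)[i, ], a1, fit$model), numeric(1))
  expect_gt(cor(co$records$severity[memb], sev_hat, method = "spearman"),
            0.8)
})

test_that("rendering writes a deterministic, non-empty image", {
  sa <- get_small_axes()
  ax <- sa$axes[[1]]
  pg <- generate_axis_pattern(sa$fit$model, ax, 2)
  path <- withr::local_tempfile(fileext = ".png")
  render_pattern(pg, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
  ## zero grid renders too
  p0 <- generate_axis_pattern(sa$fit$model, ax, 0)
  path0 <- withr::local_tempfile(fileext = ".png")
  render_pattern(p0, path0)
  expect_true(file.exists(path0))
})
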