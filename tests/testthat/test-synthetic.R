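test_that("generators are deterministic given a seed and respect field invariants", {
  a <- generate_normal_fields(30, seed = 5)
  b <- generate_normal_fields(30, seed = 5)
  expect_identical(a$records, b$records)
  g1 <- generate_glaucoma_fields(30, seed = 5)
  g2 <- generate_glaucoma_fields(30, seed = 5)
  expect_identical(g1$records, g2$records)
  expect_false(identical(a$records,
                         generate_normal_fields(30, seed = 6)$records))
  th <- cohort_thresholds(g1)
  expect_true(all(th >= 0))
  r <- g1$records
  expect_true(all(r$fp_rate <= 0.33 & r$fl_rate <= 0.33 & r$fn_rate <= 0.33))
  expect_true(all(r$age >= 18 & r$age <= 95))
  expect_error(generate_normal_fields(0), ">= 1")
})

test_that("the noiseless limit reproduces the mean surface exactly", {
  p <- generator_params(subject_sd = 1e-12, point_noise_sd = 1e-12,
                        subject_md_mean = 0)
  co <- generate_normal_fields(5, p, seed = 3)
  th <- cohort_thresholds(co)
  for (i in 1:5)
    expect_equal(unname(th[i, ]), p$normal_mean_surface, tolerance = 1e-9)
})

test_that("zero-severity glaucoma fields match the normal-arm calibration", {
  p <- generator_params(severity_scale = 1e-9)
  co <- generate_glaucoma_fields(800, p, seed = 11)
  md <- cohort_md(co, p$normal_mean_surface)
  se <- sd(md) / sqrt(length(md))
  expect_lt(abs(mean(md) - (-1.00)), 3 * se)
})

test_that("raising severity never raises any threshold in the template support", {
  p1 <- generator_params(severity_scale = 1.0)
  p2 <- generator_params(severity_scale = 2.0)
  t1 <- cohort_thresholds(generate_glaucoma_fields(200, p1, seed = 21))
  t2 <- cohort_thresholds(generate_glaucoma_fields(200, p2, seed = 21))
  expect_true(all(t2 <= t1 + 1e-9))
})

test_that("altitudinal archetypes depress the matching hemifield", {
  w <- c(superior_altitudinal = 1, inferior_altitudinal = 0,
         superior_nasal = 0, inferior_nasal = 0, arrowhead = 0,
         diffuse = 0, diffuse_superior = 0)
  p <- generator_params(archetype_weights = w)
  co <- generate_glaucoma_fields(300, p, seed = 13)
  dev <- sweep(cohort_thresholds(co), 2, p$normal_mean_surface)
  masks <- region_masks_242()
  expect_lt(mean(dev[, masks$superior]), mean(dev[, masks$inferior]))
})

test_that("archetype templates are non-positive unit-MD loss profiles", {
  tpl <- defect_archetypes()
  expect_setequal(names(tpl),
                  c("superior_altitudinal", "inferior_altitudinal",
                    "superior_nasal", "inferior_nasal", "arrowhead",
                    "diffuse", "diffuse_superior"))
  masks <- region_masks_242()
  for (nm in names(tpl)) {
    expect_true(all(tpl[[nm]] <= 0))
    expect_equal(mean(tpl[[nm]]), -1)
  }
  expect_true(all(tpl$superior_altitudinal[masks$inferior] == 0))
  expect_true(all(tpl$superior_nasal[!masks$superior_nasal] == 0))
  expect_true(all(tpl$arrowhead[masks$nasal] < 0))
  expect_true(all(tpl$arrowhead[masks$temporal] == 0))
})

test_that("the study cohort concatenates the two arms with exact counts", {
  co <- generate_study_cohort(120, 80, seed = 4)
  expect_equal(cohort_size(co), 200L)
  expect_equal(sum(co$records$fdt_label == "normal"), 120L)
  expect_equal(sum(co$records$fdt_label == "abnormal"), 80L)
  all_abn <- generate_study_cohort(0, 25, seed = 4)
  expect_true(all(all_abn$records$fdt_label == "abnormal"))
  expect_identical(generate_study_cohort(50, 30, seed = 9)$records,
                   generate_study_cohort(50, 30, seed = 9)$records)
})

test_that("arm-specific age structure matches its calibration targets", {
  nrm <- generate_normal_fields(2000, seed = 41)
  abn <- generate_glaucoma_fields(2000, seed = 42)
  se_n <- sd(nrm$records$age) / sqrt(2000)
  se_a <- sd(abn$records$age) / sqrt(2000)
  expect_lt(abs(mean(nrm$records$age) - 50.0), 3 * se_n + 0.3)
  expect_lt(abs(mean(abn$records$age) - 55.9), 3 * se_a + 0.3)
})

test_that("the ICA-mixture sampler matches its first and second moments", {
  truth <- separated_truth(K = 2, D = 6, L = 2, sep = 6)
  sam <- sample_ica_mixture(truth, 1e4, seed = 8)
  phat <- mean(sam$cluster == 1)
  se <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(phat - 0.5), 3 * se)
  ## single-cluster covariance oracle: A Cov(s) A' + noise^2 I
  tr1 <- one_cluster_truth(D = 5, L = 2, A_scale = 1.5, noise_sd = 0.4)
  s1 <- sample_ica_mixture(tr1, 2e4, seed = 9)
  A <- tr1$clusters[[1]]$A
  vs <- 1.2^2 + 0.4^2          # variance of the bimodal source
  expected <- A %*% (vs * diag(2)) %*% t(A) + 0.4^2 * diag(5)
  expect_lt(max(abs(cov(s1$X) - expected)), 0.12 * max(abs(expected)))
})

test_that("the sampler's degenerate limit returns mean plus sources exactly", {
  tr <- ica_mixture_truth(
    weights = 1,
    clusters = list(list(mean = c(5, -5), A = diag(2),
                         sources = rep(list(list(weights = 1, means = 0.5,
                                                 sds = 1)), 2),
                         noise_sd = 1e-15)))
  sam <- sample_ica_mixture(tr, 50, seed = 2)
  expect_equal(sam$X, sweep(sam$sources, 2, c(5, -5), "+"), tolerance = 1e-10)
  bad <- list(mean = rep(0, 3), A = cbind(c(1, 1, 0), c(2, 2, 0)),
              sources = rep(list(list(weights = 1, means = 0, sds = 1)), 2),
              noise_sd = 1)
  expect_error(ica_mixture_truth(1, list(bad)), "rank")
})
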