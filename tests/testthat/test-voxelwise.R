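make_maps <- function(Y, d, affine = diag(c(2, 2, 2, 1))) {
  lapply(seq_len(nrow(Y)), function(i)
    brain_volume(array(Y[i, ], dim = d), affine = affine))
}
full_mask <- function(d) brain_volume(array(1, d), affine = diag(c(2, 2, 2, 1)))

test_that("voxelwise OLS agrees with lm at a single voxel", {
  set.seed(2)
  n <- 40
  x <- rnorm(n); age <- rnorm(n, 70, 8); sex <- rbinom(n, 1, 0.5)
  y <- 0.7 * x + 0.02 * age + rnorm(n)
  d <- c(1L, 1L, 1L)
  maps <- make_maps(matrix(y, ncol = 1), d)
  fit <- fit_voxelwise(maps, x, data.frame(age = age, sex = sex),
                       full_mask(d))
  ref <- summary(stats::lm(y ~ x + age + sex))$coefficients["x", ]
  expect_equal(fit$beta_map$data[1, 1, 1], unname(ref["Estimate"]),
               tolerance = 1e-10)
  expect_equal(fit$t_map$data[1, 1, 1], unname(ref["t value"]),
               tolerance = 1e-10)
  expect_equal(fit$df, n - 4L)
})

test_that("perfect fit takes the clamped-z path with beta one", {
  x <- rnorm(10)
  d <- c(2L, 1L, 1L)
  maps <- make_maps(cbind(x, x), d)
  fit <- fit_voxelwise(maps, x, NULL, full_mask(d))
  expect_equal(unname(fit$beta_map$data[1, 1, 1]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(fit$z_map$data)))
  expect_equal(fit$z_map$data[1, 1, 1], stats::qnorm(1 - 1e-15))
})

test_that("rank-deficient designs name the collinear columns", {
  x <- rnorm(12)
  d <- c(2L, 1L, 1L)
  maps <- make_maps(matrix(rnorm(24), 12), d)
  expect_error(fit_voxelwise(maps, x, data.frame(dup = x), full_mask(d)),
               "collinear")
})

test_that("residualization leaves maps orthogonal to the nuisance", {
  set.seed(3)
  n <- 30; V <- 50
  nuis <- rnorm(n)
  eps <- matrix(rnorm(n * V, sd = 0.5), n)
  Y <- 2 * nuis %o% rep(1, V) + eps
  d <- c(5L, 5L, 2L)
  res <- residualize_against(make_maps(Y, d), nuis, full_mask(d))
  R <- t(vapply(res, function(v) as.numeric(v$data), numeric(V)))
  expect_lt(max(abs(crossprod(R, nuis))), 1e-8)
  # residual variance ~= noise variance, not signal variance
  expect_lt(mean(apply(R, 2, var)), 0.35)

  orth <- rnorm(n); orth <- residuals(lm(orth ~ nuis))
  Y2 <- orth %o% rep(1, V)
  R2 <- residualize_against(make_maps(Y2, d), nuis, full_mask(d))
  centered <- Y2[, 1] - mean(Y2[, 1])
  expect_equal(as.numeric(R2[[2]]$data[1, 1, 1]), unname(centered[2]),
               tolerance = 1e-10)
})

test_that("interaction z-map is invariant to moderator shifts", {
  set.seed(4)
  n <- 60
  x <- rnorm(n); m <- rnorm(n, 1.3, 0.2)
  d <- c(3L, 3L, 1L); V <- 9
  Y <- matrix(rnorm(n * V, sd = 0.3), n) + 0.5 * (x * m) %o% rep(1, V)
  maps <- make_maps(Y, d)
  f1 <- fit_interaction(maps, x, m, NULL, full_mask(d))
  f2 <- fit_interaction(maps, x, m + 5, NULL, full_mask(d))
  expect_equal(f1$z_map$data, f2$z_map$data, tolerance = 1e-8)
  expect_equal(f1$beta_map$data, f2$beta_map$data, tolerance = 1e-8)
})

test_that("z-maps are invariant to affine rescaling of the outcome", {
  set.seed(5)
  n <- 50; V <- 27; d <- c(3L, 3L, 3L)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * V), n) + 0.4 * x %o% rep(1, V)
  f1 <- fit_voxelwise(make_maps(Y, d), x, NULL, full_mask(d))
  f2 <- fit_voxelwise(make_maps(3.7 * Y + 2, d), x, NULL, full_mask(d))
  expect_equal(f1$z_map$data, f2$z_map$data, tolerance = 1e-8)
})

test_that("partial correlation identity r^2 = t^2/(t^2+df) holds", {
  set.seed(6)
  n <- 35; V <- 20; d <- c(5L, 2L, 2L)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * V), n) + 0.3 * x %o% rep(1, V)
  fit <- fit_voxelwise(make_maps(Y, d), x, NULL, full_mask(d))
  t <- as.numeric(fit$t_map$data)
  r <- t / sqrt(t^2 + fit$df)
  # against the definition: partial r as correlation of residualized parts
  r_direct <- apply(Y, 2, function(y) cor(y, x))
  expect_equal(r, r_direct, tolerance = 1e-10)
})

test_that("cluster extraction filters by threshold and extent", {
  d <- c(10L, 10L, 5L)
  z <- array(0, d)
  cs <- extract_clusters(brain_volume(z, affine = diag(c(2, 2, 2, 1))),
                         full_mask(d), 1.64, 1L)
  expect_length(cs$sizes, 0)

  z[2:4, 2:6, 2:3] <- 3      # 30 voxels
  z[8:10, 9, 5] <- 3         # 3 voxels
  cs <- extract_clusters(brain_volume(z, affine = diag(c(2, 2, 2, 1))),
                         full_mask(d), 1.64, 10L)
  expect_equal(cs$sizes, 30L)
  expect_equal(sum(cs$label_map$data == 1), 30)
  tab <- cluster_table(cs, brain_volume(z, affine = diag(c(2, 2, 2, 1))))
  expect_equal(tab$size, 30L)
  expect_equal(tab$peak_z, 3)
})

test_that("unsmoothed MC threshold matches its own null distribution", {
  mask <- full_mask(c(10L, 10L, 10L))
  thr <- mc_cluster_threshold(mask, smoothing_fwhm_mm = 0,
                              n_iter = 200L, seed = 9L)
  ms <- attr(thr, "max_sizes")
  expect_equal(as.integer(thr), sort(ms)[ceiling(0.95 * 200)] + 1L)
  # determinism
  thr2 <- mc_cluster_threshold(mask, smoothing_fwhm_mm = 0,
                               n_iter = 200L, seed = 9L)
  expect_identical(attr(thr2, "max_sizes"), ms)
  # sub-voxel FWHM warns and falls back to unsmoothed noise
  expect_warning(mc_cluster_threshold(mask, smoothing_fwhm_mm = 1,
                                      n_iter = 100L, seed = 1L),
                 "FWHM")
  expect_error(mc_cluster_threshold(mask, n_iter = 50L), "n_iter")
})

test_that("MC threshold is monotone in voxel threshold and smoothing", {
  mask <- full_mask(c(12L, 12L, 12L))
  thr_z <- vapply(c(1.64, 2.3, 3.1), function(z)
    as.integer(mc_cluster_threshold(mask, 0, z, n_iter = 150L, seed = 7L)),
    integer(1))
  expect_true(all(diff(thr_z) <= 0))
  thr_s <- vapply(c(0, 4, 8), function(f)
    as.integer(mc_cluster_threshold(mask, f, n_iter = 150L, seed = 7L)),
    integer(1))
  expect_true(all(diff(thr_s) >= 0))
})

test_that("directional comparison handles identity, shift and recovery", {
  set.seed(10)
  n <- 80; V <- 64; d <- c(4L, 4L, 4L)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * V, sd = 0.3), n) + 0.5 * x %o% rep(1, V)
  maps <- make_maps(Y, d)
  fwd <- fit_voxelwise(maps, x, NULL, full_mask(d))
  cl <- extract_clusters(fwd$z_map, full_mask(d), 1.64, 5L)
  expect_gt(length(cl$sizes), 0)

  same <- compare_directions(fwd, fwd, cl)
  expect_equal(same$t_stat, 0)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$pearson_r, 1)

  shifted <- fwd
  # shift the partial correlations by a constant through the t-field
  r <- fwd$t_map$data / sqrt(fwd$t_map$data^2 + fwd$df)
  r2 <- pmin(r - 0.07, 0.999)
  shifted$t_map <- brain_volume(r2 * sqrt(fwd$df / (1 - r2^2)),
                                affine = fwd$t_map$affine)
  cmp <- compare_directions(fwd, shifted, cl)
  expect_equal(cmp$mean_difference, 0.07, tolerance = 1e-10)
  expect_gt(cmp$t_stat, 1e6)

  one_voxel <- extract_clusters(fwd$z_map, full_mask(d), 1.64, 1L)
  lbl <- which(one_voxel$sizes == 1)[1]
  if (!is.na(lbl))
    expect_error(compare_directions(fwd, fwd, one_voxel, labels = lbl),
                 "degenerate")
})

test_that("forward effect is recovered with matching df convention", {
  sim <- gen_cohort(cohort_sim_spec(n_subjects = 200L, seed = 31L))
  fwd <- fit_voxelwise(sim$tau_followup, sim$table$z_intensity_r_bl,
                       sim$table[, c("age", "sex")], sim$mask)
  rev <- fit_voxelwise(sim$tau_baseline, sim$table$intensity_r_fu,
                       sim$table[, c("age", "sex")], sim$mask)
  cl <- extract_clusters(fwd$z_map, sim$mask, 1.64, 10L)
  expect_gt(length(cl$sizes), 0)
  cmp <- compare_directions(fwd, rev, cl, labels = 1L)
  expect_equal(cmp$df, sum(cl$label_map$data == 1) - 1L)
  expect_gt(cmp$mean_difference, 0)
  # planted cluster recovery: Dice overlap with the truth voxels
  rec <- which(cl$label_map$data == 1)
  truth <- sim$truth$spec$mtl_cluster_voxels
  dice <- 2 * length(intersect(rec, truth)) / (length(rec) + length(truth))
  expect_gte(dice, 0.5)
})
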