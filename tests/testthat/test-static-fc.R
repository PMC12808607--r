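test_that("fc_matrix matches hand-computed Pearson correlations", {
  x <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unclass(fc_matrix(x))[1, 2], 1)
  x2 <- rbind(c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(unclass(fc_matrix(x2))[1, 2], -1)
  # textbook covariance/SD formula
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unclass(fc_matrix(rbind(a, b)))[1, 2], r_hand,
               tolerance = 1e-12)
})

test_that("fc_matrix equals a brute-force double-loop oracle", {
  set.seed(11)
  x <- matrix(rnorm(5 * 50), 5, 50)
  fc <- unclass(fc_matrix(x))
  for (i in 1:5) for (j in 1:5) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    expect_equal(fc[i, j], r, tolerance = 1e-12)
  }
})

test_that("fc_matrix flags constant ROIs and short intervals", {
  x <- rbind(rnorm(10), rep(1, 10))
  expect_warning(fc <- fc_matrix(x), "constant")
  expect_true(is.nan(unclass(fc)[1, 2]))
  expect_equal(unclass(fc)[1, 1], 1)
  expect_error(fc_matrix(matrix(rnorm(6), 2, 3)), "at least 4")
})

test_that("ROI permutation permutes FC matrices consistently", {
  set.seed(12)
  x <- matrix(rnorm(6 * 80), 6, 80)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(unclass(fc_matrix(x[perm, ])),
               unclass(fc_matrix(x))[perm, perm], ignore_attr = TRUE)
})

test_that("Fisher transform is exact, clamped, and invertible", {
  set.seed(13)
  fc <- fc_matrix(matrix(rnorm(4 * 60), 4, 60))
  z <- fisher_z(fc)
  expect_equal(unclass(z)[1, 2], atanh(unclass(fc)[1, 2]))
  expect_true(all(is.na(diag(unclass(z)))))
  back <- inverse_fisher_z(z)
  expect_equal(unclass(back)[upper.tri(back)],
               unclass(fc)[upper.tri(fc)], tolerance = 1e-12)
  r0 <- structure(diag(2), class = c("fc_matrix", "matrix"), space = "r")
  expect_equal(unclass(fisher_z(r0))[1, 2], 0)
  # clamping at |r| ~ 1
  x <- rbind(1:10, 1:10 + 1e-9 * rnorm(10))
  expect_warning(z1 <- fisher_z(fc_matrix(x)), "clamped")
  expect_true(is.finite(unclass(z1)[1, 2]))
  expect_error(fisher_z(z), "r space")
})

test_that("interval differences subtract elementwise and check spaces", {
  set.seed(14)
  f1 <- fisher_z(fc_matrix(matrix(rnorm(4 * 50), 4, 50)))
  f2 <- fisher_z(fc_matrix(matrix(rnorm(4 * 50), 4, 50)))
  zero <- matrix(0, 4, 4); diag(zero) <- NA_real_
  expect_equal(interval_difference(f1, f1), zero)
  d <- interval_difference(f2, f1)
  expect_equal(d[1, 2], unclass(f2)[1, 2] - unclass(f1)[1, 2])
  r1 <- inverse_fisher_z(f1)
  expect_error(interval_difference(f2, r1), "different spaces")
})

test_that("group-mean differences vanish on stationary synthetic data", {
  sim <- simulate_cohort(clean_null_config(n_animals_per_genotype = 4,
                                           n_roi = 12, seed = 15,
                                           noise_sd = 0.2))
  seg <- segment_conditions(sim$tsset)
  fcints <- interval_fc_matrices(sim$tsset, seg)
  diffs <- lapply(fcints, function(zl)
    interval_difference(zl[["drug1"]], zl[["vehicle3"]]))
  md <- Reduce(`+`, diffs) / length(diffs)
  # 3 x SE of a mean of 4 animals' windowed-z differences
  tol <- 3 * sqrt(2 / (2 * 0.092 * 600)) / sqrt(4)
  expect_lt(max(abs(md[upper.tri(md)])), tol * 2)
  expect_lt(abs(mean(md[upper.tri(md)])), tol / 2)
})

test_that("genotype baseline contrast is zero for identical groups", {
  set.seed(16)
  zs <- lapply(1:3, function(k)
    fisher_z(fc_matrix(matrix(rnorm(5 * 100), 5, 100))))
  d <- genotype_baseline_contrast(zs, zs)
  expect_equal(max(abs(d[upper.tri(d)])), 0)
  # single animal per group reduces to a plain difference
  d2 <- genotype_baseline_contrast(zs[1], zs[2])
  expect_equal(d2[1, 2], unclass(zs[[2]])[1, 2] - unclass(zs[[1]])[1, 2])
  expect_error(genotype_baseline_contrast(list(), zs), "non-empty")
})

test_that("fc_variability is the population variance of pooled upper-triangle z", {
  z <- as_z_matrix(rbind(c(0, 0.1, 0.2), c(0.1, 0, 0.6), c(0.2, 0.6, 0)))
  seg <- data.frame(condition = "baseline", interval = 1, label = "baseline1",
                    start_s = 0, start_sample = 1, end_sample = 600)
  v <- fc_variability(list(baseline1 = z), seg, "baseline")
  vals <- c(0.1, 0.2, 0.6)
  expect_equal(v, mean((vals - mean(vals))^2), tolerance = 1e-12)
  # all edges equal -> zero variability
  z0 <- as_z_matrix(matrix(0.3, 3, 3))
  expect_equal(fc_variability(list(baseline1 = z0), seg, "baseline"), 0)
})

test_that("fc_variability is invariant to ROI ordering", {
  set.seed(17)
  x <- matrix(rnorm(6 * 600), 6, 600)
  seg <- data.frame(condition = "baseline", interval = 1, label = "baseline1",
                    start_s = 0, start_sample = 1, end_sample = 600)
  v1 <- fc_variability(list(baseline1 = fisher_z(fc_matrix(x))), seg,
                       "baseline")
  perm <- sample(6)
  v2 <- fc_variability(list(baseline1 = fisher_z(fc_matrix(x[perm, ]))), seg,
                       "baseline")
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("identical genotype cohorts give a null variability comparison", {
  set.seed(18)
  sigs <- lapply(1:6, function(k) matrix(rnorm(6 * 2400), 6, 2400))
  ts <- make_tsset(c(sigs[1:3], sigs[1:3]), tr_s = 1,
                   vehicle_onset_s = 600, drug_onset_s = 1200,
                   genotypes = rep(c("WT", "KO"), each = 3))
  tab <- fc_variability_table(ts, segment_conditions(ts))
  tests <- attr(tab, "tests")
  expect_equal(tests$t, rep(0, 3), tolerance = 1e-10)
  expect_equal(tests$df, rep(4, 3))
})

test_that("group_mean_sem matches the hand formula", {
  xs <- list(c(1, 4), c(2, 6), c(3, 11))
  gs <- group_mean_sem(xs)
  expect_equal(gs$mean, c(2, 7))
  expect_equal(gs$sem, c(stats::sd(c(1, 2, 3)) / sqrt(3),
                         stats::sd(c(4, 6, 11)) / sqrt(3)))
})
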