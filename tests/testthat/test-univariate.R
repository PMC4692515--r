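test_that("the two-gamma response has the canonical shape", {
  expect_equal(two_gamma_hrf(0), 0)
  tt <- seq(0, 32, by = 0.1)
  h <- two_gamma_hrf(tt)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(h)], 5, tolerance = 0.2)
  expect_lt(abs(two_gamma_hrf(30)), 0.01)
  # undershoot present
  expect_lt(min(h), 0)
})

test_that("design columns equal the direct-convolution oracle", {
  ev <- structure(data.frame(run = 1, onset = 10, duration = 6, condition = 1),
                  tr_s = 2, n_volumes = 40,
                  class = c("event_table", "data.frame"))
  X <- build_design(ev, conditions = 1)
  u <- numeric(40)
  u[6:8] <- 1  # 0-based volumes 5,6,7 cover 10-16 s
  hrf <- two_gamma_hrf(seq(0, 32, by = 2))
  expect_equal(unname(X[, 1]), conv_oracle(u, hrf), tolerance = 1e-12)
})

test_that("an absent condition yields a rank-deficiency error", {
  ev <- structure(data.frame(run = 1, onset = c(10, 30), duration = 6,
                             condition = c(1, 2)),
                  tr_s = 2, n_volumes = 40,
                  class = c("event_table", "data.frame"))
  expect_error(build_design(ev, conditions = 1:3), "rank deficient")
})

test_that("noise-free betas recover the simulated amplitudes exactly", {
  spec <- small_spec(seed = 71, blocks = 2)
  shape <- c(3, 3, 3)
  truth <- tuned_truth(shape, n_inf = 4, amp = 2.5, noise_sd = 0, seed = 71)
  ev <- generate_events(spec)
  bold <- generate_bold(ev, truth, shape)
  Y <- do.call(rbind, preprocess_runs(bold, n_cycles = 0, zscore = FALSE)$runs)
  X <- build_design(ev)
  fit <- fit_glm(Y, X)
  expect_lt(max(abs(fit$beta[1:4, 1:4] - truth$amplitudes)), 1e-8)
  # linearity: doubling amplitudes doubles betas
  truth2 <- truth; truth2$amplitudes <- 2 * truth$amplitudes
  Y2 <- do.call(rbind, preprocess_runs(generate_bold(ev, truth2, shape),
                                       n_cycles = 0, zscore = FALSE)$runs)
  fit2 <- fit_glm(Y2, X)
  expect_equal(fit2$beta[1:4, 1:4], 2 * fit$beta[1:4, 1:4], tolerance = 1e-8)
  # residuals orthogonal to the design
  res <- Y - X %*% fit$beta
  expect_lt(max(abs(crossprod(X, res))), 1e-6)
})

test_that("null-voxel t-statistics are calibrated against the t distribution", {
  spec <- small_spec(seed = 72, blocks = 2)
  shape <- c(6, 6, 6)   # 216 null voxels
  ev <- generate_events(spec)
  bold <- generate_bold(ev, ground_truth(noise_sd = 1, seed = 72), shape)
  Y <- do.call(rbind, preprocess_runs(bold, n_cycles = 0, zscore = FALSE)$runs)
  X <- build_design(ev)
  fit <- fit_glm(Y, X)
  t1 <- contrast_t(fit, 1)
  p <- 2 * pt(-abs(t1), fit$dof)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("one-vs-all contrasts separate tuned from non-selective voxels", {
  spec <- small_spec(seed = 73, blocks = 3)
  shape <- c(3, 3, 3)
  ev <- generate_events(spec)
  # voxel 1 responds only to condition 1; voxel 2 equally to all four
  iv <- linear_to_grid_oracle(1:2, shape)
  A <- cbind(c(6, 0, 0, 0), c(3, 3, 3, 3))
  bold <- generate_bold(ev, ground_truth(iv, A, noise_sd = 1, seed = 73), shape)
  Y <- do.call(rbind, preprocess_runs(bold, n_cycles = 0, zscore = FALSE)$runs)
  fit <- fit_glm(Y, build_design(ev))
  tm <- sapply(1:4, function(cc) contrast_t(fit, cc))
  expect_gt(tm[1, 1], 10)
  expect_true(all(tm[1, 2:4] < 0))
  expect_lt(abs(tm[2, 1]), 3)  # non-selective voxel: t near 0
})

test_that("permuting condition labels permutes the t-maps identically", {
  spec <- small_spec(seed = 74, blocks = 2)
  shape <- c(3, 3, 3)
  ev <- generate_events(spec)
  truth <- tuned_truth(shape, n_inf = 4, amp = 3, noise_sd = 1, seed = 74)
  bold <- generate_bold(ev, truth, shape)
  Y <- do.call(rbind, preprocess_runs(bold, n_cycles = 0, zscore = FALSE)$runs)
  fit <- fit_glm(Y, build_design(ev))
  tm <- sapply(1:4, function(cc) contrast_t(fit, cc))
  # relabel conditions 1<->2 in the events: maps for 1 and 2 swap
  ev2 <- ev
  ev2$condition <- c(2, 1, 3, 4)[ev$condition]
  fit2 <- fit_glm(Y, build_design(ev2))
  tm2 <- sapply(1:4, function(cc) contrast_t(fit2, cc))
  expect_equal(tm2[, c(2, 1, 3, 4)], tm, tolerance = 1e-10)
})

test_that("preference maps take the argmax with deterministic ties", {
  tm <- rbind(c(3, 1, 0, -1), c(1, 1, 0, 0), c(-1, 0, 2, 2))
  pref <- preference_map(tm, c(TRUE, TRUE, TRUE))
  expect_equal(pref, c(1L, 1L, 3L))
  expect_equal(preference_map(tm, c(FALSE, FALSE, FALSE)), c(0L, 0L, 0L))
  expect_error(preference_map(tm, c(TRUE, TRUE)), "mismatch")
})

test_that("t-map FDR thresholding is rank-based and order-invariant", {
  expect_false(any(fdr_threshold_t(rep(0, 50), dof = 100)))
  t <- c(rnorm(99, sd = 0.5), 20)
  m <- fdr_threshold_t(t, dof = 100)
  expect_true(m[100])
  perm <- sample(100)
  expect_equal(fdr_threshold_t(t[perm], dof = 100), m[perm])
})

test_that("FDR on null t-maps controls the false-positive fraction", {
  set.seed(75)
  fps <- replicate(20, {
    t <- rt(200, df = 50)
    mean(fdr_threshold_t(t, dof = 50, q = 0.05))
  })
  expect_lte(mean(fps), 0.05)
})
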