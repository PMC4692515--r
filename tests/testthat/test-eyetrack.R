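make_gaze <- function(x, y, par = rep(1, length(x)), trial = rep(1L, length(x)),
                      condition = rep(1L, length(x)), rate = 60) {
  n <- length(x)
  structure(data.frame(time = (seq_len(n) - 1) / rate, x = x, y = y,
                       par = par, trial = trial, condition = condition),
            sampling_rate_hz = rate, class = c("gaze_recording", "data.frame"))
}

test_that("blink rejection drops exactly the pupil-aspect outliers", {
  g_const <- make_gaze(rnorm(100, sd = 0.01), rnorm(100, sd = 0.01))
  expect_equal(nrow(remove_blinks(g_const)), 100)
  par <- c(rep(1, 99), 0.2)
  g <- make_gaze(rnorm(100, sd = 0.01), rnorm(100, sd = 0.01), par = par)
  clean <- remove_blinks(g)
  expect_equal(nrow(clean), 99)
  expect_true(all(clean$par == 1))
  expect_equal(unname(attr(clean, "retention")["1"]), 0.99)
  # idempotent on already-clean data (constant par: zero-SD interval keeps all)
  expect_equal(nrow(remove_blinks(clean)), 99)
})

test_that("saccade detection is quiet on fixation noise", {
  n_quiet <- sapply(1:20, function(s) {
    set.seed(800 + s)
    g <- make_gaze(rnorm(360, sd = 0.03), rnorm(360, sd = 0.03))
    nrow(detect_saccades(g))
  })
  expect_gte(mean(n_quiet == 0), 0.95)
})

test_that("an injected step is detected once with the right direction", {
  for (ang in c(0, 45, 90, 210, 330)) {
    set.seed(810 + ang)
    n <- 360
    step <- 1 / (1 + exp(-((seq_len(n) - 180) / 0.5)))
    x <- rnorm(n, sd = 0.01) + cospi(ang / 180) * step
    y <- rnorm(n, sd = 0.01) + sinpi(ang / 180) * step
    ev <- detect_saccades(make_gaze(x, y))
    expect_equal(nrow(ev), 1)
    err <- abs((ev$direction_deg - ang + 180) %% 360 - 180)
    expect_lt(err, 5)
    expect_equal(ev$amplitude_deg, 1, tolerance = 0.1)
  }
})

test_that("net-displacement direction follows the atan2 convention", {
  # pure upward step: (dx, dy) = (0, 1) -> 90 degrees
  n <- 100
  step <- c(rep(0, 50), rep(1, 50))
  ev <- detect_saccades(make_gaze(rnorm(n, sd = 0.005),
                                  step + rnorm(n, sd = 0.005)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction_deg, 90, tolerance = 5)
})

test_that("degenerate flat traces raise an error", {
  g <- make_gaze(rep(0, 50), rep(0, 50))
  expect_error(detect_saccades(g), "degenerate")
})

test_that("common-median test: identical groups give P = 0, p = 1", {
  a <- c(10, 80, 200, 355)
  res <- circ_median_test(c(a, a), rep(1:2, each = 4))
  expect_equal(res$statistic_value, 0)
  expect_equal(res$p_value, 1)
  ident <- circ_median_test(rep(90, 8), rep(1:2, each = 4))
  expect_equal(ident$p_value, 1)
})

test_that("common-median test is invariant under common rotation", {
  set.seed(820)
  ang <- runif(27, 0, 360)
  grp <- rep(1:3, each = 9)
  base <- circ_median_test(ang, grp)
  for (rot in c(30, 123, 270)) {
    r <- circ_median_test((ang + rot) %% 360, grp)
    expect_equal(r$statistic_value, base$statistic_value, tolerance = 1e-9)
  }
})

test_that("common-median test is calibrated under a shared von Mises null", {
  set.seed(821)
  rej <- replicate(500, {
    ang <- (motionmvpa:::rvonmises(48, pi / 3, 2) * 180 / pi) %% 360
    circ_median_test(ang, rep(1:4, each = 12))$p_value < 0.05
  })
  rate <- mean(rej)
  ci <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("circular correlation hits the trivial limits", {
  a <- c(10, 50, 90, 200, 300)
  expect_equal(circ_corr(a, a)$statistic_value, 1, tolerance = 1e-12)
  expect_equal(circ_corr(a, (a + 77) %% 360)$statistic_value, 1,
               tolerance = 1e-9)
  expect_equal(circ_corr(a, (-a) %% 360)$statistic_value, -1,
               tolerance = 1e-9)
  degen <- circ_corr(c(0, 0, 0), c(10, 20, 30))
  expect_true(degen$degenerate)
})

test_that("the MVEE matches known geometry and a grid-search oracle", {
  P <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  fit <- fit_mvee(P)
  expect_equal(fit$semi_axes, c(2, 1), tolerance = 0.01)
  expect_equal(fit$rotation_deg %% 90, 0, tolerance = 0.5)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-3, ignore_attr = TRUE)
  # rotating the point set rotates the fit
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit30 <- fit_mvee(P %*% t(R))
  expect_equal(fit30$rotation_deg %% 180, (fit$rotation_deg + 30) %% 180,
               tolerance = 1)
  # minimality within 1% of the coarse-grid oracle
  set.seed(830)
  for (i in 1:3) {
    Q <- matrix(rnorm(16), 8)
    f <- fit_mvee(Q)
    oracle <- mvee_grid_oracle(Q)
    expect_lte(f$area, oracle * 1.01)
    # defining property: all points enclosed (within tolerance)
    dev <- sweep(Q, 2, f$center)
    expect_lte(max(rowSums((dev %*% f$A) * dev)), 1 + 1e-6)
  }
  expect_error(fit_mvee(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("ellipse rotation tests use the doubled axial scale", {
  # doubling then halving is the identity on [0, 180)
  rot <- c(0, 10, 95, 179.5)
  expect_equal(((2 * rot) %% 360) / 2, rot)
  conds <- rep(1:4, each = 3)
  shared <- rep(42, 12)
  res <- ellipse_rotation_tests(shared, conds)
  expect_equal(res$median_test$p_value, 1)
  # rotations locked to the condition angle: |r| near 1
  angles <- c("1" = 0, "2" = 45, "3" = 90, "4" = 135)
  locked <- angles[as.character(conds)]
  res2 <- ellipse_rotation_tests(locked %% 180, conds,
                                 condition_angles_deg = angles * 2)
  expect_equal(abs(res2$correlation$statistic_value), 1, tolerance = 1e-9)
  expect_error(ellipse_rotation_tests(rot, c(1, 1, 2, 3)), "2 trials")
})

test_that("simulated session gaze flows through cleaning and detection", {
  spec <- small_spec(seed = 84, blocks = 2, n_runs = 1)
  ev <- generate_events(spec)
  lock <- c("1" = 0, "2" = 90, "3" = 180, "4" = 270)
  gz <- generate_gaze(ev, direction_lock = lock, blink_rate_hz = 0.05,
                      kappa = 300, seed = 84)
  clean <- remove_blinks(gz)
  sacc <- detect_saccades(clean)
  expect_equal(nrow(sacc), nrow(ev))
  target <- lock[as.character(sacc$condition)]
  err <- abs((sacc$direction_deg - target + 180) %% 360 - 180)
  expect_lt(max(err), 10)
})
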