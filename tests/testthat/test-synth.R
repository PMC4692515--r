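test_that("default paradigm yields 160 trials, 40 per condition, balanced blocks", {
  ev <- generate_events(paradigm_spec(seed = 11))
  expect_equal(nrow(ev), 160)
  expect_equal(unname(table(ev$condition)), rep(40L, 4), ignore_attr = TRUE)
  expect_equal(length(unique(ev$run)), 4)
  # each block of 4 consecutive trials holds each condition exactly once
  for (r in 1:4) {
    conds <- ev$condition[ev$run == r]
    blocks <- matrix(conds, nrow = 4)
    expect_true(all(apply(blocks, 2, function(b) setequal(b, 1:4))))
  }
})

test_that("a one-run one-block paradigm gives one trial per condition", {
  ev <- generate_events(paradigm_spec(n_runs = 1, blocks_per_run = 1, seed = 2))
  expect_equal(nrow(ev), 4)
  expect_setequal(ev$condition, 1:4)
})

test_that("event generation is seeded and deterministic", {
  a <- generate_events(paradigm_spec(seed = 5))
  b <- generate_events(paradigm_spec(seed = 5))
  c <- generate_events(paradigm_spec(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$condition, c$condition))
})

test_that("onsets and durations sit on the volume grid and never overlap", {
  ev <- generate_events(paradigm_spec(seed = 3))
  expect_true(all(ev$onset %% 2 == 0))
  expect_true(all(ev$duration %in% c(6, 8)))
  for (r in unique(ev$run)) {
    e <- ev[ev$run == r, ]
    expect_true(all(diff(e$onset) >= e$duration[-nrow(e)]))
  }
})

test_that("trial durations and rests are drawn from the stated sets", {
  ev <- generate_events(paradigm_spec(seed = 9))
  expect_setequal(unique(ev$duration), c(6, 8))
  # gaps between consecutive blocks are 8, 10 or 12 s
  for (r in unique(ev$run)) {
    e <- ev[ev$run == r, ]
    block_end <- e$onset[seq(4, nrow(e) - 1, by = 4)] +
      e$duration[seq(4, nrow(e) - 1, by = 4)]
    block_start <- e$onset[seq(5, nrow(e), by = 4)]
    expect_true(all((block_start - block_end) %in% c(8, 10, 12)))
  }
})

test_that("paradigm invariants are enforced", {
  expect_error(paradigm_spec(trials_per_block = 3), "number of conditions")
  expect_error(paradigm_spec(trial_durations_s = c(6, 7)), "multiples")
})

test_that("noise- and signal-free volumes are constant at baseline", {
  spec <- small_spec(seed = 4, blocks = 2)
  ev <- generate_events(spec)
  gt <- ground_truth(noise_sd = 0, drift_amplitude = 0, baseline = 50)
  bold <- generate_bold(ev, gt, c(3, 3, 3))
  for (run in bold$runs) expect_true(all(run == 50))
})

test_that("a noise-free informative voxel matches the direct-convolution oracle", {
  spec <- small_spec(seed = 7, blocks = 2)
  ev <- generate_events(spec)
  gt <- ground_truth(matrix(c(1L, 1L, 1L), 1), amplitudes = matrix(c(1, 0, 0, 0), 4),
                     noise_sd = 0, drift_amplitude = 0, baseline = 0)
  bold <- generate_bold(ev, gt, c(3, 3, 3))
  hrf <- two_gamma_hrf(seq(0, 32, by = 2))
  for (ri in seq_along(bold$runs)) {
    nv <- dim(bold$runs[[ri]])[4]
    e <- ev[ev$run == ri & ev$condition == 1, ]
    u <- numeric(nv)
    tvol <- (seq_len(nv) - 1) * 2
    for (j in seq_len(nrow(e)))
      u[tvol >= e$onset[j] & tvol < e$onset[j] + e$duration[j]] <- 1
    expected <- conv_oracle(u, hrf)
    got <- bold$runs[[ri]][2, 2, 2, ]
    expect_equal(got, expected, tolerance = 1e-12)
    # non-informative voxel stays flat
    expect_true(all(bold$runs[[ri]][1, 1, 1, ] == 0))
  }
})

test_that("BOLD simulation is bit-identical under a fixed seed", {
  spec <- small_spec(seed = 8, blocks = 2)
  ev <- generate_events(spec)
  gt <- ground_truth(noise_sd = 1, seed = 21)
  expect_identical(generate_bold(ev, gt, c(3, 3, 3)),
                   generate_bold(ev, gt, c(3, 3, 3)))
})

test_that("simulator rejects invalid inputs", {
  spec <- small_spec(seed = 1, blocks = 2)
  ev <- generate_events(spec)
  expect_error(ground_truth(noise_sd = -1), "non-negative")
  expect_error(generate_bold(ev[0, ], ground_truth(), c(3, 3, 3)), "empty")
  expect_error(
    generate_bold(ev, ground_truth(matrix(c(5L, 0L, 0L), 1),
                                   amplitudes = matrix(1, 4)), c(3, 3, 3)),
    "outside")
})

test_that("mask dilation adds face neighbors, clips at borders, is monotone", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_equal(sum(dilate_mask(m, 1)), 7)
  # Manhattan ball of radius 2 (independent count by enumeration)
  d2 <- dilate_mask(m, 2)
  g <- expand.grid(1:7, 1:7, 1:7)
  expect_equal(sum(d2), sum(abs(g[, 1] - 4) + abs(g[, 2] - 4) + abs(g[, 3] - 4) <= 2))
  expect_equal(sum(d2), 25)
  corner <- array(FALSE, c(4, 4, 4)); corner[1, 1, 1] <- TRUE
  expect_equal(sum(dilate_mask(corner, 1)), 4)
  expect_identical(dilate_mask(m, 0), m)
  expect_true(all(d2[dilate_mask(m, 1)]))  # monotone growth
  expect_error(dilate_mask(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("gaze generator injects saccades only when direction-locked", {
  spec <- small_spec(seed = 10, blocks = 1, n_runs = 1)
  ev <- generate_events(spec)
  quiet <- generate_gaze(ev, seed = 1)
  expect_equal(nrow(attr(quiet, "saccade_log")), 0)
  locked <- generate_gaze(ev, direction_lock = c("1" = 0, "2" = 90,
                                                 "3" = 180, "4" = 270),
                          kappa = 200, seed = 1)
  log <- attr(locked, "saccade_log")
  expect_equal(nrow(log), 4)
  ang <- log$angle_deg[order(log$trial)]
  target <- c(0, 90, 180, 270)[ev$condition]
  err <- abs((ang - target + 180) %% 360 - 180)
  expect_true(all(err < 15))  # von Mises kappa=200 ~ sd 4 deg
})

test_that("gaze traces are seeded and rates validated", {
  spec <- small_spec(seed = 12, blocks = 1, n_runs = 1)
  ev <- generate_events(spec)
  expect_identical(generate_gaze(ev, seed = 3), generate_gaze(ev, seed = 3))
  expect_error(generate_gaze(ev, blink_rate_hz = -1), "rates")
  tt <- generate_gaze(ev, seed = 3)$time
  expect_true(all(diff(tt) > 0))
  expect_equal(max(abs(diff(tt) - 1 / 60)), 0, tolerance = 1e-9)
})

test_that("blink simulation drops the pupil aspect ratio with gaze dropout", {
  spec <- small_spec(seed = 13, blocks = 2, n_runs = 1)
  ev <- generate_events(spec)
  gz <- generate_gaze(ev, blink_rate_hz = 0.2, seed = 13)
  blink <- gz$par < 0.5
  expect_gt(sum(blink), 0)
  expect_true(all(is.na(gz$x[blink])))
})
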