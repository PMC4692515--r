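#' Remove blink samples from a gaze recording
#'
#' Per trial, discards samples whose pupil aspect ratio lies outside
#' mean +/- 2 SD of that trial (and samples with missing gaze). Trials
#' losing every sample are flagged for downstream exclusion.
#'
#' @param gaze A `gaze_recording` (columns `time,x,y,par,trial,condition`).
#' @return Cleaned `gaze_recording` with attributes `retention` (per-trial
#'   kept fraction) and `dropped_trials`.
#' @export
remove_blinks <- function(gaze) {
  keep <- rep(TRUE, nrow(gaze))
  trials <- setdiff(unique(gaze$trial), 0L)
  retention <- numeric(0)
  for (tr in trials) {
    idx <- which(gaze$trial == tr)
    par <- gaze$par[idx]
    m <- mean(par); s <- stats::sd(par)
    ok <- abs(par - m) <= 2 * s + 1e-12
    ok <- ok & is.finite(gaze$x[idx]) & is.finite(gaze$y[idx])
    keep[idx] <- ok
    retention[as.character(tr)] <- mean(ok)
  }
  out <- gaze[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            sampling_rate_hz = attr(gaze, "sampling_rate_hz"),
            retention = retention,
            dropped_trials = as.integer(names(retention)[retention == 0]),
            class = class(gaze))
}

#' Detect saccades with a velocity-threshold algorithm
#'
#' Per trial: velocities from the 5-sample moving-window differentiator
#' v_i = (p_\{i+2\} + p_\{i+1\} - p_\{i-1\} - p_\{i-2\}) / (6 dt) per axis;
#' a robust (median-based) SD per axis sets an elliptic threshold at
#' `lambda` multiples; samples exceeding it for at least
#' `min_duration_samples` form a saccade. Direction comes from the net
#' displacement between onset and offset, as atan2(dy, dx) in [0, 360).
#'
#' @param gaze A cleaned `gaze_recording`.
#' @param lambda Velocity threshold multiplier (default 6).
#' @param min_duration_samples Minimum over-threshold run length.
#' @param sampling_rate_hz Overrides the recording's sampling rate.
#' @return Data frame of saccade events: `trial`, `condition`,
#'   `onset_index`, `offset_index` (row indices into `gaze`),
#'   `amplitude_deg`, `direction_deg`.
#' @export
detect_saccades <- function(gaze, lambda = 6, min_duration_samples = 3,
                            sampling_rate_hz = attr(gaze, "sampling_rate_hz")) {
  if (lambda <= 0) stop("lambda must be positive")
  dt <- 1 / sampling_rate_hz
  events <- list()
  for (tr in setdiff(unique(gaze$trial), 0L)) {
    idx <- which(gaze$trial == tr)
    n <- length(idx)
    if (n < 5L) next
    x <- gaze$x[idx]; y <- gaze$y[idx]
    vx <- moving_velocity(x, dt)
    vy <- moving_velocity(y, dt)
    sx <- robust_sd(vx); sy <- robust_sd(vy)
    if (sx == 0 || sy == 0) stop("degenerate gaze trace in trial ", tr)
    over <- (vx / (lambda * sx))^2 + (vy / (lambda * sy))^2 > 1
    over[is.na(over)] <- FALSE
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_duration_samples)) {
      a <- starts[j]; b <- ends[j]
      dx <- x[b] - x[a]; dy <- y[b] - y[a]
      events[[length(events) + 1L]] <- data.frame(
        trial = tr, condition = gaze$condition[idx[a]],
        onset_index = idx[a], offset_index = idx[b],
        amplitude_deg = sqrt(dx^2 + dy^2),
        direction_deg = (atan2(dy, dx) * 180 / pi) %% 360)
    }
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(trial = integer(), condition = integer(),
                  onset_index = integer(), offset_index = integer(),
                  amplitude_deg = numeric(), direction_deg = numeric())
}

# 5-sample moving-window velocity estimate; NA at the 2-sample borders
moving_velocity <- function(p, dt) {
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 5L) {
    i <- 3:(n - 2L)
    v[i] <- (p[i + 2L] + p[i + 1L] - p[i - 1L] - p[i - 2L]) / (6 * dt)
  }
  v
}

robust_sd <- function(v) {
  v <- v[is.finite(v)]
  sqrt(stats::median(v^2) - stats::median(v)^2)
}

## ---- circular statistics -------------------------------------------------

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# circular median direction (radians): candidate datum minimizing the mean
# absolute circular deviation; ties resolved towards the first candidate.
circ_median <- function(a) {
  dev <- vapply(a, function(m) mean(pi - abs(pi - abs(a - m) %% (2 * pi))),
                numeric(1L))
  a[which.min(dev)]
}

# signed circular distance in (-pi, pi]
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Common-median test for several groups of angles
#'
#' Non-parametric multi-sample test of equal median directions (Fisher's
#' common-median test): the pooled circular median splits the circle into
#' two half-planes; per-group counts on the negative side feed a
#' chi-square-type statistic P with #groups - 1 degrees of freedom. All
#' angles identical is degenerate and reports p = 1.
#'
#' @param angles Angles in degrees.
#' @param groups Group label per angle.
#' @return A `circ_test` list: `statistic_name` ("P"), `statistic_value`,
#'   `df`, `p_value`, `n` per group.
#' @export
circ_median_test <- function(angles, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 angles")
  a <- deg2rad(angles %% 360)
  ns <- as.integer(table(groups))
  N <- length(a)
  if (max(abs(circ_dist(a, a[1L]))) < 1e-12)
    return(structure(list(statistic_name = "P", statistic_value = 0,
                          df = nlevels(groups) - 1L, p_value = 1, n = ns,
                          degenerate = TRUE), class = "circ_test"))
  med <- circ_median(a)
  below <- circ_dist(a, med) < 0
  m <- as.integer(tapply(below, groups, sum))
  M <- sum(m)
  if (M == 0L || M == N)
    return(structure(list(statistic_name = "P", statistic_value = 0,
                          df = nlevels(groups) - 1L, p_value = 1, n = ns,
                          degenerate = TRUE), class = "circ_test"))
  P <- N^2 / (M * (N - M)) * sum(m^2 / ns) - N * M / (N - M)
  structure(list(statistic_name = "P", statistic_value = P,
                 df = nlevels(groups) - 1L,
                 p_value = stats::pchisq(P, nlevels(groups) - 1L,
                                         lower.tail = FALSE),
                 n = ns, degenerate = FALSE), class = "circ_test")
}

#' Circular-circular correlation
#'
#' Jammalamadaka-SenGupta correlation between two angle samples:
#' r = sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2 sum sin^2) with
#' circular mean directions abar, bbar, and the standard large-sample
#' normal test.
#'
#' @param a,b Paired angles in degrees.
#' @return A `circ_test` list with `statistic_name` "r".
#' @export
circ_corr <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples required")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  ar <- deg2rad(a); br <- deg2rad(b)
  abar <- atan2(mean(sin(ar)), mean(cos(ar)))
  bbar <- atan2(mean(sin(br)), mean(cos(br)))
  sa <- sin(ar - abar); sb <- sin(br - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0)
    return(structure(list(statistic_name = "r", statistic_value = NA_real_,
                          p_value = NA_real_, n = n, degenerate = TRUE),
                     class = "circ_test"))
  r <- sum(sa * sb) / den
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * r
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic_name = "r", statistic_value = r, p_value = p,
                 n = n, degenerate = FALSE), class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (n = %s)\n", x$statistic_name,
              x$statistic_value, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Minimum-volume enclosing ellipse of 2D points
#'
#' Khachiyan's iterative weight-update algorithm on the lifted point set,
#' run until the relative weight change falls below `tolerance`. The
#' returned ellipse is inflated (at most marginally) so that every input
#' point is contained within a 1e-6 relative tolerance.
#'
#' @param x,y Point coordinates (one trial's gaze samples), or `x` a
#'   two-column matrix.
#' @param tolerance Convergence tolerance on the weight update.
#' @return An `ellipse_fit` list: `center` (x, y), `semi_axes` (a >= b),
#'   `rotation_deg` (axial angle of the major axis in [0, 180)), `area`,
#'   and the shape matrix `A` with (p - c)' A (p - c) <= 1.
#' @export
fit_mvee <- function(x, y = NULL, tolerance = 1e-4) {
  P <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  storage.mode(P) <- "double"
  P <- P[stats::complete.cases(P), , drop = FALSE]
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 points")
  if (abs(stats::sd(P[, 1L])) < 1e-12 || abs(stats::sd(P[, 2L])) < 1e-12 ||
      qr(sweep(P, 2L, colMeans(P)))$rank < 2L)
    stop("degenerate geometry: points are collinear")
  d <- 2L
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(1000L)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    u_new <- (1 - step) * u
    u_new[j] <- u_new[j] + step
    if (sqrt(sum((u_new - u)^2)) < tolerance) { u <- u_new; break }
    u <- u_new
  }
  ctr <- drop(crossprod(P, u))
  A <- solve(crossprod(P, u * P) - tcrossprod(ctr)) / d
  # guarantee containment: inflate by the worst-case point
  dev <- sweep(P, 2L, ctr)
  scale_fix <- max(rowSums((dev %*% A) * dev))
  if (scale_fix > 1) A <- A / (scale_fix * (1 + 1e-9))
  eg <- eigen(A, symmetric = TRUE)
  semi <- rev(1 / sqrt(eg$values))          # a >= b
  major <- eg$vectors[, which.min(eg$values)]
  rot <- (atan2(major[2L], major[1L]) * 180 / pi) %% 180
  structure(list(center = ctr, semi_axes = semi, rotation_deg = rot,
                 area = pi * semi[1L] * semi[2L], A = A, n = n),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "MVEE: center (%.3f, %.3f), semi-axes (%.3f, %.3f), rotation %.1f deg\n",
    x$center[1L], x$center[2L], x$semi_axes[1L], x$semi_axes[2L],
    x$rotation_deg))
  invisible(x)
}

#' Tests on gaze-ellipse rotations across trials
#'
#' Ellipse rotation is axial (180 degree periodic), so angles are doubled
#' before the common-median test across imagined directions and the
#' circular-circular correlation with the imagined direction angles;
#' results are reported on the doubled scale.
#'
#' @param rotations_deg Per-trial ellipse rotations in [0, 180).
#' @param conditions Per-trial condition labels.
#' @param condition_angles_deg Named map from condition label to imagined
#'   direction angle (degrees); required for the correlation.
#' @return List of two `circ_test` results: `median_test`, `correlation`.
#' @export
ellipse_rotation_tests <- function(rotations_deg, conditions,
                                   condition_angles_deg = NULL) {
  if (any(table(conditions) < 2L)) stop("need at least 2 trials per condition")
  doubled <- (2 * rotations_deg) %% 360
  med <- circ_median_test(doubled, conditions)
  corr <- NULL
  if (!is.null(condition_angles_deg)) {
    ang <- condition_angles_deg[as.character(conditions)]
    corr <- circ_corr(doubled, ang)
  }
  list(median_test = med, correlation = corr)
}
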