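# Shared fixtures and independent oracles, built in code at test time.

# small paradigm: 4 runs x `blocks` blocks x 4 trials
small_spec <- function(seed = 1, blocks = 3, n_runs = 4) {
  paradigm_spec(blocks_per_run = blocks, n_runs = n_runs, seed = seed)
}

# ground truth with `n_inf` voxels tuned in condition pairs: voxel v is
# driven with `amp` by condition (v - 1) %/% (n_inf / 4) + 1
tuned_truth <- function(shape, n_inf = 8, amp = 5, noise_sd = 1,
                        drift = 0, seed = 1) {
  stopifnot(n_inf %% 4 == 0)
  iv <- linear_to_grid_oracle(seq_len(n_inf), shape)
  A <- matrix(0, 4, n_inf)
  per <- n_inf / 4
  for (cc in 1:4) A[cc, ((cc - 1) * per + 1):(cc * per)] <- amp
  ground_truth(iv, amplitudes = A, noise_sd = noise_sd,
               drift_amplitude = drift, seed = seed)
}

# independent linear-index -> 0-based (i,j,k), by explicit arithmetic
linear_to_grid_oracle <- function(lin, shape) {
  t(vapply(lin, function(l) {
    l0 <- l - 1L
    c(l0 %% shape[1], (l0 %/% shape[1]) %% shape[2],
      l0 %/% (shape[1] * shape[2]))
  }, numeric(3)))
}

# features from a freshly simulated dataset
sim_features <- function(spec, shape = c(4, 4, 4), truth = NULL) {
  ev <- generate_events(spec)
  if (is.null(truth)) truth <- ground_truth(noise_sd = 1, seed = spec$seed)
  bold <- generate_bold(ev, truth, shape)
  list(events = ev,
       features = extract_trial_features(preprocess_runs(bold), ev),
       bold = bold)
}

# direct O(n^2) discrete convolution oracle, truncated to length(u)
conv_oracle <- function(u, h) {
  n <- length(u)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_len(min(t, length(h))))
      out[t] <- out[t] + h[j] * u[t - j + 1]
  out
}

# brute-force lattice sphere count via triple loop
sphere_count_oracle <- function(r) {
  cnt <- 0L
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if (x * x + y * y + z * z <= r * r) cnt <- cnt + 1L
  cnt
}

# Wilcoxon signed-rank two-sided p by literal enumeration of sign patterns
wsr_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- apply(signs, 1, function(s) min(sum(r[s == 1]), sum(r[s == 0])))
  mean(w_all <= w_obs + 1e-9)
}

# Mann-Whitney U two-sided p by literal enumeration of group assignments
mwu_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_obs <- min(ua, na * nb - ua)
  splits <- utils::combn(na + nb, na)
  u_all <- apply(splits, 2, function(ix) {
    uu <- sum(r[ix]) - na * (na + 1) / 2
    min(uu, na * nb - uu)
  })
  mean(u_all <= u_obs + 1e-9)
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# smallest enclosing-ellipse area over a coarse parameter grid
mvee_grid_oracle <- function(P, n_grid = 15) {
  cx <- seq(min(P[, 1]), max(P[, 1]), length.out = n_grid)
  cy <- seq(min(P[, 2]), max(P[, 2]), length.out = n_grid)
  span <- max(dist(P))
  axes <- seq(span / 4, span, length.out = n_grid)
  angs <- seq(0, pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best <- Inf
  for (x0 in cx) for (y0 in cy) for (a in axes) for (b in axes) {
    if (b > a) next
    for (th in angs) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      Q <- sweep(P, 2, c(x0, y0)) %*% R
      if (all((Q[, 1] / a)^2 + (Q[, 2] / b)^2 <= 1 + 1e-9)) {
        ar <- pi * a * b
        if (ar < best) best <- ar
      }
    }
  }
  best
}
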