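#' High-pass filter run time courses with a GLM Fourier basis
#'
#' Per voxel, fits ordinary least squares on a basis of intercept, linear
#' trend, and sine/cosine pairs at 1..`n_cycles` cycles per run, and
#' returns the residuals with the run mean restored. With the default two
#' cycles this removes offsets, linear drift and fluctuations at or below
#' two cycles per run.
#'
#' @param Y Time x voxel matrix for one run.
#' @param n_cycles Highest Fourier pair, cycles per run (default 2).
#' @return Filtered matrix of the same shape.
#' @export
highpass_fourier <- function(Y, n_cycles = 2) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2 * (2 * n_cycles + 2))
    stop("run too short (", n, " volumes) for a ", n_cycles, "-cycle basis")
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  for (k in seq_len(n_cycles))
    X <- cbind(X, sin(2 * pi * k * (tt - 1) / n), cos(2 * pi * k * (tt - 1) / n))
  res <- qr.resid(qr(X), Y)
  sweep(res, 2L, colMeans(Y), `+`)
}

#' Z-score run time courses
#'
#' Per voxel and per run: subtract the temporal mean and divide by the
#' temporal population standard deviation (denominator N). Constant voxels
#' map to all-zeros and are flagged in the `constant_voxels` attribute.
#'
#' @param Y Time x voxel matrix for one run.
#' @return Standardized matrix; attribute `constant_voxels` marks columns
#'   with zero variance.
#' @export
zscore_run <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 volumes per run")
  mu <- colMeans(Y)
  ctr <- sweep(Y, 2L, mu)
  sd_pop <- sqrt(colMeans(ctr^2))
  const <- sd_pop == 0
  sd_pop[const] <- 1
  out <- sweep(ctr, 2L, sd_pop, `/`)
  out[, const] <- 0
  structure(out, constant_voxels = which(const))
}

#' Preprocess simulated or loaded runs
#'
#' Applies the standard order filter -> z-score per run and flattens each
#' run to a time x voxel matrix (optionally restricted to a mask).
#'
#' @param bold A `bold_sim` object or a list of 4D arrays.
#' @param mask Optional 3D logical array selecting voxels.
#' @param n_cycles High-pass filter cycles per run; `0` skips filtering.
#' @param zscore Apply run-wise z-scoring?
#' @return A `preprocessed_runs` object: `runs` (list of time x voxel
#'   matrices), `voxel_index` (1-based linear grid indices of columns),
#'   `shape`, `tr_s`.
#' @export
preprocess_runs <- function(bold, mask = NULL, n_cycles = 2, zscore = TRUE) {
  if (inherits(bold, "bold_sim")) {
    runs <- bold$runs; tr_s <- bold$tr_s; shape <- bold$shape
  } else {
    runs <- bold
    shape <- dim(runs[[1]])[1:3]
    tr_s <- attr(bold, "tr_s")
    if (is.null(tr_s)) tr_s <- 2
  }
  vox <- if (is.null(mask)) seq_len(prod(shape)) else {
    stopifnot(all(dim(mask) == shape))
    which(mask)
  }
  mats <- lapply(runs, function(a) {
    nv <- dim(a)[4L]
    m <- t(matrix(a, prod(shape), nv)[vox, , drop = FALSE])
    if (n_cycles > 0) m <- highpass_fourier(m, n_cycles)
    if (zscore) m <- zscore_run(m)
    m
  })
  structure(list(runs = mats, voxel_index = vox, shape = shape, tr_s = tr_s),
            class = "preprocessed_runs")
}

#' Extract trial features from preprocessed runs
#'
#' For every trial and voxel, averages the volumes whose onset-relative
#' acquisition time t (volume k acquired at k*TR, 0-based) satisfies
#' `window[1] <= t < window[2]`. With the default half-open window of
#' 4 to 10 s at TR = 2 s this averages exactly the 3 volumes at 4, 6 and
#' 8 s after onset. Onsets off the volume grid are rounded to the nearest
#' volume.
#'
#' @param pre A [preprocess_runs()] result (or a `bold_sim`, which is then
#'   preprocessed with defaults).
#' @param events An `event_table`; rows map one-to-one to feature rows in
#'   the given order.
#' @param window Onset-relative half-open time window in seconds.
#' @return A `trial_features` object: `values` (trials x voxels), `labels`,
#'   `runs`, `voxel_index`, `shape`.
#' @export
extract_trial_features <- function(pre, events, window = c(4, 10)) {
  if (inherits(pre, "bold_sim")) pre <- preprocess_runs(pre)
  stopifnot(inherits(pre, "preprocessed_runs"))
  tr <- pre$tr_s
  run_ids <- sort(unique(events$run))
  if (length(run_ids) != length(pre$runs))
    stop("event table and data disagree on the number of runs")
  n_trials <- nrow(events)
  vals <- matrix(NA_real_, n_trials, ncol(pre$runs[[1]]))
  for (i in seq_len(n_trials)) {
    ri <- match(events$run[i], run_ids)
    m <- pre$runs[[ri]]
    onset_vol <- round(events$onset[i] / tr)
    k <- ceiling((window[1] - 1e-9) / tr):floor((window[2] - 1e-9) / tr)
    k <- k[k * tr >= window[1] - 1e-9 & k * tr < window[2] - 1e-9]
    idx <- onset_vol + k + 1L  # 1-based volume indices
    if (any(idx > nrow(m)) || any(idx < 1L))
      stop("feature window for trial ", i, " (run ", events$run[i],
           ", onset ", events$onset[i], " s) lies outside the run")
    vals[i, ] <- colMeans(m[idx, , drop = FALSE])
  }
  if (any(!is.finite(vals))) stop("non-finite feature values")
  structure(list(values = vals, labels = as.integer(events$condition),
                 runs = as.integer(events$run), voxel_index = pre$voxel_index,
                 shape = pre$shape),
            class = "trial_features")
}

#' @export
print.trial_features <- function(x, ...) {
  cat("Trial feature matrix:", nrow(x$values), "trials x", ncol(x$values),
      "voxels;", length(unique(x$labels)), "conditions,",
      length(unique(x$runs)), "runs\n")
  invisible(x)
}

# column subset of a trial_features object
subset_features <- function(feat, cols) {
  structure(list(values = feat$values[, cols, drop = FALSE],
                 labels = feat$labels, runs = feat$runs,
                 voxel_index = feat$voxel_index[cols], shape = feat$shape),
            class = "trial_features")
}

#' Write a trial feature matrix as a tabular audit file
#'
#' Tab-separated: `label`, `run`, then one column per voxel (named by its
#' 1-based linear grid index).
#'
#' @param feat A `trial_features` object.
#' @param path File path.
#' @export
write_features <- function(feat, path) {
  df <- data.frame(label = feat$labels, run = feat$runs,
                   feat$values, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("v", feat$voxel_index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
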