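#' Specify ground truth for the BOLD simulator
#'
#' @param informative_voxels Integer matrix (n x 3) of 0-based grid indices
#'   of direction-coding voxels, or `NULL` for none.
#' @param amplitudes Condition x voxel matrix of response amplitudes
#'   (signal units); rows indexed by the paradigm's conditions. A single
#'   number is recycled.
#' @param noise_sd Gaussian noise standard deviation (signal units, >= 0).
#' @param drift_amplitude Amplitude of a one-cycle-per-run cosine drift.
#' @param baseline Constant signal offset.
#' @param seed Integer seed for the noise substream.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(informative_voxels = NULL, amplitudes = NULL,
                         noise_sd = 1, drift_amplitude = 0,
                         baseline = 100, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(informative_voxels)) {
    informative_voxels <- matrix(as.integer(informative_voxels), ncol = 3L)
    if (is.null(amplitudes)) stop("amplitudes required with informative voxels")
    if (!is.matrix(amplitudes))
      amplitudes <- matrix(amplitudes, nrow = if (length(amplitudes) > 1)
        length(amplitudes) else 4L, ncol = nrow(informative_voxels))
    if (ncol(amplitudes) != nrow(informative_voxels))
      stop("one amplitude column per informative voxel required")
  }
  structure(list(informative_voxels = informative_voxels,
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, baseline = baseline,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate a 4D BOLD dataset from events and ground truth
#'
#' Forward model: each voxel's time course is
#' `baseline + sum_c amplitude(c, voxel) * x_c(t) + drift + noise`, where
#' `x_c` is the condition-c trial boxcar convolved with the canonical
#' two-gamma hemodynamic response, drift is one cosine cycle per run scaled
#' by `drift_amplitude`, and noise is iid Gaussian. Non-informative voxels
#' receive baseline, drift and noise only.
#'
#' @param events An `event_table`.
#' @param truth A [ground_truth()].
#' @param shape 3D grid dimensions, e.g. `c(6, 6, 6)`.
#' @param tr_s Repetition time (defaults to the event table's).
#' @return A `bold_sim` object: `runs` (list of 4D arrays `i,j,k,t`),
#'   `tr_s`, `voxel_size_mm`, `shape`, plus the events and truth used.
#' @export
generate_bold <- function(events, truth, shape, tr_s = attr(events, "tr_s"),
                          voxel_size_mm = 1.1) {
  if (nrow(events) == 0L) stop("empty event table")
  stopifnot(inherits(truth, "ground_truth"), length(shape) == 3L)
  shape <- as.integer(shape)
  inf_lin <- NULL
  if (!is.null(truth$informative_voxels)) {
    iv <- truth$informative_voxels
    if (any(iv < 0L) || any(iv >= matrix(shape, nrow(iv), 3L, byrow = TRUE)))
      stop("informative voxels outside grid")
    inf_lin <- grid_to_linear(iv, shape)
  }
  conds <- sort(unique(events$condition))
  n_volumes <- events_n_volumes(events, tr_s)
  runs <- sort(unique(events$run))
  nvox <- prod(shape)
  hrf <- two_gamma_hrf(seq(0, 32, by = tr_s))
  out <- vector("list", length(runs))
  with_seed(derive_seed(truth$seed, "bold_noise"), {
    for (ri in seq_along(runs)) {
      nv <- n_volumes[ri]
      e <- events[events$run == runs[ri], , drop = FALSE]
      # regressors: nv x conditions
      reg <- matrix(0, nv, length(conds))
      tvol <- (seq_len(nv) - 1L) * tr_s
      for (ci in seq_along(conds)) {
        u <- numeric(nv)
        rows <- e[e$condition == conds[ci], , drop = FALSE]
        for (j in seq_len(nrow(rows)))
          u[tvol >= rows$onset[j] - 1e-9 &
              tvol < rows$onset[j] + rows$duration[j] - 1e-9] <- 1
        reg[, ci] <- convolve_truncate(u, hrf)
      }
      drift <- truth$drift_amplitude * cos(2 * pi * (seq_len(nv) - 1L) / nv)
      mat <- matrix(truth$baseline + rep(drift, nvox), nvox, nv, byrow = TRUE)
      if (truth$noise_sd > 0)
        mat <- mat + matrix(stats::rnorm(nvox * nv, sd = truth$noise_sd), nvox, nv)
      if (!is.null(inf_lin)) {
        amp <- truth$amplitudes[seq_along(conds), , drop = FALSE]
        mat[inf_lin, ] <- mat[inf_lin, ] + t(reg %*% amp)
      }
      out[[ri]] <- array(mat, c(shape, nv))
    }
  })
  structure(list(runs = out, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 shape = shape, events = events, truth = truth),
            class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat("Synthetic BOLD dataset:", length(x$runs), "runs, grid",
      paste(x$shape, collapse = "x"), ", TR =", x$tr_s, "s, voxel",
      x$voxel_size_mm, "mm\n")
  invisible(x)
}

#' Dilate a volumetric mask by face adjacency
#'
#' Each of `n_fold` iterations adds every voxel that shares a face
#' (6-connectivity) with the current mask, clipped at the grid borders.
#' `n_fold = 0` returns the input unchanged.
#'
#' @param mask 3D logical array.
#' @param n_fold Number of dilation iterations (>= 0).
#' @return 3D logical array of the same shape.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' sum(dilate_mask(m, 1))  # 7
#' @export
dilate_mask <- function(mask, n_fold) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!is_count(n_fold)) stop("n_fold must be a non-negative integer")
  if (!any(mask)) stop("empty mask")
  m <- mask
  d <- dim(m)
  for (i in seq_len(n_fold)) {
    grown <- m
    grown[-1, , ] <- grown[-1, , ] | m[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | m[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | m[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | m[, -1, ]
    grown[, , -1] <- grown[, , -1] | m[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | m[, , -1]
    m <- grown
  }
  m
}

#' Write / read a 3D or 4D volume as NIfTI
#'
#' Volumes are stored with a diagonal affine at the given isotropic voxel
#' size (and TR in the 4th pixdim slot for 4D data).
#'
#' @param vol 3D/4D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel edge length.
#' @param tr_s Repetition time for 4D data.
#' @return `read_volume` returns the array (with `pixdim` attribute);
#'   `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 1.1, tr_s = 2) {
  img <- RNifti::asNifti(vol * 1)
  pd <- if (length(dim(vol)) == 4L) c(rep(voxel_size_mm, 3L), tr_s)
        else rep(voxel_size_mm, 3L)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}
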