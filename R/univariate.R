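#' Canonical two-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical parameter set:
#' response peak delay 6 s, undershoot delay 16 s, both with dispersion
#' 1 s, and a peak-to-undershoot ratio of 6. The curve is normalized so
#' that its maximum (evaluated on a fine grid) equals 1; the empirical
#' peak falls near 5 s.
#'
#' @param t Times in seconds (>= 0 where the response is defined; negative
#'   times return 0).
#' @param peak_delay,under_delay Gamma delays (shape x dispersion), seconds.
#' @param peak_disp,under_disp Gamma dispersions (scale), seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Amplitudes, dimensionless, max-normalized to 1.
#' @examples
#' two_gamma_hrf(c(0, 5, 16, 30))
#' @export
two_gamma_hrf <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 6) {
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt >= 0
    out[pos] <- stats::dgamma(tt[pos], shape = peak_delay / peak_disp,
                              scale = peak_disp) -
      stats::dgamma(tt[pos], shape = under_delay / under_disp,
                    scale = under_disp) / ratio
    out
  }
  peak <- max(raw(seq(0, 32, by = 0.01)))
  raw(t) / peak
}

#' Build a GLM design matrix from an event table
#'
#' One predictor per condition: a unit boxcar over each trial's duration,
#' sampled at the TR grid and discretely convolved with [two_gamma_hrf()].
#' Runs are concatenated; a per-run intercept column is always included and
#' per-run linear drift columns optionally. The design is checked for full
#' column rank.
#'
#' @param events An `event_table`.
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Integer vector of volumes per run (defaults to the
#'   event table's metadata).
#' @param drift Add a per-run linear trend column?
#' @param hrf Impulse response sampled at multiples of `tr_s`; defaults to
#'   the canonical two-gamma evaluated on a 0..32 s support.
#' @param conditions Condition labels expected in the design (defaults to
#'   the labels carried by the event table); a condition with no trials
#'   yields an all-zero predictor and a rank-deficiency error.
#' @return A numeric matrix with attributes `condition_cols` (named column
#'   indices of the condition predictors), `run` (run index per row) and
#'   `tr_s`.
#' @export
build_design <- function(events, tr_s = attr(events, "tr_s"),
                         n_volumes = events_n_volumes(events, tr_s),
                         drift = FALSE, hrf = NULL, conditions = NULL) {
  ang <- attr(events, "condition_angles_deg")
  conds <- if (!is.null(conditions)) sort(conditions)
           else if (!is.null(ang)) sort(as.integer(names(ang)))
           else sort(unique(events$condition))
  if (is.null(hrf)) hrf <- two_gamma_hrf(seq(0, 32, by = tr_s))
  runs <- sort(unique(events$run))
  if (length(n_volumes) != length(runs))
    stop("n_volumes must give one volume count per run")
  blocks <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    nv <- n_volumes[ri]
    e <- events[events$run == runs[ri], ]
    X <- matrix(0, nv, length(conds))
    tvol <- (seq_len(nv) - 1L) * tr_s
    for (ci in seq_along(conds)) {
      u <- numeric(nv)
      tr_rows <- e[e$condition == conds[ci], , drop = FALSE]
      for (j in seq_len(nrow(tr_rows))) {
        on <- tr_rows$onset[j]
        if (on + tr_rows$duration[j] > nv * tr_s + 1e-9)
          stop("trial at onset ", on, " s (run ", runs[ri],
               ") extends past the run")
        u[tvol >= on - 1e-9 & tvol < on + tr_rows$duration[j] - 1e-9] <- 1
      }
      X[, ci] <- convolve_truncate(u, hrf)
    }
    blocks[[ri]] <- X
  }
  Xc <- do.call(rbind, blocks)
  run_of_row <- rep(runs, n_volumes)
  intercepts <- outer(run_of_row, runs, `==`) * 1
  colnames(intercepts) <- paste0("run", runs)
  extra <- intercepts
  if (drift) {
    dr <- matrix(0, nrow(Xc), length(runs))
    for (ri in seq_along(runs)) {
      idx <- which(run_of_row == runs[ri])
      dr[idx, ri] <- seq_along(idx) - mean(seq_along(idx))
    }
    colnames(dr) <- paste0("drift", runs)
    extra <- cbind(intercepts, dr)
  }
  X <- cbind(Xc, extra)
  colnames(X)[seq_along(conds)] <- paste0("cond", conds)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (empty condition predictor?)")
  structure(X, condition_cols = stats::setNames(seq_along(conds), conds),
            run = run_of_row, tr_s = tr_s)
}

# discrete causal convolution truncated to the input length
convolve_truncate <- function(u, h) {
  n <- length(u)
  out <- numeric(n)
  for (j in seq_along(h)) {
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + h[j] * u[idx]
  }
  out
}

#' Fit a voxel-wise ordinary least squares GLM
#'
#' @param Y Time x voxel data matrix (runs concatenated to match `design`).
#' @param design Design matrix from [build_design()].
#' @return A `glm_fit` object: `beta` (coefficients x voxels), `sigma2`
#'   (residual variance per voxel), `dof`, and the design's QR
#'   decomposition for downstream contrasts.
#' @export
fit_glm <- function(Y, design) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("non-finite values in data")
  if (nrow(Y) != nrow(design)) stop("data and design row mismatch")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  dof <- nrow(Y) - qrX$rank
  sigma2 <- colSums(res^2) / dof
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 design = design, qr = qrX,
                 xtx_inv = chol2inv(qr.R(qrX))),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Voxel-wise GLM fit:", ncol(x$beta), "voxels,",
      nrow(x$design), "volumes,", x$dof, "residual dof\n")
  invisible(x)
}

#' One-vs-all condition contrast t-map
#'
#' Contrast weights are +1 on the tested condition and -1/3 on each of the
#' other three (zero-sum), so a voxel responding equally to all conditions
#' scores t near 0.
#'
#' @param fit A [fit_glm()] result.
#' @param condition Condition label to test against the rest.
#' @return Numeric vector of t-values, one per voxel; voxels with zero
#'   residual variance are flagged `Inf` (sign of the contrast estimate).
#' @export
contrast_t <- function(fit, condition) {
  cc <- attr(fit$design, "condition_cols")
  if (is.null(cc) || length(cc) < 2L) stop("design lacks condition columns")
  w <- numeric(ncol(fit$design))
  ci <- cc[as.character(condition)]
  if (is.na(ci)) stop("unknown condition ", condition)
  w[cc] <- -1 / (length(cc) - 1)
  w[ci] <- 1
  est <- drop(crossprod(w, fit$beta))
  se2 <- fit$sigma2 * drop(crossprod(w, fit$xtx_inv %*% w))
  t <- ifelse(se2 > 0, est / sqrt(se2), sign(est) * Inf)
  t
}

#' FDR-threshold a t-map
#'
#' Two-sided p-values from the t distribution, Benjamini-Hochberg adjusted
#' across voxels; the mask is true where adjusted p < `q`.
#'
#' @param t Vector of t-values.
#' @param dof Residual degrees of freedom.
#' @param q FDR level (default 0.05).
#' @return Logical vector: significant voxels.
#' @export
fdr_threshold_t <- function(t, dof, q = 0.05) {
  if (dof <= 0) stop("dof must be positive")
  p <- 2 * stats::pt(-abs(t), df = dof)
  stats::p.adjust(p, method = "BH") < q
}

#' Direction preference map
#'
#' Within a significance mask, labels each voxel with the condition whose
#' one-vs-all contrast t-value is largest (ties broken towards the lowest
#' label); voxels outside the mask are 0.
#'
#' @param tmaps Matrix of t-values, voxels x conditions (columns ordered by
#'   condition label).
#' @param sig_mask Logical vector, one entry per voxel.
#' @return Integer vector of preferred condition labels (0 outside mask).
#' @export
preference_map <- function(tmaps, sig_mask) {
  tmaps <- as.matrix(tmaps)
  if (nrow(tmaps) != length(sig_mask)) stop("t-map / mask shape mismatch")
  pref <- integer(nrow(tmaps))
  if (any(sig_mask))
    pref[sig_mask] <- max.col(tmaps[sig_mask, , drop = FALSE],
                              ties.method = "first")
  pref
}
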