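#' Integer voxel offsets of a searchlight sphere
#'
#' All integer (di, dj, dk) with squared Euclidean norm at most
#' `radius^2` (inclusive boundary, voxel units). Radius 4 gives the
#' 257-voxel feature set.
#'
#' @param radius_voxels Sphere radius in voxels (>= 0).
#' @return Integer matrix (n x 3) of offsets, including (0,0,0), with
#'   attribute `radius`.
#' @examples
#' nrow(sphere_offsets(4))  # 257
#' @export
sphere_offsets <- function(radius_voxels) {
  if (!is.numeric(radius_voxels) || radius_voxels < 0)
    stop("radius must be non-negative")
  r <- floor(radius_voxels)
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  off <- g[rowSums(g^2) <= radius_voxels^2 + 1e-9, , drop = FALSE]
  rownames(off) <- NULL
  structure(off, radius = radius_voxels)
}

#' Volumetric searchlight information mapping
#'
#' Moves a sphere through every voxel of the ribbon mask and, per center,
#' decodes the trial labels from the sphere's voxels (all in-volume voxels
#' at the sphere offsets; members need not lie in the ribbon, only the
#' center does, unless `strict`) with leave-one-run-out cross-validation,
#' no voxel pre-selection and no permutation testing. Each center's
#' pooled confusion matrix is tested with a chi-square test of
#' independence.
#'
#' @param pre A [preprocess_runs()] result covering the full volume.
#' @param events The `event_table`.
#' @param ribbon 3D logical array of allowed center voxels.
#' @param radius Sphere radius in voxels (default 4).
#' @param cost SVM soft-margin constant.
#' @param strict Restrict sphere members to the ribbon as well?
#' @param window Feature extraction window, seconds after trial onset.
#' @return A `searchlight_map`: 3D arrays `accuracy`, `chi2`, `p` (`NA`
#'   outside swept centers), `centers` (linear indices), and `confusions`
#'   (list of per-center confusion matrices).
#' @export
run_searchlight <- function(pre, events, ribbon, radius = 4, cost = 1,
                            strict = FALSE, window = c(4, 10)) {
  stopifnot(inherits(pre, "preprocessed_runs"))
  shape <- pre$shape
  stopifnot(all(dim(ribbon) == shape))
  if (!any(ribbon)) stop("empty ribbon mask")
  if (any(2 * radius + 1 > shape))
    stop("sphere diameter exceeds the volume")
  if (length(pre$voxel_index) != prod(shape))
    stop("searchlight needs full-volume preprocessed data")
  feats <- extract_trial_features(pre, events, window = window)
  off <- sphere_offsets(radius)
  centers <- which(ribbon)
  acc <- array(NA_real_, shape)
  chi2 <- array(NA_real_, shape)
  pmap <- array(NA_real_, shape)
  confusions <- vector("list", length(centers))
  allowed <- if (strict) ribbon else array(TRUE, shape)
  for (ci in seq_along(centers)) {
    ctr <- linear_to_grid(centers[ci], shape)
    vox <- sweep(off, 2L, as.integer(ctr), `+`)
    keep <- vox[, 1L] >= 0L & vox[, 1L] < shape[1L] &
      vox[, 2L] >= 0L & vox[, 2L] < shape[2L] &
      vox[, 3L] >= 0L & vox[, 3L] < shape[3L]
    lin <- grid_to_linear(vox[keep, , drop = FALSE], shape)
    lin <- lin[allowed[lin]]
    cv <- cross_validate(subset_features(feats, lin), k = NULL, cost = cost)
    acc[centers[ci]] <- cv$mean_accuracy
    ct <- chisq_confusion(cv$confusion)
    chi2[centers[ci]] <- ct$statistic
    pmap[centers[ci]] <- ct$p_value
    confusions[[ci]] <- cv$confusion
  }
  structure(list(accuracy = acc, chi2 = chi2, p = pmap,
                 centers = centers, confusions = confusions,
                 radius = radius, shape = shape),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat("Searchlight map: radius", x$radius, "voxels,", length(x$centers),
      "centers; accuracy range",
      sprintf("%.3f-%.3f", min(x$accuracy, na.rm = TRUE),
              max(x$accuracy, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Chi-square test of a decoding confusion matrix
#'
#' Pearson chi-square test of independence between true and predicted
#' labels. Expected counts come from the row/column margins; for the
#' 4-class design the degrees of freedom are fixed at 9 (cells with zero
#' expected count contribute 0, which occurs when a class is never
#' predicted).
#'
#' @param confusion Square count matrix, rows = true, columns = predicted.
#' @return List: `statistic`, `df`, `p_value`.
#' @examples
#' chisq_confusion(diag(10, 4))  # chi2 = 120, df = 9
#' @export
chisq_confusion <- function(confusion) {
  O <- as.matrix(confusion)
  n <- sum(O)
  if (n <= 0) stop("empty confusion matrix")
  rs <- rowSums(O)
  if (any(rs == 0)) stop("a class was never tested (zero row)")
  cs <- colSums(O)
  E <- outer(rs, cs) / n
  stat <- sum(ifelse(E > 0, (O - E)^2 / E, 0))
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' FDR-threshold a searchlight p map
#'
#' Benjamini-Hochberg step-up over all swept centers; the mask is true
#' where the adjusted p falls below `q`.
#'
#' @param p_map 3D array of p-values (`NA` outside centers) or a
#'   `searchlight_map`.
#' @param q FDR level.
#' @return 3D logical array (`FALSE` outside centers).
#' @export
fdr_mask <- function(p_map, q = 0.05) {
  if (inherits(p_map, "searchlight_map")) p_map <- p_map$p
  idx <- which(!is.na(p_map))
  if (length(idx) == 0L) stop("empty p map")
  adj <- stats::p.adjust(p_map[idx], method = "BH")
  out <- array(FALSE, dim(p_map))
  out[idx] <- adj < q
  out
}
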