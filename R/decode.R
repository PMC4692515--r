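#' Voxel-wise one-way ANOVA F scores
#'
#' Omnibus F per voxel: ratio of between-class to within-class variance of
#' the trial features across the condition labels. Voxels with zero
#' within-class variance (but non-zero between-class variance) score
#' `Inf` and rank above every finite score.
#'
#' @param values Trials x voxels matrix.
#' @param labels Condition label per trial.
#' @return Numeric vector of F values (one per voxel), with attribute
#'   `df` = c(between, within).
#' @examples
#' anova_f(matrix(c(0, 1, 2, 3)), c(1, 1, 2, 2))  # 8
#' @export
anova_f <- function(values, labels) {
  values <- as.matrix(values)
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 classes")
  if (any(counts < 2L)) stop("need at least 2 trials per class")
  n <- nrow(values)
  grand <- colMeans(values)
  group_sums <- rowsum(values, labels)
  group_means <- group_sums / as.integer(counts)
  ssb <- colSums(as.integer(counts) * (sweep(group_means, 2L, grand))^2)
  sst <- colSums(sweep(values, 2L, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- length(counts) - 1L
  df_w <- n - length(counts)
  f <- ifelse(ssw > 0, (ssb / df_b) / (ssw / df_w),
              ifelse(ssb > 0, Inf, 0))
  structure(f, df = c(between = df_b, within = df_w))
}

#' Select the top-k voxels by F score
#'
#' Ties at the cutoff are broken by ascending voxel (column) index, so the
#' selection is deterministic; infinite scores sort above all finite ones.
#'
#' @param f F score per voxel.
#' @param k Number of voxels to keep.
#' @return Integer column indices of the selected voxels (ascending order).
#' @export
select_top_k <- function(f, k) {
  if (!is_count(k, 1L)) stop("k must be a positive integer")
  if (length(f) < k)
    stop("only ", length(f), " voxels available; lower k (requested ", k, ")")
  o <- order(-f, seq_along(f))
  sort(o[seq_len(k)])
}

#' One-vs-one multiclass prediction with linear SVMs
#'
#' Fits one binary soft-margin linear support vector machine per class
#' pair (C(4,2) = 6 for four classes) on the training trials and predicts
#' each test trial by majority vote over the pairwise decisions. Vote ties
#' are broken towards the lowest class label.
#'
#' @param train_x,train_y Training features and labels.
#' @param test_x Test features (same columns as `train_x`).
#' @param cost Soft-margin regularization constant C.
#' @return Integer predicted labels; attribute `n_classifiers` records the
#'   number of binary problems.
#' @export
train_predict_ovo <- function(train_x, train_y, test_x, cost = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x))
    stop("train and test voxel sets differ")
  classes <- sort(unique(as.integer(train_y)))
  if (length(classes) < 2L) stop("need at least 2 classes in training data")
  pairs <- utils::combn(classes, 2L)
  votes <- matrix(0L, nrow(test_x), length(classes),
                  dimnames = list(NULL, classes))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    sel <- train_y %in% c(a, b)
    fit <- e1071::svm(train_x[sel, , drop = FALSE],
                      factor(train_y[sel], levels = c(a, b)),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- as.integer(as.character(predict(fit, test_x)))
    for (cl in c(a, b)) {
      col <- match(cl, classes)
      votes[pred == cl, col] <- votes[pred == cl, col] + 1L
    }
  }
  pred <- classes[vote_majority(votes)]
  structure(pred, n_classifiers = ncol(pairs))
}

# majority vote; ties towards the first (lowest-label) column
vote_majority <- function(votes) {
  max.col(votes, ties.method = "first")
}

#' Leave-one-run-out cross-validated decoding
#'
#' One fold per run. Within each fold, ANOVA-F feature scores and the
#' top-k selection are computed on the training trials only (no leakage),
#' then a one-vs-one linear SVM ensemble predicts the held-out run.
#'
#' @param features A `trial_features` object.
#' @param k Voxels to select per fold; `NULL` disables selection (all
#'   voxels used, as in searchlight spheres).
#' @param cost SVM soft-margin constant.
#' @param check_runs Require every run to contain every class (the
#'   precondition for observed data; scrambled-label reruns relax it to
#'   the training folds, which always need all classes).
#' @return List: `fold_accuracies`, `mean_accuracy`, `confusion` (true x
#'   predicted counts pooled over folds), `selected` (per-fold selected
#'   column indices), `folds` (held-out run per fold).
#' @export
cross_validate <- function(features, k = 1000, cost = 1, check_runs = TRUE) {
  stopifnot(inherits(features, "trial_features"))
  runs <- sort(unique(features$runs))
  if (length(runs) < 2L) stop("leave-one-run-out needs at least 2 runs")
  classes <- sort(unique(features$labels))
  if (check_runs)
    for (r in runs)
      if (length(unique(features$labels[features$runs == r])) < length(classes))
        stop("run ", r, " does not contain every class")
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(length(runs))
  selected <- vector("list", length(runs))
  for (fi in seq_along(runs)) {
    test_idx <- features$runs == runs[fi]
    tr_x <- features$values[!test_idx, , drop = FALSE]
    tr_y <- features$labels[!test_idx]
    te_x <- features$values[test_idx, , drop = FALSE]
    te_y <- features$labels[test_idx]
    if (!is.null(k)) {
      f <- anova_f(tr_x, tr_y)
      cols <- select_top_k(f, k)
      tr_x <- tr_x[, cols, drop = FALSE]
      te_x <- te_x[, cols, drop = FALSE]
      selected[[fi]] <- cols
    } else selected[[fi]] <- seq_len(ncol(features$values))
    pred <- train_predict_ovo(tr_x, tr_y, te_x, cost = cost)
    fold_acc[fi] <- mean(pred == te_y)
    for (i in seq_along(te_y))
      conf[match(te_y[i], classes), match(pred[i], classes)] <-
        conf[match(te_y[i], classes), match(pred[i], classes)] + 1L
  }
  list(fold_accuracies = fold_acc, mean_accuracy = mean(fold_acc),
       confusion = conf, selected = selected, folds = runs)
}

#' Decode condition labels with cross-validation and permutation inference
#'
#' The central fit of the package: leave-one-run-out cross-validated
#' one-vs-one linear SVM decoding with fold-wise ANOVA-F voxel selection,
#' followed by a scrambled-label permutation test in which the *entire*
#' analysis (including fold-wise feature selection) is re-run `n_perm`
#' times with permuted labels. The p-value uses the add-one rule
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param features A `trial_features` object.
#' @param k Voxels selected per fold (`NULL` = no selection).
#' @param n_perm Number of label permutations (0 skips the null).
#' @param cost SVM soft-margin constant.
#' @param seed Integer seed for the permutation stream.
#' @param perm_scheme `"global"` permutes labels over all trials
#'   (preserving class counts); `"within_run"` permutes within each run.
#' @return An object of class `mvpa_decoding`: fold accuracies, mean
#'   accuracy, pooled confusion matrix, null accuracies, `p_value`,
#'   `null_95th` (95th percentile of the null, quantile type 7), and the
#'   per-fold selected voxels.
#' @examples
#' \donttest{
#' spec <- paradigm_spec(blocks_per_run = 3, seed = 7)
#' ev <- generate_events(spec)
#' iv <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' gt <- ground_truth(iv, amplitudes = matrix(rnorm(32), 4), noise_sd = 1,
#'                    seed = 7)
#' bold <- generate_bold(ev, gt, c(4, 4, 4))
#' feat <- extract_trial_features(preprocess_runs(bold), ev)
#' fit <- mvpa_decode(feat, k = NULL, n_perm = 49, seed = 7)
#' print(fit)
#' }
#' @export
mvpa_decode <- function(features, k = 1000, n_perm = 1000, cost = 1,
                        seed = 1L, perm_scheme = c("global", "within_run")) {
  perm_scheme <- match.arg(perm_scheme)
  if (!is_count(n_perm)) stop("n_perm must be a non-negative integer")
  cv <- cross_validate(features, k = k, cost = cost)
  null_acc <- NULL; p_value <- NA_real_; null_95 <- NA_real_
  if (n_perm >= 1L) {
    null_acc <- with_seed(derive_seed(seed, "permutations"), {
      vapply(seq_len(n_perm), function(i) {
        fp <- features
        fp$labels <- permute_labels(features$labels, features$runs,
                                    perm_scheme)
        cross_validate(fp, k = k, cost = cost,
                       check_runs = FALSE)$mean_accuracy
      }, numeric(1L))
    })
    p_value <- (1 + sum(null_acc >= cv$mean_accuracy)) / (n_perm + 1)
    null_95 <- unname(stats::quantile(null_acc, 0.95))
  }
  structure(list(fold_accuracies = cv$fold_accuracies,
                 mean_accuracy = cv$mean_accuracy,
                 confusion = cv$confusion, selected = cv$selected,
                 folds = cv$folds, null_accuracies = null_acc,
                 p_value = p_value, null_95th = null_95,
                 n_perm = n_perm, k = k, cost = cost,
                 perm_scheme = perm_scheme,
                 n_trials = length(features$labels),
                 n_voxels = ncol(features$values),
                 call = match.call()),
            class = "mvpa_decoding")
}

permute_labels <- function(labels, runs, scheme) {
  if (scheme == "global") return(sample(labels))
  out <- labels
  for (r in unique(runs)) {
    idx <- runs == r
    out[idx] <- sample(labels[idx])
  }
  out
}

#' @export
print.mvpa_decoding <- function(x, ...) {
  cat("One-vs-one linear SVM decoding (leave-one-run-out)\n")
  cat(sprintf("  %d trials, %d voxels%s, %d folds\n", x$n_trials, x$n_voxels,
              if (!is.null(x$k)) sprintf(" (top %d selected per fold)", x$k)
              else "", length(x$folds)))
  cat(sprintf("  mean accuracy: %.1f%% (chance %.1f%%)\n",
              100 * x$mean_accuracy, 100 / nrow(x$confusion)))
  if (!is.null(x$null_accuracies))
    cat(sprintf("  permutation test: %d scrambles, p = %.4g, null 95th pct = %.1f%%\n",
                x$n_perm, x$p_value, 100 * x$null_95th))
  invisible(x)
}

#' @export
summary.mvpa_decoding <- function(object, ...) {
  structure(list(fit = object), class = "summary.mvpa_decoding")
}

#' @export
print.summary.mvpa_decoding <- function(x, ...) {
  print(x$fit)
  cat("  fold accuracies:",
      paste(sprintf("%.1f%%", 100 * x$fit$fold_accuracies), collapse = ", "),
      "\n  confusion matrix (true x predicted):\n")
  print(x$fit$confusion)
  invisible(x)
}

#' Plot the permutation null against the observed accuracy
#'
#' @param x An `mvpa_decoding` fit with a permutation null.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.mvpa_decoding <- function(x, ...) {
  if (is.null(x$null_accuracies))
    stop("no permutation null in this fit (n_perm = 0)")
  graphics::hist(x$null_accuracies, breaks = 20,
                 main = "Scrambled-label null distribution",
                 xlab = "mean cross-validated accuracy",
                 xlim = range(c(x$null_accuracies, x$mean_accuracy)), ...)
  graphics::abline(v = x$mean_accuracy, col = "red", lwd = 2)
  graphics::abline(v = x$null_95th, col = "grey40", lty = 2)
  invisible(x)
}
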