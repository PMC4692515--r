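#' Exact Wilcoxon signed-rank test (tie-aware enumeration)
#'
#' Paired test of per-subject real decoding accuracy against the mean
#' accuracy of that subject's label-permutation null. Zero differences are
#' dropped (Wilcoxon's original treatment); absolute differences are
#' ranked with midranks for ties. The reported statistic W is the smaller
#' of the two signed-rank sums. For n <= 25 the two-sided p is exact:
#' P(min-rank-sum <= W) over all 2^n equiprobable sign assignments,
#' computed by generating-function convolution (equivalent to full
#' enumeration, exact under ties). Larger n falls back to the normal
#' approximation with tie correction.
#'
#' @param x,y Paired vectors (`y` defaults to zeros: one-sample test).
#' @return A `group_test` list: `statistic_name` ("W"), `statistic_value`,
#'   `p_value`, `n` (pairs after dropping zeros), `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # W = 0, p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n < 3L) warning("fewer than 3 non-zero differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    poly <- numeric(total + 1L)
    poly[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), poly[seq_len(total + 1L - ri)])
      poly <- poly + shifted
    }
    sums <- (seq_along(poly) - 1L) / 2      # possible T+ values
    tmin <- pmin(sums, sum(r) - sums)
    p <- sum(poly[tmin <= W + 1e-9]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu + 0.5) / sqrt(sig2)   # W is the smaller sum: left tail
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation"
  }
  structure(list(statistic_name = "W", statistic_value = W, p_value = p,
                 n = n, method = method), class = "group_test")
}

#' Exact Mann-Whitney U test (tie-aware enumeration)
#'
#' Compares decoding accuracies between two independent groups of
#' subjects. Combined midranks handle ties; U is the smaller of the two
#' group statistics. For small samples (choose(n, n_a) <= 2e5) the
#' two-sided p is exact by enumerating every group assignment; otherwise
#' the normal approximation with tie correction is used.
#'
#' @param a,b Numeric vectors for the two groups.
#' @return A `group_test` list with `statistic_name` "U".
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  ua <- ra - na * (na + 1) / 2
  ub <- na * nb - ua
  U <- min(ua, ub)
  if (choose(n, na) <= 2e5) {
    ra_all <- utils::combn(r, na, sum)
    ua_all <- ra_all - na * (na + 1) / 2
    u_all <- pmin(ua_all, na * nb - ua_all)
    p <- mean(u_all <= U + 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu + 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation"
  }
  structure(list(statistic_name = "U", statistic_value = U, p_value = p,
                 n = c(na, nb), method = method), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s = %g, p = %.4g (%s, n = %s)\n", x$statistic_name,
              x$statistic_value, x$p_value, x$method,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Spearman correlations with questionnaire scales, FDR corrected
#'
#' Rank-order correlation between per-subject mean decoding accuracy and
#' each questionnaire scale, with Benjamini-Hochberg adjustment across the
#' scales. A constant input vector yields an undefined rho (`NA`, flagged
#' in the output).
#'
#' @param mean_acc Per-subject mean accuracy across ROIs.
#' @param scores Data frame or matrix of per-subject scale scores (one
#'   column per scale, e.g. object/spatial/verbal).
#' @return A data frame: scale, rho, p_value, adjusted_p, n, degenerate.
#' @export
spearman_fdr <- function(mean_acc, scores) {
  scores <- as.data.frame(scores)
  if (nrow(scores) != length(mean_acc)) stop("paired vectors required")
  if (length(mean_acc) < 4L) stop("need at least 4 subjects")
  res <- lapply(names(scores), function(sc) {
    v <- scores[[sc]]
    if (stats::sd(v) == 0 || stats::sd(mean_acc) == 0)
      return(data.frame(scale = sc, rho = NA_real_, p_value = NA_real_,
                        n = length(v), degenerate = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(mean_acc, v, method = "spearman", exact = FALSE))
    data.frame(scale = sc, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(v), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("scale", "rho", "p_value", "adjusted_p", "n", "degenerate")]
}

#' Group-level inference over a per-subject decoding summary
#'
#' Reproduces the group statistics of the decoding pipeline: per ROI, an
#' exact Wilcoxon signed-rank test of real accuracy against the subject's
#' mean permutation-null accuracy; a Mann-Whitney U test of subject mean
#' accuracy (across ROIs) between the two direction groups; and Spearman
#' correlations (BH-corrected) of mean accuracy with the questionnaire
#' scales.
#'
#' @param df Data frame with columns `subject`, `roi`, `mean_accuracy`,
#'   `mean_null_accuracy`, `group`, and the scale columns `object`,
#'   `spatial`, `verbal`.
#' @return List: `wilcoxon` (data frame per ROI), `mann_whitney`
#'   (`group_test`), `spearman` (data frame per scale).
#' @export
group_inference <- function(df) {
  need <- c("subject", "roi", "mean_accuracy", "mean_null_accuracy",
            "group", "object", "spatial", "verbal")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  wil <- do.call(rbind, lapply(unique(df$roi), function(roi) {
    d <- df[df$roi == roi, ]
    t <- wilcoxon_signed_rank(d$mean_accuracy, d$mean_null_accuracy)
    data.frame(roi = roi, W = t$statistic_value, p_value = t$p_value,
               n = t$n)
  }))
  subj <- stats::aggregate(mean_accuracy ~ subject + group, df, mean)
  groups <- split(subj$mean_accuracy, subj$group)
  mw <- if (length(groups) == 2L)
    mann_whitney_u(groups[[1L]], groups[[2L]]) else NULL
  scales <- unique(df[, c("subject", "object", "spatial", "verbal")])
  scales <- scales[match(subj$subject, scales$subject), ]
  sp <- spearman_fdr(subj$mean_accuracy,
                     scales[, c("object", "spatial", "verbal")])
  list(wilcoxon = wil, mann_whitney = mw, spearman = sp)
}
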