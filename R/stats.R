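# Co-localization and discriminative-ion statistics: Pearson correlation of
# ion images against a reference image or region mask, ROC/AUC via the
# Mann-Whitney rank identity, balanced reference subsampling, and grouped
# intensity summaries with confidence-band outlier flagging.

fm_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
}

fm_centers <- function(features) {
  if (inherits(features, "feature_matrix")) features$centers else
    seq_len(ncol(fm_values(features)))
}

#' Pearson co-localization ranking
#'
#' Correlates every m/z interval's pixel vector with a reference vector
#' (a seed-ion image, or a 0/1 region mask: the point-biserial form).
#' Intervals with zero variance get r = 0 and are flagged.
#'
#' @param features A [feature_matrix] (or matrix, pixels x intervals).
#' @param reference Numeric vector, one value per pixel (same order as the
#'   feature rows); must have positive variance.
#' @return data.frame with columns `center`, `r`, `rank`, `zero_variance`,
#'   sorted by `r` descending.
#' @export
pearson_colocalization <- function(features, reference) {
  X <- fm_values(features)
  reference <- as.numeric(reference)
  if (length(reference) != nrow(X)) {
    msi_stop("reference length must equal the number of pixels")
  }
  if (stats::var(reference) == 0) {
    msi_stop("reference has zero variance", class = "msi3d_input_error")
  }
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], reference))
  }
  out <- data.frame(center = fm_centers(features), r = r,
                    zero_variance = !ok)
  out <- out[order(-out$r), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("center", "r", "rank", "zero_variance")]
}

# AUC via midranks (Mann-Whitney identity), exact under ties
auc_rank <- function(a, b) {
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}

#' ROC analysis of discriminative m/z intervals
#'
#' For each interval, the AUC for separating pixel group A from group B is
#' computed by the rank-sum (Mann-Whitney) identity with midrank tie
#' handling: the probability that a random A-pixel exceeds a random B-pixel
#' (+ half the tie probability). Results are oriented so AUC >= 0.5, with
#' the originally higher group recorded.
#'
#' @param features A [feature_matrix] or matrix.
#' @param pixels_A,pixels_B Row indices of the two disjoint, nonempty pixel
#'   groups.
#' @return data.frame with `center`, `auc`, `direction` (`"A"` or `"B"`:
#'   which group has the higher intensities), `n_A`, `n_B`, sorted by `auc`
#'   descending.
#' @export
roc_discriminative <- function(features, pixels_A, pixels_B) {
  X <- fm_values(features)
  pixels_A <- as.integer(pixels_A); pixels_B <- as.integer(pixels_B)
  if (!length(pixels_A) || !length(pixels_B)) {
    msi_stop("both pixel groups must be nonempty")
  }
  if (length(intersect(pixels_A, pixels_B))) {
    msi_stop("pixel groups must be disjoint", class = "msi3d_input_error")
  }
  auc <- vapply(seq_len(ncol(X)), function(j) {
    auc_rank(X[pixels_A, j], X[pixels_B, j])
  }, numeric(1))
  out <- data.frame(
    center = fm_centers(features),
    auc = pmax(auc, 1 - auc),
    direction = ifelse(auc >= 0.5, "A", "B"),
    n_A = length(pixels_A), n_B = length(pixels_B)
  )
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}

#' Balanced subsample of two reference segments
#'
#' Draws (about) equal numbers of pixels from each of two segments without
#' replacement, so that the combined reference group matches the size of a
#' comparison group.
#'
#' @param pixels_R1,pixels_C1 Row indices available in the two segments.
#' @param n_target Total size of the combined set.
#' @param seed Integer seed.
#' @return Integer vector of `n_target` row indices.
#' @export
balanced_subsample <- function(pixels_R1, pixels_C1, n_target, seed = 1L) {
  n1 <- ceiling(n_target / 2); n2 <- n_target - n1
  if (n1 > length(pixels_R1) || n2 > length(pixels_C1)) {
    msi_stop("n_target exceeds the available pixels",
             class = "msi3d_input_error")
  }
  with_preserved_seed(derive_seed(seed, "balanced_subsample"), {
    c(sample(pixels_R1, n1), sample(pixels_C1, n2))
  })
}

#' Grouped intensity summary with confidence-band outliers
#'
#' Per group and interval: mean, standard deviation and the population band
#' `mean +/- z(ci_level) * sd` (an interval for single observations, not a
#' standard-error band); pixels outside the band are flagged as outliers.
#'
#' @param features A [feature_matrix] or matrix.
#' @param grouping Factor/vector with one group label per pixel (e.g.
#'   timepoint or segment).
#' @param ci_level Confidence level of the band (default 0.95).
#' @return List with `summary` (data.frame: group, center, n, mean, sd,
#'   ci_lower, ci_upper, n_outliers) and `outliers` (data.frame: row,
#'   group, center, value).
#' @export
group_intensity_summary <- function(features, grouping, ci_level = 0.95) {
  X <- fm_values(features)
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == nrow(X), ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  centers <- fm_centers(features)
  summ <- list(); outl <- list(); k <- 0L
  for (g in levels(grouping)) {
    rows <- which(grouping == g)
    for (j in seq_len(ncol(X))) {
      v <- X[rows, j]
      m <- mean(v); s <- stats::sd(v)
      if (is.na(s)) s <- 0
      lo <- m - z * s; hi <- m + z * s
      bad <- rows[v < lo | v > hi]
      k <- k + 1L
      summ[[k]] <- data.frame(group = g, center = centers[j],
                              n = length(rows), mean = m, sd = s,
                              ci_lower = lo, ci_upper = hi,
                              n_outliers = length(bad))
      if (length(bad)) {
        outl[[k]] <- data.frame(row = bad, group = g, center = centers[j],
                                value = X[bad, j])
      }
    }
  }
  list(
    summary = do.call(rbind, summ),
    outliers = if (length(outl)) do.call(rbind, outl) else
      data.frame(row = integer(0), group = character(0),
                 center = numeric(0), value = numeric(0))
  )
}

#' Strip-chart summary plot of selected intervals by group
#'
#' Base-graphics rendering of grouped per-pixel intensities with the
#' population confidence band; out-of-band pixels are drawn in red.
#'
#' @inheritParams group_intensity_summary
#' @param centers Interval centers to plot (default: all).
#' @param file Optional PNG path; when given the plot is written there.
#' @export
plot_group_summary <- function(features, grouping, centers = NULL,
                               ci_level = 0.95, file = NULL) {
  X <- fm_values(features)
  all_centers <- fm_centers(features)
  if (is.null(centers)) centers <- all_centers
  cols <- match(centers, all_centers)
  if (anyNA(cols)) msi_stop("unknown interval center requested")
  grouping <- as.factor(grouping)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (!is.null(file)) {
    grDevices::png(file, width = 300 * length(cols), height = 350)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, length(cols)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (j in cols) {
    gi <- as.integer(grouping)
    jit <- gi + stats::runif(length(gi), -0.2, 0.2)
    m <- tapply(X[, j], grouping, mean)
    s <- tapply(X[, j], grouping, stats::sd)
    out <- X[, j] < (m[gi] - z * s[gi]) | X[, j] > (m[gi] + z * s[gi])
    graphics::plot(jit, X[, j], col = ifelse(out, "red", "grey40"),
                   pch = 16, cex = 0.5, xaxt = "n", xlab = "",
                   ylab = "intensity (a.u.)",
                   main = sprintf("m/z %.1f", all_centers[j]))
    graphics::axis(1, at = seq_along(levels(grouping)),
                   labels = levels(grouping))
    graphics::segments(seq_along(m) - 0.3, m, seq_along(m) + 0.3, m,
                       lwd = 2, col = "blue")
  }
  invisible(NULL)
}
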