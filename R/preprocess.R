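# Spectral preprocessing: baseline removal by iterative convolution and
# total-ion-count (TIC) normalization, plus the study mean spectrum.
#
# The baseline estimator is the min-of-smoothed recursion
#   b_0 = spectrum,  b_{k+1}(i) = min(b_k(i), (b_k * G)(i))
# with a Gaussian kernel G (reflective boundaries). Each iteration can only
# lower the estimate, so the final baseline lies below the input everywhere
# and converges onto the smooth envelope under the peaks.

#' Preprocessing parameters
#'
#' @param kernel_sigma Gaussian smoothing width of the baseline kernel, in Da.
#' @param iterations Number of min-of-smoothed iterations.
#' @param tic_target Constant every pixel's total ion count is scaled to.
#' @param grid_step Integer decimation step for baseline estimation on whole
#'   studies; `NULL` (default) picks `max(1, round(sigma_bins / 4))`, i.e. at
#'   least four baseline samples per kernel sigma. Single-spectrum
#'   [estimate_baseline()] always uses step 1 unless told otherwise.
#' @return Object of class `preprocess_params`.
#' @export
preprocess_params <- function(kernel_sigma = 5, iterations = 30,
                              tic_target = 1, grid_step = NULL) {
  stopifnot(kernel_sigma > 0, iterations >= 1, tic_target > 0)
  structure(list(kernel_sigma = kernel_sigma, iterations = as.integer(iterations),
                 tic_target = tic_target, grid_step = grid_step),
            class = "preprocess_params")
}

# Core recursion on a pixels x bins matrix (rows are spectra), optionally on
# a decimated bin grid with linear interpolation back to the full axis.
baseline_matrix <- function(X, mz, params, grid_step = 1L) {
  n <- length(mz)
  delta <- axis_bin_width(mz)
  idx <- seq(1L, n, by = max(1L, as.integer(grid_step)))
  if (idx[length(idx)] != n) idx <- c(idx, n)
  sigma_bins <- params$kernel_sigma / (delta * grid_step)
  S <- gaussian_smoother(length(idx), sigma_bins)
  tS <- Matrix::t(S)
  B <- X[, idx, drop = FALSE]
  for (k in seq_len(params$iterations)) {
    B <- pmin(B, as.matrix(B %*% tS))
  }
  if (length(idx) == n) return(B)
  # linear interpolation of the (smooth) decimated baseline back to the axis
  t(apply(B, 1L, function(b) stats::approx(mz[idx], b, xout = mz)$y))
}

#' Estimate the baseline of one spectrum by iterative convolution
#'
#' @param spectrum Numeric intensity vector on a uniform m/z axis.
#' @param mz The (uniform, increasing) m/z axis.
#' @param params [preprocess_params()].
#' @param grid_step Decimation step (1 = exact evaluation at every bin).
#' @return Baseline vector, pointwise below `spectrum`.
#' @export
estimate_baseline <- function(spectrum, mz, params = preprocess_params(),
                              grid_step = 1L) {
  stopifnot(length(spectrum) == length(mz))
  axis_bin_width(mz) # errors on non-uniform axis
  drop(baseline_matrix(matrix(spectrum, 1L), mz, params, grid_step))
}

#' Remove the baseline of one spectrum
#'
#' @inheritParams estimate_baseline
#' @return `pmax(0, spectrum - baseline)`.
#' @export
remove_baseline <- function(spectrum, mz, params = preprocess_params(),
                            grid_step = 1L) {
  pmax(0, spectrum - estimate_baseline(spectrum, mz, params, grid_step))
}

#' TIC-normalize a spectrum
#'
#' Scales the spectrum so its sum equals `tic_target`.
#'
#' @param spectrum Non-negative intensity vector.
#' @param tic_target Target total ion count.
#' @return Scaled spectrum summing to `tic_target`.
#' @export
normalize_tic <- function(spectrum, tic_target = 1) {
  s <- sum(spectrum)
  if (!is.finite(s) || s <= 0) {
    msi_stop("cannot TIC-normalize an all-zero spectrum",
             class = "msi3d_normalization_error")
  }
  spectrum * (tic_target / s)
}

#' Preprocess a whole study
#'
#' Removes the per-pixel baseline (iterative convolution, evaluated on a
#' decimated bin grid for speed; see [preprocess_params()]) and
#' TIC-normalizes every pixel. Pixels whose corrected spectrum is all zero
#' are flagged and excluded from the mean spectrum and from feature
#' extraction.
#'
#' @param study An [msi_study].
#' @param params [preprocess_params()].
#' @return The study with corrected, normalized intensities and per-section
#'   `flagged` vectors filled in.
#' @export
preprocess_study <- function(study, params = preprocess_params()) {
  delta <- axis_bin_width(study$mz)
  sigma_bins <- params$kernel_sigma / delta
  step <- params$grid_step
  if (is.null(step)) step <- max(1L, as.integer(round(sigma_bins / 4)))
  study$sections <- lapply(study$sections, function(s) {
    B <- baseline_matrix(s$intensities, study$mz, params, step)
    X <- pmax(s$intensities - B, 0)
    tic <- rowSums(X)
    flag <- !is.finite(tic) | tic <= 0
    X[!flag, ] <- X[!flag, , drop = FALSE] * (params$tic_target / tic[!flag])
    s$intensities <- X
    s$flagged <- flag
    # baseline-removed, pre-normalization TIC: the anatomical contrast
    # image used for registration (normalization flattens total content)
    s$tic_content <- tic
    s
  })
  attr(study, "preprocessed") <- TRUE
  study
}

#' Mean spectrum of a study
#'
#' Arithmetic mean over all non-flagged pixels of all sections.
#'
#' @param study An [msi_study] (typically after [preprocess_study()]).
#' @return Numeric vector on the study's m/z axis.
#' @export
mean_spectrum <- function(study) {
  tot <- numeric(length(study$mz))
  n <- 0
  for (s in study$sections) {
    keep <- !s$flagged
    if (!any(keep)) next
    tot <- tot + colSums(s$intensities[keep, , drop = FALSE])
    n <- n + sum(keep)
  }
  if (n == 0) msi_stop("no usable pixels for the mean spectrum")
  tot / n
}
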