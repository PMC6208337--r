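# Peak picking by orthogonal matching pursuit (OMP) on the mean spectrum,
# and centroid-matching alignment of every pixel to the detected peak set.
#
# The OMP dictionary holds one unit-norm Gaussian atom per m/z bin, with a
# linear resolution model sigma(mz) = width_a + width_b * mz. Each iteration
# selects the atom with the largest |<residual, atom>|, re-fits all selected
# amplitudes jointly by least squares, and updates the residual; the residual
# norm therefore decreases strictly and no atom is selected twice.

#' Peak width model
#' @param a Intercept (Da) of sigma(mz) = a + b * mz.
#' @param b Slope (Da per Da).
#' @return Function mapping m/z to sigma in Da.
#' @export
width_model <- function(a = 0.05, b = 1e-4) {
  stopifnot(a > 0, b >= 0)
  function(mz) a + b * mz
}

#' Construct a peak list
#' @param center Peak centers (Da), strictly increasing.
#' @param sigma Gaussian widths (Da), positive.
#' @param amplitude Peak heights (a.u.).
#' @return data.frame of class `peaklist`.
#' @export
peaklist <- function(center, sigma, amplitude) {
  o <- order(center)
  center <- center[o]; sigma <- sigma[o]; amplitude <- amplitude[o]
  if (length(center) > 1L && any(diff(center) <= 0)) {
    msi_stop("peak centers must be strictly increasing")
  }
  if (any(sigma <= 0)) msi_stop("peak widths must be positive")
  structure(
    data.frame(center = center, sigma = sigma, amplitude = amplitude),
    class = c("peaklist", "data.frame")
  )
}

# sparse dictionary of unit-norm Gaussian atoms, one per bin
omp_dictionary <- function(mz, wm) {
  n <- length(mz)
  delta <- axis_bin_width(mz)
  sig_bins <- wm(mz) / delta
  hw <- pmax(1L, ceiling(4 * sig_bins))
  trip_i <- vector("list", length(unique(hw)))
  trip_j <- trip_i; trip_x <- trip_i
  u <- 0L
  for (h in sort(unique(hw))) {
    u <- u + 1L
    atoms <- which(hw == h)
    off <- -h:h
    centers <- rep(atoms, each = length(off))
    rows <- centers + rep(off, times = length(atoms))
    ok <- rows >= 1L & rows <= n
    w <- exp(-(rep(off, times = length(atoms)))^2 /
               (2 * rep(sig_bins[atoms], each = length(off))^2))
    trip_i[[u]] <- rows[ok]
    trip_j[[u]] <- centers[ok]
    trip_x[[u]] <- w[ok]
  }
  D <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n, n)
  )
  nrm <- sqrt(Matrix::colSums(D^2))
  D %*% Matrix::Diagonal(x = 1 / nrm)
}

#' Detect peaks on a mean spectrum by orthogonal matching pursuit
#'
#' Greedy sparse approximation over a dictionary of unit-norm Gaussian atoms
#' centered at every axis bin. Stops when the relative residual energy
#' drops below `residual_fraction` or `max_peaks` atoms are selected. Atoms
#' whose jointly re-fit amplitude is not positive are discarded; centers are
#' refined to the intensity-weighted centroid within +/- 2 sigma, and peaks
#' refining to within one sigma of each other are merged.
#'
#' @param spectrum Baseline-removed mean spectrum.
#' @param mz Uniform m/z axis.
#' @param max_peaks Maximum number of atoms to select.
#' @param residual_fraction Stop when `||r||^2 / ||x||^2` falls below this.
#' @param wm Width model from [width_model()].
#' @return A [peaklist] (empty for an all-zero spectrum).
#' @export
detect_peaks_omp <- function(spectrum, mz, max_peaks = 60L,
                             residual_fraction = 0.01,
                             wm = width_model()) {
  stopifnot(length(spectrum) == length(mz), max_peaks >= 1L,
            residual_fraction >= 0)
  empty <- peaklist(numeric(0), numeric(0), numeric(0))
  normx2 <- sum(spectrum^2)
  if (normx2 == 0) return(empty)
  D <- omp_dictionary(mz, wm)
  x <- as.numeric(spectrum)
  r <- x
  sel <- integer(0)
  amps <- numeric(0)
  repeat {
    corr <- as.numeric(Matrix::crossprod(D, r))
    if (length(sel)) corr[sel] <- 0
    j <- which.max(abs(corr))
    if (abs(corr[j]) < 1e-12 * sqrt(normx2)) break
    sel <- c(sel, j)
    A <- as.matrix(D[, sel, drop = FALSE])
    amps <- qr.solve(A, x)
    r <- x - as.numeric(A %*% amps)
    if (sum(r^2) / normx2 < residual_fraction) break
    if (length(sel) >= max_peaks) break
  }
  if (!length(sel)) return(empty)
  # convert subspace coefficients (unit-norm atoms) to peak heights
  peak_height <- amps * apply(as.matrix(D[, sel, drop = FALSE]), 2L, max)
  keep <- peak_height > 0
  sel <- sel[keep]; peak_height <- peak_height[keep]
  if (!length(sel)) return(empty)
  delta <- axis_bin_width(mz)
  sig <- wm(mz[sel])
  centers <- vapply(seq_along(sel), function(k) {
    w <- max(1L, ceiling(2 * sig[k] / delta))
    i0 <- max(1L, sel[k] - w); i1 <- min(length(mz), sel[k] + w)
    y <- x[i0:i1]
    if (sum(y) <= 0) return(mz[sel[k]])
    sum(mz[i0:i1] * y) / sum(y)
  }, numeric(1))
  # peaks closer than twice the model width are unresolvable at the
  # assumed resolution: merge them (amplitude-weighted)
  o <- order(centers)
  centers <- centers[o]; sig <- sig[o]; peak_height <- peak_height[o]
  grp <- cumsum(c(TRUE, diff(centers) > 2 * sig[-length(sig)]))
  merged <- lapply(split(seq_along(grp), grp), function(ii) {
    w <- peak_height[ii]
    c(center = sum(centers[ii] * w) / sum(w),
      sigma = sum(sig[ii] * w) / sum(w),
      amplitude = sum(peak_height[ii]))
  })
  m <- do.call(rbind, merged)
  peaklist(m[, "center"], m[, "sigma"], m[, "amplitude"])
}

#' Construct a feature matrix
#' @param values Pixels x intervals matrix of integrated intensities.
#' @param keys data.frame of pixel keys (`section`, `x`, `y`).
#' @param centers Interval centers (Da).
#' @param sigmas Interval Gaussian widths (Da).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, keys, centers, sigmas = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(keys) == nrow(values), length(centers) == ncol(values))
  if (anyDuplicated(keys)) msi_stop("duplicate pixel keys in feature matrix")
  colnames(values) <- sprintf("mz_%.4f", centers)
  structure(list(values = values, keys = keys, centers = centers,
                 sigmas = sigmas),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d pixels x %d m/z intervals\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Align every pixel spectrum to the mean-spectrum peaks (centroid matching)
#'
#' For each pixel and each peak, the local maximum within
#' `+/- match_tolerance` of the peak center is located, its intensity
#' centroid computed, and intensity integrated (trapezoidal) over
#' centroid `+/- 2 sigma`. Where the pixel shows no interior local maximum,
#' integration is done at the nominal peak center, so a genuinely absent
#' peak contributes its (near-zero) local residual rather than an imputed
#' zero.
#'
#' @param study Preprocessed [msi_study].
#' @param peaks [peaklist] detected on the mean spectrum.
#' @param match_tolerance Per-peak matching tolerance in Da; default
#'   `pmax(0.2, 2 * sigma)`.
#' @return A [feature_matrix] over all non-flagged pixels.
#' @export
align_to_mean <- function(study, peaks, match_tolerance = NULL) {
  stopifnot(inherits(peaks, "peaklist"))
  if (nrow(peaks) == 0L) msi_stop("empty peak list")
  mz <- study$mz
  delta <- axis_bin_width(mz)
  tol <- if (is.null(match_tolerance)) pmax(0.2, 2 * peaks$sigma) else
    rep_len(match_tolerance, nrow(peaks))
  if (any(tol <= 0)) msi_stop("match tolerance must be positive",
                              class = "msi3d_config_error")
  out_vals <- list(); out_keys <- list()
  for (si in seq_along(study$sections)) {
    s <- study$sections[[si]]
    keep <- which(!s$flagged)
    X <- s$intensities[keep, , drop = FALSE]
    np <- nrow(X)
    V <- matrix(0, np, nrow(peaks))
    for (p in seq_len(nrow(peaks))) {
      ctr_bin <- which.min(abs(mz - peaks$center[p]))
      wt <- max(1L, round(tol[p] / delta))
      ws <- max(1L, ceiling(2 * peaks$sigma[p] / delta))
      i0 <- max(1L, ctr_bin - wt); i1 <- min(length(mz), ctr_bin + wt)
      sub <- X[, i0:i1, drop = FALSE]
      imax <- max.col(sub, ties.method = "first")
      interior <- imax > 1L & imax < ncol(sub)
      peak_bin <- ifelse(interior, i0 + imax - 1L, ctr_bin)
      # centroid within +/- 2 sigma of the located maximum
      c0 <- pmax(1L, peak_bin - ws); c1 <- pmin(length(mz), peak_bin + ws)
      w <- ws # fixed half-width; windows clipped at axis edges
      offs <- -w:w
      idx <- pmin(pmax(rep(peak_bin, each = length(offs)) +
                         rep(offs, times = np), 1L), length(mz))
      idx <- matrix(idx, nrow = np, byrow = TRUE)
      Y <- matrix(X[cbind(rep(seq_len(np), times = ncol(idx)), as.vector(idx))],
                  nrow = np)
      ysum <- rowSums(Y)
      cent_bin <- ifelse(
        ysum > 0,
        round(rowSums(Y * matrix(rep(offs, each = np), nrow = np)) / ysum),
        0
      ) + peak_bin
      cent_bin <- pmin(pmax(cent_bin, 1L), length(mz))
      # trapezoidal integral over centroid +/- 2 sigma
      idx2 <- pmin(pmax(rep(cent_bin, each = 1L) +
                          rep(offs, each = np), 1L), length(mz))
      idx2 <- matrix(idx2, nrow = np)
      Y2 <- matrix(X[cbind(rep(seq_len(np), times = ncol(idx2)),
                           as.vector(idx2))], nrow = np)
      V[, p] <- delta * (rowSums(Y2) - (Y2[, 1L] + Y2[, ncol(Y2)]) / 2)
    }
    out_vals[[si]] <- V
    out_keys[[si]] <- data.frame(section = si, x = s$coords$x[keep],
                                 y = s$coords$y[keep])
  }
  feature_matrix(do.call(rbind, out_vals), do.call(rbind, out_keys),
                 peaks$center, peaks$sigma)
}
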