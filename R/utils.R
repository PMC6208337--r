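# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' Derive a stage-specific seed from a global seed (stable across sessions)
#' @noRd
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131L)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Check that an m/z axis is uniform (constant bin width) and increasing
#' @noRd
axis_bin_width <- function(mz, tol = 1e-6) {
  if (length(mz) < 2L) stop("m/z axis needs at least two bins", call. = FALSE)
  d <- diff(mz)
  if (any(d <= 0)) stop("m/z axis must be strictly increasing", call. = FALSE)
  if ((max(d) - min(d)) > tol * mean(d)) {
    stop("m/z axis must be uniform (constant bin width)", call. = FALSE)
  }
  mean(d)
}

#' Trapezoidal integral on a uniform grid
#' @noRd
trapz_uniform <- function(y, delta) {
  n <- length(y)
  if (n < 2L) return(0)
  delta * (sum(y) - (y[1L] + y[n]) / 2)
}

#' Sparse reflective-boundary Gaussian smoothing matrix (n x n).
#' Row i holds the kernel weights used to smooth bin i; columns falling
#' outside [1, n] are reflected back inside, so smoothing a constant vector
#' returns the same constant.
#' @noRd
gaussian_smoother <- function(n, sigma_bins) {
  stopifnot(sigma_bins > 0)
  hw <- max(1L, ceiling(4 * sigma_bins))
  off <- -hw:hw
  w <- exp(-off^2 / (2 * sigma_bins^2))
  w <- w / sum(w)
  i <- rep(seq_len(n), each = length(off))
  j <- i + rep(off, times = n)
  # reflect indices (1-based, mirror about the edges)
  j <- ifelse(j < 1L, 2L - j, j)
  j <- ifelse(j > n, 2L * n - j, j)
  j <- pmin(pmax(j, 1L), n)
  Matrix::sparseMatrix(
    i = i, j = j, x = rep(w, times = n),
    dims = c(n, n)
  )
}

#' Clamp helper
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' stop() with a consistent error class
#' @noRd
msi_stop <- function(..., class = "msi3d_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
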