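# Rigid 2D transforms (rotation about the grid center + translation) and
# bilinear image resampling.
#
# Convention: a transform T = (theta, dx, dy) moves image content forward,
# i.e. a feature at point p of the input appears at
#   T(p) = R(theta) (p - c) + c + (dx, dy)
# in the output (c = grid center, x rightward, y downward, theta
# counter-clockwise in the x-right/y-up sense, degrees). Resampling is done
# by inverse mapping with bilinear interpolation; points mapping outside
# the grid read 0.

#' Construct a rigid 2D transform
#' @param theta Rotation in degrees about the grid center.
#' @param dx,dy Translation in pixels.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, dx = 0, dy = 0) {
  structure(list(theta = theta, dx = dx, dy = dy), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: theta = %.3f deg, d = (%.3f, %.3f) px\n",
              x$theta, x$dx, x$dy))
  invisible(x)
}

rot_mat <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first, then
#' `t2` (function composition `t2 o t1`).
#'
#' @param t2,t1 `rigid_transform` objects.
#' @export
compose_transforms <- function(t2, t1) {
  R2 <- rot_mat(t2$theta)
  d <- R2 %*% c(t1$dx, t1$dy) + c(t2$dx, t2$dy)
  rigid_transform(t1$theta + t2$theta, d[1L], d[2L])
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Ri <- rot_mat(-tf$theta)
  d <- -Ri %*% c(tf$dx, tf$dy)
  rigid_transform(-tf$theta, d[1L], d[2L])
}

#' Apply a rigid transform to an image (bilinear resampling)
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param tf A `rigid_transform`.
#' @return Resampled matrix of the same size; out-of-grid samples are 0.
#' @export
apply_transform <- function(img, tf) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  xo <- rep(seq_len(nc), each = nr)
  yo <- rep(seq_len(nr), times = nc)
  Ri <- rot_mat(-tf$theta)
  px <- xo - cx - tf$dx
  py <- yo - cy - tf$dy
  xi <- Ri[1L, 1L] * px + Ri[1L, 2L] * py + cx
  yi <- Ri[2L, 1L] * px + Ri[2L, 2L] * py + cy
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  val <- numeric(nr * nc)
  for (k in 1:4) {
    xs <- x0 + (k == 2L | k == 4L)
    ys <- y0 + (k == 3L | k == 4L)
    w <- (ifelse(xs == x0, 1 - fx, fx)) * (ifelse(ys == y0, 1 - fy, fy))
    ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr & w > 0
    if (any(ok)) {
      val[ok] <- val[ok] + w[ok] * img[cbind(ys[ok], xs[ok])]
    }
  }
  matrix(val, nr, nc)
}

#' Apply a rigid transform to all spectral channels of a section
#'
#' Resamples every m/z bin's image through the transform and rebuilds the
#' section's intensity matrix (clipped at zero).
#'
#' @param section An [msi_section].
#' @param tf A `rigid_transform`.
#' @export
apply_transform_section <- function(section, tf) {
  co <- section$coords
  nr <- max(co$y) + 1L; nc <- max(co$x) + 1L
  full_grid <- nrow(co) == nr * nc
  if (!full_grid) msi_stop("section transform needs a full dense grid")
  ridx <- cbind(co$y + 1L, co$x + 1L)
  out <- section$intensities
  for (j in seq_len(ncol(out))) {
    img <- matrix(0, nr, nc)
    img[ridx] <- section$intensities[, j]
    out[, j] <- pmax(0, apply_transform(img, tf)[ridx])
  }
  section$intensities <- out
  section
}
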