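# Scalar ion volumes D(x, y, z): registered z-stacks of one m/z interval's
# images, virtual dissection along arbitrary planes, and composite
# multi-channel projections.

#' Ion image of one m/z interval in a section
#'
#' Trapezoidal integral of each pixel's spectrum over
#' `center +/- 2 sigma`, placed on the section grid.
#'
#' @param section An [msi_section].
#' @param mz The study m/z axis.
#' @param center Interval center (Da).
#' @param sigma Interval Gaussian width (Da).
#' @return Numeric matrix (rows = y, cols = x).
#' @export
ion_image <- function(section, mz, center, sigma) {
  delta <- axis_bin_width(mz)
  ctr <- which.min(abs(mz - center))
  w <- max(1L, ceiling(2 * sigma / delta))
  i0 <- max(1L, ctr - w); i1 <- min(length(mz), ctr + w)
  Y <- section$intensities[, i0:i1, drop = FALSE]
  vals <- delta * (rowSums(Y) - (Y[, 1L] + Y[, ncol(Y)]) / 2)
  grid_to_image(vals, section$coords)
}

#' Build a scalar ion volume from registered sections
#'
#' Extracts one interval's ion image per section, applies the per-section
#' rigid transforms, and stacks them along z at `z_spacing`.
#'
#' @param study An [msi_study] (sections in z order).
#' @param transforms List of `rigid_transform`s from [register_stack()]
#'   (or `NULL` for identity).
#' @param center,sigma Interval definition in Da.
#' @param z_spacing Spacing between sections in micrometres.
#' @param interpolate_z Integer; when > 1, each inter-slice gap is filled
#'   with this many linearly interpolated sub-slices (for near-isotropic
#'   export).
#' @return Object of class `ion_volume`: `data` array (y, x, z), `voxel_um`
#'   (y, x, z sizes), `center`, `transforms`.
#' @export
build_volume <- function(study, transforms = NULL, center, sigma,
                         z_spacing = 204, interpolate_z = 1L) {
  secs <- study$sections
  if (is.null(transforms)) {
    transforms <- replicate(length(secs), rigid_transform(0, 0, 0),
                            simplify = FALSE)
  }
  stopifnot(length(transforms) == length(secs))
  slices <- lapply(seq_along(secs), function(i) {
    pmax(apply_transform(ion_image(secs[[i]], study$mz, center, sigma),
                         transforms[[i]]), 0)
  })
  arr <- array(0, dim = c(nrow(slices[[1L]]), ncol(slices[[1L]]),
                          length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  vz <- z_spacing
  if (interpolate_z > 1L && length(slices) > 1L) {
    nsub <- as.integer(interpolate_z)
    nz <- (length(slices) - 1L) * nsub + 1L
    out <- array(0, dim = c(dim(arr)[1L], dim(arr)[2L], nz))
    for (k in seq_len(nz)) {
      pos <- (k - 1) / nsub + 1
      i0 <- floor(pos); f <- pos - i0
      i1 <- min(i0 + 1L, dim(arr)[3L])
      out[, , k] <- (1 - f) * arr[, , i0] + f * arr[, , i1]
    }
    arr <- out
    vz <- z_spacing / nsub
  }
  structure(
    list(data = arr,
         voxel_um = c(y = study$pixel_size, x = study$pixel_size, z = vz),
         center = center, transforms = transforms),
    class = "ion_volume"
  )
}

#' @export
print.ion_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ion_volume m/z %.4f: %d x %d x %d voxels (%.0f x %.0f x %.0f um)\n",
    x$center, d[2L], d[1L], d[3L], x$voxel_um["x"], x$voxel_um["y"],
    x$voxel_um["z"]))
  invisible(x)
}

# trilinear sampling of a (y, x, z) array at fractional voxel coordinates
trilinear_sample <- function(arr, xs, ys, zs) {
  d <- dim(arr)
  val <- numeric(length(xs))
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  for (k in 0:7) {
    bx <- k %% 2L; by <- (k %/% 2L) %% 2L; bz <- k %/% 4L
    xi <- x0 + bx; yi <- y0 + by; zi <- z0 + bz
    w <- (if (bx == 0L) 1 - fx else fx) * (if (by == 0L) 1 - fy else fy) *
      (if (bz == 0L) 1 - fz else fz)
    ok <- xi >= 1 & xi <= d[2L] & yi >= 1 & yi <= d[1L] &
      zi >= 1 & zi <= d[3L] & w > 0
    if (any(ok)) {
      val[ok] <- val[ok] + w[ok] * arr[cbind(yi[ok], xi[ok], zi[ok])]
    }
  }
  val
}

#' Virtually dissect an ion volume along a plane
#'
#' Resamples the scalar density D(x, y, z) on a regular grid spanning the
#' plane defined by a point and a normal (micrometre coordinates, trilinear
#' interpolation; samples outside the volume read 0).
#'
#' @param volume An [ion_volume].
#' @param point Numeric length-3 (x, y, z) in micrometres on the plane.
#' @param normal Numeric length-3 plane normal (x, y, z).
#' @param spacing_um In-plane sample spacing; default = the smallest voxel
#'   size.
#' @return Numeric matrix of plane samples with attributes `u_axis`,
#'   `v_axis` (unit vectors, micrometres) and `spacing_um`.
#' @export
virtual_dissection <- function(volume, point, normal, spacing_um = NULL) {
  stopifnot(length(point) == 3L, length(normal) == 3L)
  n <- normal / sqrt(sum(normal^2))
  seed <- if (abs(n[1L]) <= abs(n[2L]) && abs(n[1L]) <= abs(n[3L])) {
    c(1, 0, 0)
  } else if (abs(n[2L]) <= abs(n[3L])) c(0, 1, 0) else c(0, 0, 1)
  u <- seed - sum(seed * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  d <- dim(volume$data)
  ext_um <- c((d[2L] - 1) * volume$voxel_um["x"],
              (d[1L] - 1) * volume$voxel_um["y"],
              (d[3L] - 1) * volume$voxel_um["z"])
  half <- sqrt(sum(ext_um^2)) / 2
  if (is.null(spacing_um)) spacing_um <- min(volume$voxel_um)
  # lattice centered on the plane point, so axis-aligned planes through
  # voxel centers sample the array exactly
  ticks <- seq(0, half, by = spacing_um)
  ticks <- c(-rev(ticks[-1L]), ticks)
  uu <- rep(ticks, times = length(ticks))
  vv <- rep(ticks, each = length(ticks))
  px <- point[1L] + uu * u[1L] + vv * v[1L]
  py <- point[2L] + uu * u[2L] + vv * v[2L]
  pz <- point[3L] + uu * u[3L] + vv * v[3L]
  xs <- px / volume$voxel_um["x"] + 1
  ys <- py / volume$voxel_um["y"] + 1
  zs <- pz / volume$voxel_um["z"] + 1
  img <- matrix(trilinear_sample(volume$data, xs, ys, zs),
                nrow = length(ticks))
  structure(img, u_axis = u, v_axis = v, spacing_um = spacing_um)
}

#' Compose ion volumes into a multi-channel color volume
#'
#' Each channel is min-max scaled to `[0, 1]` and mapped to its color;
#' colors add where channels overlap.
#'
#' @param volumes List of [ion_volume]s on the same grid.
#' @param colors Character vector of R color names/hex, one per channel.
#' @return Object of class `msi_composite`: scaled channel arrays + RGB
#'   weights.
#' @export
composite_channels <- function(volumes, colors) {
  stopifnot(length(volumes) == length(colors), length(volumes) >= 1L)
  d <- dim(volumes[[1L]]$data)
  channels <- lapply(volumes, function(v) {
    stopifnot(all(dim(v$data) == d))
    rng <- range(v$data)
    if (diff(rng) == 0) array(0, d) else (v$data - rng[1L]) / diff(rng)
  })
  rgb_w <- grDevices::col2rgb(colors) / 255
  structure(list(channels = channels, rgb = rgb_w, dim = d,
                 voxel_um = volumes[[1L]]$voxel_um,
                 centers = vapply(volumes, `[[`, numeric(1), "center")),
            class = "msi_composite")
}

#' Maximum-intensity projection of a composite volume
#'
#' @param composite An `msi_composite`.
#' @param axis Projection axis: `"z"` (default), `"x"` or `"y"`.
#' @return Array height x width x 3 (RGB in `[0, 1]`).
#' @export
mip_composite <- function(composite, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  proj <- lapply(composite$channels, function(ch) {
    switch(axis,
      z = apply(ch, c(1L, 2L), max),
      x = apply(ch, c(1L, 3L), max),
      y = apply(ch, c(2L, 3L), max))
  })
  out <- array(0, dim = c(dim(proj[[1L]]), 3L))
  for (i in seq_along(proj)) {
    for (c3 in 1:3) {
      out[, , c3] <- out[, , c3] + proj[[i]] * composite$rgb[c3, i]
    }
  }
  out[out > 1] <- 1
  out
}

#' Write an ion volume as NRRD (raw little-endian doubles)
#' @param volume An [ion_volume].
#' @param path Output path (`.nrrd`).
#' @export
write_volume_nrrd <- function(volume, path) {
  d <- dim(volume$data)
  hdr <- c(
    "NRRD0004",
    "# scalar MSI ion volume",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1L], d[2L], d[3L]),
    "encoding: raw",
    "endian: little",
    sprintf("spacings: %g %g %g", volume$voxel_um["y"], volume$voxel_um["x"],
            volume$voxel_um["z"]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write an ion volume as a multi-page TIFF (one page per z slice)
#' @param volume An [ion_volume].
#' @param path Output path (`.tif`).
#' @export
write_volume_tiff <- function(volume, path) {
  mx <- max(volume$data)
  sc <- if (mx > 0) 1 / mx else 1
  pages <- lapply(seq_len(dim(volume$data)[3L]),
                  function(k) volume$data[, , k] * sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
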