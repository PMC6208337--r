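# Core containers: gridded MSI sections and studies.
#
# An msi_section stores spectra of one serial section on a shared m/z axis:
# a dense pixels x bins intensity matrix plus 0-based grid coordinates
# (x rightward, y downward, image convention) and section metadata.

#' Construct an MSI section
#'
#' @param mz Shared m/z axis (Da), strictly increasing.
#' @param intensities Numeric matrix, pixels x bins, non-negative.
#' @param coords data.frame with integer columns `x`, `y` (0-based grid
#'   coordinates), one row per pixel, no duplicates.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param segment,timepoint_days,z_index,z_position_um Section metadata.
#' @return An object of class `msi_section`.
#' @export
msi_section <- function(mz, intensities, coords, pixel_size = 40,
                        segment = NA_character_, timepoint_days = NA_real_,
                        z_index = 1L, z_position_um = 0) {
  intensities <- as.matrix(intensities)
  stopifnot(
    is.numeric(mz), !is.unsorted(mz, strictly = TRUE),
    nrow(coords) == nrow(intensities),
    ncol(intensities) == length(mz),
    all(c("x", "y") %in% names(coords))
  )
  if (anyDuplicated(coords[, c("x", "y")])) {
    msi_stop("duplicate pixel coordinates in section")
  }
  if (any(intensities < 0)) msi_stop("intensities must be non-negative")
  structure(
    list(
      mz = as.numeric(mz),
      intensities = intensities,
      coords = data.frame(x = as.integer(coords$x), y = as.integer(coords$y)),
      pixel_size = pixel_size,
      meta = list(segment = segment, timepoint_days = timepoint_days,
                  z_index = as.integer(z_index), z_position_um = z_position_um),
      flagged = rep(FALSE, nrow(intensities))
    ),
    class = "msi_section"
  )
}

#' @export
print.msi_section <- function(x, ...) {
  cat(sprintf(
    "msi_section: %d pixels, %d m/z bins [%.1f-%.1f Da], segment %s, day %s, z %d\n",
    nrow(x$intensities), length(x$mz), min(x$mz), max(x$mz),
    x$meta$segment, format(x$meta$timepoint_days), x$meta$z_index
  ))
  invisible(x)
}

#' Bundle sections into a study
#'
#' Sections must share one m/z axis; within each (timepoint, segment) group
#' they are ordered by `z_index`, which must be unique there.
#'
#' @param sections List of [msi_section] objects.
#' @return An object of class `msi_study`.
#' @export
msi_study <- function(sections) {
  stopifnot(length(sections) >= 1L)
  mz <- sections[[1]]$mz
  for (s in sections) {
    if (!isTRUE(all.equal(s$mz, mz))) {
      msi_stop("all sections of a study must share one m/z axis")
    }
  }
  key <- vapply(sections, function(s)
    paste(s$meta$timepoint_days, s$meta$segment, sep = "|"), character(1))
  zi <- vapply(sections, function(s) s$meta$z_index, integer(1))
  if (anyDuplicated(data.frame(key, zi))) {
    msi_stop("z_index must be unique within (timepoint, segment)")
  }
  # groups keep their order of first appearance (rostro-caudal segment
  # order is meaningful); sections sort by z within each group
  sections <- sections[order(match(key, unique(key)), zi)]
  structure(list(sections = sections, mz = mz,
                 pixel_size = sections[[1]]$pixel_size),
            class = "msi_study")
}

#' @export
print.msi_study <- function(x, ...) {
  cat(sprintf("msi_study: %d sections, %d m/z bins, %d pixels total\n",
              length(x$sections), length(x$mz), n_pixels(x)))
  invisible(x)
}

#' Total number of pixels across all sections of a study
#' @param study An [msi_study].
#' @export
n_pixels <- function(study) {
  sum(vapply(study$sections, function(s) nrow(s$intensities), numeric(1)))
}

#' Pixel keys (section index, x, y) for all pixels of a study, in section order
#' @param study An [msi_study].
#' @return data.frame with columns `section`, `x`, `y`.
#' @export
pixel_keys <- function(study) {
  do.call(rbind, lapply(seq_along(study$sections), function(i) {
    s <- study$sections[[i]]
    data.frame(section = i, x = s$coords$x, y = s$coords$y)
  }))
}

#' Total-ion-count image of a section
#'
#' Sums each pixel's spectrum and places it on the section's grid. For a
#' preprocessed section, `type = "content"` (the default) returns the
#' baseline-removed TIC recorded *before* normalization — the image that
#' actually carries anatomical contrast, since after TIC normalization
#' every pixel sums to the same constant.
#'
#' @param section An [msi_section].
#' @param type `"content"` (baseline-removed TIC where available) or
#'   `"raw"` (plain sum of the stored intensities).
#' @return Numeric matrix (rows = y, cols = x).
#' @export
tic_image <- function(section, type = c("content", "raw")) {
  type <- match.arg(type)
  tic <- if (type == "content" && !is.null(section$tic_content)) {
    section$tic_content
  } else {
    rowSums(section$intensities)
  }
  grid_to_image(tic, section$coords)
}

#' Place per-pixel values on a dense image grid
#'
#' @param values Numeric vector, one per pixel.
#' @param coords 0-based coordinates data.frame (`x`, `y`).
#' @param fill Value for grid cells without a pixel.
#' @return Matrix with `max(y)+1` rows and `max(x)+1` columns.
#' @export
grid_to_image <- function(values, coords, fill = 0) {
  nr <- max(coords$y) + 1L
  nc <- max(coords$x) + 1L
  img <- matrix(fill, nr, nc)
  img[cbind(coords$y + 1L, coords$x + 1L)] <- values
  img
}
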