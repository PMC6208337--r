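# Automated rigid 2D registration of serial sections: coarse-to-fine
# rotation search with phase-correlation translation estimation and
# normalized cross-correlation (NCC) scoring, then sequential chaining
# across a section stack.

ncc_images <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  av <- a[mask]; bv <- b[mask]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

# translation aligning `moving` to `fixed` by phase correlation with
# subpixel quadratic refinement; returns c(dx, dy)
phase_correlation_shift <- function(fixed, moving) {
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  R <- Ff * Conj(Fm)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(stats::fft(R / mag, inverse = TRUE))
  nr <- nrow(r); nc <- ncol(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1L, ]
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  # quadratic subpixel refinement along each axis (periodic neighbours)
  sub <- function(i, n, get) {
    ym <- get(((i - 2L) %% n) + 1L); y0 <- get(i); yp <- get((i %% n) + 1L)
    den <- ym - 2 * y0 + yp
    if (den == 0) 0 else clamp(0.5 * (ym - yp) / den, -0.5, 0.5)
  }
  dyf <- sub(pk[1L], nr, function(i) r[i, pk[2L]])
  dxf <- sub(pk[2L], nc, function(j) r[pk[1L], j])
  c(dx = unname(wrap(pk[2L], nc)) + dxf, dy = unname(wrap(pk[1L], nr)) + dyf)
}

#' Estimate the rigid transform aligning a moving image to a fixed image
#'
#' Coarse-to-fine search: for each candidate rotation, the moving image is
#' rotated, the translation recovered by phase correlation (subpixel
#' quadratic refinement), and the candidate scored by NCC between the
#' warped moving image and the fixed image; the rotation grid is then
#' refined around the best candidate.
#'
#' @param fixed,moving Numeric matrices of the same size with nonzero
#'   variance.
#' @param rotation_range Half-range of the rotation search in degrees.
#' @param rotation_step Coarse step in degrees (refined to `fine_step`).
#' @param fine_step Refinement step in degrees.
#' @param fixed_mask Optional logical matrix: pixels of `fixed` that are
#'   valid for scoring (used when `fixed` is itself a resampled image with
#'   empty borders).
#' @return A `rigid_transform` with attribute `ncc` (the final score);
#'   `apply_transform(moving, tf)` approximates `fixed`.
#' @export
estimate_rigid <- function(fixed, moving, rotation_range = 10,
                           rotation_step = 0.5, fine_step = 0.1,
                           fixed_mask = NULL) {
  stopifnot(all(dim(fixed) == dim(moving)))
  if (stats::sd(as.numeric(fixed)) == 0 || stats::sd(as.numeric(moving)) == 0) {
    msi_stop("cannot register a constant image", class = "msi3d_input_error")
  }
  if (is.null(fixed_mask)) fixed_mask <- matrix(TRUE, nrow(fixed), ncol(fixed))
  eval_theta <- function(theta) {
    rot <- apply_transform(moving, rigid_transform(theta, 0, 0))
    d <- phase_correlation_shift(fixed, rot)
    tf <- rigid_transform(theta, d[["dx"]], d[["dy"]])
    warped <- apply_transform(moving, tf)
    support <- (apply_transform(matrix(1, nrow(moving), ncol(moving)), tf) >
                  0.99) & fixed_mask
    score <- ncc_images(fixed, warped, support)
    list(tf = tf, score = if (is.na(score)) -Inf else score)
  }
  thetas <- seq(-rotation_range, rotation_range, by = rotation_step)
  coarse <- lapply(thetas, eval_theta)
  scores <- vapply(coarse, `[[`, numeric(1), "score")
  best <- coarse[[which.max(scores)]]
  fine <- seq(best$tf$theta - rotation_step, best$tf$theta + rotation_step,
              by = fine_step)
  refined <- lapply(fine, eval_theta)
  rscores <- vapply(refined, `[[`, numeric(1), "score")
  best <- refined[[which.max(rscores)]]
  structure(best$tf, ncc = best$score)
}

#' Register a stack of serial-section images sequentially
#'
#' Each section's image (typically its TIC image, which carries all-ion
#' anatomical contrast even where individual ions vanish) is registered to
#' its already-registered predecessor; the first section is the reference.
#' Composed transforms map every section into the reference frame.
#'
#' @param images List of numeric matrices (one per section, same size), or
#'   an [msi_study] (spectral-content images are computed; see Details).
#' @param ... Passed to [estimate_rigid()].
#' @details For a study, each section's registration image is the per-pixel
#'   projection of its spectrum onto the study's baseline-removed mean
#'   spectrum. This is an all-ion content image like a TIC image, but the
#'   projection weights concentrate on the peak-carrying bins, so the
#'   broadband per-bin detector noise (which integrates into a flat TIC
#'   pedestal over thousands of bins) is suppressed and anatomical
#'   contrast survives.
#' @return List of `rigid_transform` objects (first = identity), each with
#'   attribute `ncc`.
#' @export
register_stack <- function(images, ...) {
  if (inherits(images, "msi_study")) {
    study <- images
    ms <- mean_spectrum(study)
    if (!isTRUE(attr(study, "preprocessed"))) {
      ms <- pmax(ms - estimate_baseline(ms, study$mz,
                                        grid_step = 8L), 0)
    }
    w <- ms / sqrt(sum(ms^2))
    images <- lapply(study$sections, function(s) {
      grid_to_image(as.numeric(s$intensities %*% w), s$coords)
    })
  }
  n <- length(images)
  stopifnot(n >= 1L)
  out <- vector("list", n)
  out[[1L]] <- structure(rigid_transform(0, 0, 0), ncc = 1)
  if (n == 1L) return(out)
  prev_registered <- images[[1L]]
  ones <- matrix(1, nrow(images[[1L]]), ncol(images[[1L]]))
  prev_mask <- ones > 0
  for (i in 2L:n) {
    pair <- estimate_rigid(prev_registered, images[[i]],
                           fixed_mask = prev_mask, ...)
    out[[i]] <- structure(pair, ncc = attr(pair, "ncc"))
    prev_registered <- apply_transform(images[[i]], out[[i]])
    prev_mask <- apply_transform(ones, out[[i]]) > 0.99
  }
  out
}

#' Write stack transforms as CSV
#' @param transforms List from [register_stack()].
#' @param path Output CSV path.
#' @export
write_transforms_csv <- function(transforms, path) {
  df <- do.call(rbind, lapply(seq_along(transforms), function(i) {
    tf <- transforms[[i]]
    data.frame(section = i, theta_deg = tf$theta, dx_px = tf$dx,
               dy_px = tf$dy, ncc = attr(tf, "ncc") %||% NA_real_)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
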