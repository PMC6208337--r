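# Synthetic 3D spinal-cord MSI phantom with full ground truth.
#
# Each section is a square pixel grid holding five mutually exclusive
# regions: background (outside the cord), butterfly-shaped gray matter,
# the surrounding white matter, and — inside the axial extent of the
# lesion — a core disk and a margin ring. The margin ring follows a
# "turnip" axial profile: a dorsal spot at the rostral entry, an expanding
# thin ring to the lesion center, progressive thickening towards the
# caudal side, then collapse back to a spot. Spectra are synthesized as
# Gaussian peaks (linear resolution model) with region-dependent
# amplitudes over a smooth decaying baseline, plus truncated-Gaussian
# noise and per-pixel multiplicative TIC variation; every section is
# resampled through a small random rigid transform that is recorded as
# ground truth.

.region_levels <- c("background", "gray", "white", "lesion_core",
                    "lesion_margin")

#' Phantom configuration
#'
#' Defaults reflect the emulated acquisition design: a 40 um pixel grid,
#' m/z 300-1100 at 0.1 Da bins, 36 sections per segment for the three
#' segments R1 (rostral), L (lesion) and C1 (caudal) at 3, 7 and 10 days
#' post injury, and 12 um sections imaged every 204 um (12 um kept + 16
#' skipped).
#'
#' @param grid_size Pixels per side (>= 16).
#' @param pixel_size Lateral pixel size, micrometres.
#' @param mz_range Length-2 m/z interval (Da).
#' @param mz_bin_width Bin width (Da, > 0).
#' @param sections_per_segment Imaged sections per segment (>= 1).
#' @param segments Ordered segment labels, rostral to caudal.
#' @param timepoints Days post injury.
#' @param z_spacing Micrometres between imaged sections.
#' @param noise_sd Truncated-Gaussian noise SD (a.u.).
#' @param baseline_amplitude Baseline height at the low-mass end (a.u.).
#' @param tic_variation_cv Coefficient of variation of the per-pixel
#'   multiplicative TIC factor.
#' @param misalignment_max Length-2: max |translation| (px) and
#'   max |rotation| (degrees) of the per-section misalignment.
#' @param seed Integer seed; the study is fully reproducible from it.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 64L, pixel_size = 40,
                           mz_range = c(300, 1100), mz_bin_width = 0.1,
                           sections_per_segment = 36L,
                           segments = c("R1", "L", "C1"),
                           timepoints = c(3, 7, 10), z_spacing = 204,
                           noise_sd = 0.3, baseline_amplitude = 2,
                           tic_variation_cv = 0.15,
                           misalignment_max = c(translation_px = 3,
                                                rotation_deg = 5),
                           seed = 1L) {
  stopifnot(grid_size >= 16L, mz_bin_width > 0, sections_per_segment >= 1L,
            length(mz_range) == 2L, mz_range[2L] > mz_range[1L],
            noise_sd >= 0, baseline_amplitude >= 0, tic_variation_cv >= 0,
            all(misalignment_max >= 0), length(segments) >= 1L,
            length(timepoints) >= 1L)
  structure(
    list(grid_size = as.integer(grid_size), pixel_size = pixel_size,
         mz_range = mz_range, mz_bin_width = mz_bin_width,
         sections_per_segment = as.integer(sections_per_segment),
         segments = segments, timepoints = timepoints, z_spacing = z_spacing,
         noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
         tic_variation_cv = tic_variation_cv,
         misalignment_max = misalignment_max, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' m/z axis of a phantom configuration
#' @param config A [phantom_config].
#' @export
phantom_mz_axis <- function(config) {
  seq(config$mz_range[1L], config$mz_range[2L], by = config$mz_bin_width)
}

#' Planted peak table of the phantom
#'
#' Theoretical m/z values come from the package's own adduct calculator.
#' Lesion-margin pixels carry the acylcarnitine class; lesion-core pixels
#' carry lysoPCs and the heme marker (which fades from day 3 to day 10)
#' plus a weak acylcarnitine component (the "widespread, less confined"
#' caudal behaviour) and a residual of the destroyed gray/white signal;
#' margin pixels also retain part of the peripheral white-matter signal.
#' Gray and white matter carry distinct high-mass phospholipid peaks.
#'
#' @param timepoint Days post injury (sets the heme amplitude).
#' @return data.frame: `mz`, `class`, and one amplitude column per region.
#' @export
phantom_peaks <- function(timepoint = 3) {
  heme_amp <- if (timepoint <= 3) 10 else if (timepoint <= 7) 2 else 0.3
  ac <- function(f) adduct_mz(f, "[M+H]+")
  na <- function(f) adduct_mz(f, "[M+Na]+")
  k <- function(f) adduct_mz(f, "[M+K]+")
  p <- function(mz, class, gray = 0, white = 0, core = 0, margin = 0) {
    data.frame(mz = mz, class = class, gray = gray, white = white,
               lesion_core = core, lesion_margin = margin, background = 0)
  }
  tab <- rbind(
    p(ac("C21H41NO4"), "margin", core = 0.25 * 10, margin = 10),
    p(ac("C23H43NO4"), "margin", core = 0.25 * 12, margin = 12),
    p(ac("C23H45NO4"), "margin", core = 0.25 * 15, margin = 15),
    p(ac("C25H47NO4"), "margin", core = 0.25 * 12, margin = 12),
    p(na("C24H50NO7P"), "core", core = 12),
    p(na("C26H52NO7P"), "core", core = 10),
    p(adduct_mz("C34H32FeN4O4", "[M]+."), "heme", core = heme_amp),
    p(k("C46H80NO8P"), "gray", gray = 14, core = 0.1 * 14),
    p(798.5411, "gray", gray = 10, core = 0.1 * 10),
    p(768.55, "white", white = 14, core = 0.15 * 14, margin = 0.5 * 14),
    p(822.60, "white", white = 10, core = 0.15 * 10, margin = 0.5 * 10)
  )
  tab[order(tab$mz), ]
}

ellipse_mask <- function(xg, yg, cx, cy, a, b, phi_deg) {
  ph <- phi_deg * pi / 180
  dx <- xg - cx; dy <- yg - cy
  u <- dx * cos(ph) + dy * sin(ph)
  v <- -dx * sin(ph) + dy * cos(ph)
  (u / a)^2 + (v / b)^2 <= 1
}

# axial lesion interval on the global rostro-caudal coordinate u in [0, 1]
# (segments R1 | L | C1 occupy equal thirds)
lesion_extent <- function(timepoint) {
  if (timepoint <= 3) {
    c(1 / 3 - 0.06, 2 / 3 + 0.06)   # extends into caudal R1 / rostral C1
  } else if (timepoint <= 7) {
    c(1 / 3 + 0.04, 2 / 3 - 0.04)   # restricted to L
  } else {
    c(1 / 3 + 0.08, 2 / 3 - 0.08)   # smaller still at 10 days
  }
}

# turnip profile: outer radius and ring thickness as functions of the
# within-lesion coordinate t in [0, 1] (rostral -> caudal), in units of
# the cord radius. The outer radius rises from a small dorsal spot,
# borders ~the whole cord girth over the central plateau, and collapses
# back to a spot caudally; the ring thickness grows monotonically towards
# the caudal side before the collapse.
turnip_profile <- function(t) {
  smoothstep <- function(x) {
    x <- clamp(x, 0, 1)
    x * x * (3 - 2 * x)
  }
  s <- pmin(smoothstep(t / 0.25), smoothstep((1 - t) / 0.25))
  r_out <- 0.10 + 0.88 * s
  thick <- ifelse(t <= 0.8,
                  0.14 + 0.46 * (t / 0.8),
                  0.60 - 0.48 * ((t - 0.8) / 0.2))
  list(r_out = r_out, r_in = pmax(0, r_out - thick))
}

#' Region masks of one phantom section
#'
#' @param z_fraction Position of the section within its segment, 0
#'   (rostral face) to 1 (caudal face).
#' @param timepoint Days post injury (must be a configured timepoint).
#' @param segment Segment label (must be a configured segment).
#' @param config A [phantom_config].
#' @return List with `masks` (named list of logical matrices over the
#'   grid: background, gray, white, lesion_core, lesion_margin — mutually
#'   exclusive and jointly covering it), `labels` (character matrix), and
#'   `profile` (u coordinate plus inner/outer lesion radii in px).
#' @export
make_section_geometry <- function(z_fraction, timepoint, segment, config) {
  stopifnot(z_fraction >= 0, z_fraction <= 1)
  seg_i <- match(segment, config$segments)
  if (is.na(seg_i)) {
    msi_stop("unknown segment label: '", segment, "'",
             class = "msi3d_input_error")
  }
  if (!timepoint %in% config$timepoints) {
    msi_stop("timepoint ", timepoint, " is not configured",
             class = "msi3d_input_error")
  }
  n <- config$grid_size
  ctr <- (n + 1) / 2
  R <- 0.45 * n
  xg <- matrix(rep(seq_len(n), each = n), n, n)   # column index = x
  yg <- matrix(rep(seq_len(n), times = n), n, n)  # row index = y
  cord <- ((xg - ctr)^2 + (yg - ctr)^2) <= R^2
  gray <- cord & (
    # ventral horns (bottom, y grows downward)
    ellipse_mask(xg, yg, ctr - 0.30 * R, ctr + 0.25 * R,
                 0.25 * R, 0.35 * R, 25) |
    ellipse_mask(xg, yg, ctr + 0.30 * R, ctr + 0.25 * R,
                 0.25 * R, 0.35 * R, -25) |
    # dorsal horns (top, slender)
    ellipse_mask(xg, yg, ctr - 0.17 * R, ctr - 0.30 * R,
                 0.15 * R, 0.37 * R, 10) |
    ellipse_mask(xg, yg, ctr + 0.17 * R, ctr - 0.30 * R,
                 0.15 * R, 0.37 * R, -10) |
    # central commissure connecting the horns
    ellipse_mask(xg, yg, ctr, ctr, 0.36 * R, 0.15 * R, 0)
  )
  core <- matrix(FALSE, n, n); margin <- matrix(FALSE, n, n)
  u <- (seg_i - 1 + z_fraction) / length(config$segments)
  ext <- lesion_extent(timepoint)
  r_in_px <- NA_real_; r_out_px <- NA_real_
  if (u >= ext[1L] && u <= ext[2L]) {
    t <- (u - ext[1L]) / (ext[2L] - ext[1L])
    prof <- turnip_profile(t)
    r_out_px <- prof$r_out * R
    r_in_px <- prof$r_in * R
    # lesion center drifts towards the dorsal column where the
    # distribution contracts to a spot
    cy <- ctr - 0.45 * R * (1 - prof$r_out / 0.98)
    d <- sqrt((xg - ctr)^2 + (yg - cy)^2)
    core <- cord & (d <= r_in_px)
    margin <- cord & (d > r_in_px) & (d <= r_out_px)
  }
  gray <- gray & !core & !margin
  white <- cord & !gray & !core & !margin
  background <- !cord
  masks <- list(background = background, gray = gray, white = white,
                lesion_core = core, lesion_margin = margin)
  lab <- matrix(.region_levels[1L], n, n)
  for (r in .region_levels[-1L]) lab[masks[[r]]] <- r
  list(masks = masks, labels = lab,
       profile = data.frame(u = u, r_in_px = r_in_px, r_out_px = r_out_px))
}

baseline_shape <- function(mz, config) {
  config$baseline_amplitude * exp(-(mz - mz[1L]) / 300)
}

# Region template spectra: peaks as Gaussian profiles with the linear
# resolution model sigma(mz) = 0.05 + 1e-4 mz (the width model the peak
# picker assumes). Each bin holds the profile's average over the bin
# (bin-integrated), so peak mass is conserved even when the bin width
# exceeds the peak width; for fine bins this converges to pointwise
# evaluation.
region_templates <- function(mz, peaks_tab) {
  wm <- width_model()
  delta <- axis_bin_width(mz)
  tmpl <- matrix(0, length(.region_levels), length(mz),
                 dimnames = list(.region_levels, NULL))
  for (i in seq_len(nrow(peaks_tab))) {
    ctr <- peaks_tab$mz[i]
    sig <- wm(ctr)
    prof <- sig * sqrt(2 * pi) / delta *
      (stats::pnorm(mz + delta / 2, ctr, sig) -
         stats::pnorm(mz - delta / 2, ctr, sig))
    for (r in .region_levels) {
      amp <- peaks_tab[[r]][i]
      if (amp > 0) tmpl[r, ] <- tmpl[r, ] + amp * prof
    }
  }
  tmpl
}

#' Synthesize one pixel spectrum
#'
#' Region-weighted mixture of the planted-peak templates plus the smooth
#' baseline and truncated-Gaussian noise, scaled by a random multiplicative
#' TIC factor. Uses the current RNG state; fix the seed for reproducibility.
#'
#' @param weights Named region occupancy weights (summing to 1).
#' @param peaks_tab Planted peaks from [phantom_peaks()].
#' @param config A [phantom_config].
#' @param mz Optional precomputed axis.
#' @return Intensity vector on the shared m/z axis.
#' @export
synthesize_spectrum <- function(weights, peaks_tab = phantom_peaks(),
                                config = phantom_config(), mz = NULL) {
  if (is.null(mz)) mz <- phantom_mz_axis(config)
  if (abs(sum(weights) - 1) > 1e-8) msi_stop("weights must sum to 1")
  amp_cols <- intersect(.region_levels, names(peaks_tab))
  if (any(as.matrix(peaks_tab[, amp_cols]) < 0)) {
    msi_stop("planted peak amplitudes must be non-negative",
             class = "msi3d_config_error")
  }
  tmpl <- region_templates(mz, peaks_tab)
  w <- numeric(length(.region_levels)); names(w) <- .region_levels
  w[names(weights)] <- weights
  spec <- as.numeric(w %*% tmpl) + baseline_shape(mz, config)
  if (config$noise_sd > 0) {
    spec <- spec + pmax(0, stats::rnorm(length(mz), 0, config$noise_sd))
  }
  tic_f <- if (config$tic_variation_cv > 0) {
    exp(stats::rnorm(1L, 0, sqrt(log(1 + config$tic_variation_cv^2))))
  } else 1
  spec * tic_f
}

# vectorized section synthesis: W (pixels x regions) %*% templates
synthesize_section <- function(W, tmpl, mz, config) {
  spec <- W %*% tmpl
  spec <- sweep(spec, 2L, baseline_shape(mz, config), "+")
  if (config$noise_sd > 0) {
    spec <- spec + pmax(0, matrix(stats::rnorm(length(spec), 0,
                                               config$noise_sd),
                                  nrow(spec)))
  }
  if (config$tic_variation_cv > 0) {
    tic_f <- exp(stats::rnorm(nrow(spec), 0,
                              sqrt(log(1 + config$tic_variation_cv^2))))
    spec <- spec * tic_f
  }
  spec
}

#' Generate a synthetic MSI study with ground truth
#'
#' Emits `sections_per_segment x |segments| x |timepoints|` sections. Each
#' section's ideal region masks are resampled through a random small rigid
#' transform (recorded in the ground truth) before spectra are synthesized,
#' emulating the per-section placement error that registration must undo.
#'
#' @param config A [phantom_config].
#' @param outdir Optional directory: when given, one imzML/ibd pair per
#'   (timepoint, segment) plus a `ground_truth.json` sidecar and mask TIFFs
#'   are written there.
#' @return List with `study` (an [msi_study]) and `truth` (class
#'   `phantom_truth`): per-section label matrices, true transforms, lesion
#'   profiles, planted peak tables, and the configuration.
#' @export
generate_study <- function(config = phantom_config(), outdir = NULL) {
  mz <- phantom_mz_axis(config)
  n <- config$grid_size
  coords <- data.frame(x = rep(seq_len(n) - 1L, each = n),
                       y = rep(seq_len(n) - 1L, times = n))
  ridx <- cbind(coords$y + 1L, coords$x + 1L)
  with_preserved_seed(config$seed, {
    sections <- list(); truth_sections <- list()
    peak_tabs <- lapply(config$timepoints, phantom_peaks)
    names(peak_tabs) <- as.character(config$timepoints)
    si <- 0L
    for (tp in config$timepoints) {
      tmpl <- region_templates(mz, peak_tabs[[as.character(tp)]])
      for (seg in config$segments) {
        for (k in seq_len(config$sections_per_segment)) {
          si <- si + 1L
          zf <- (k - 0.5) / config$sections_per_segment
          geo <- make_section_geometry(zf, tp, seg, config)
          tf <- rigid_transform(
            theta = stats::runif(1L, -1, 1) * config$misalignment_max[[2L]],
            dx = stats::runif(1L, -1, 1) * config$misalignment_max[[1L]],
            dy = stats::runif(1L, -1, 1) * config$misalignment_max[[1L]]
          )
          # soft region-occupancy weights: warped ideal masks
          W <- matrix(0, n * n, length(.region_levels),
                      dimnames = list(NULL, .region_levels))
          for (r in .region_levels[-1L]) {
            W[, r] <- clamp(apply_transform(geo$masks[[r]] * 1, tf)[ridx],
                            0, 1)
          }
          W[, "background"] <- pmax(0, 1 - rowSums(W[, -1L, drop = FALSE]))
          dom <- max.col(W, ties.method = "first")
          emitted <- matrix(.region_levels[dom], n, n)
          purity <- matrix(W[cbind(seq_len(n * n), dom)], n, n)
          X <- synthesize_section(W, tmpl, mz, config)
          sections[[si]] <- msi_section(
            mz, X, coords, pixel_size = config$pixel_size, segment = seg,
            timepoint_days = tp, z_index = k,
            z_position_um = (k - 1) * config$z_spacing
          )
          truth_sections[[si]] <- list(
            segment = seg, timepoint_days = tp, z_index = k,
            labels = geo$labels, labels_emitted = emitted,
            purity = purity, transform = tf, profile = geo$profile
          )
        }
      }
    }
    truth <- structure(
      list(sections = truth_sections, planted_peaks = peak_tabs,
           config = config),
      class = "phantom_truth"
    )
    study <- msi_study(sections)
    # msi_study() reorders sections (groups by first appearance, z within);
    # apply the same rule so truth sections align with study sections
    tkey <- vapply(truth_sections, function(t)
      paste(t$timepoint_days, t$segment, sep = "|"), character(1))
    okey <- order(match(tkey, unique(tkey)),
                  vapply(truth_sections, function(t) t$z_index, integer(1)))
    truth$sections <- truth_sections[okey]
    stopifnot(identical(
      tkey[okey],
      vapply(study$sections, function(s)
        paste(s$meta$timepoint_days, s$meta$segment, sep = "|"),
        character(1))))
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      for (tp in config$timepoints) {
        for (seg in config$segments) {
          sel <- vapply(study$sections, function(s)
            s$meta$timepoint_days == tp && s$meta$segment == seg, logical(1))
          write_imzml(study$sections[sel],
                      file.path(outdir, sprintf("day%g_%s", tp, seg)))
        }
      }
      write_ground_truth(truth, file.path(outdir, "ground_truth.json"))
    }
    list(study = study, truth = truth)
  })
}

#' Region masks of one ground-truth section
#' @param truth A `phantom_truth`.
#' @param i Section index (in study order).
#' @return Named list of logical matrices.
#' @export
region_masks <- function(truth, i) {
  lab <- truth$sections[[i]]$labels
  out <- lapply(.region_levels, function(r) {
    matrix(as.character(lab) == r, nrow(lab), ncol(lab))
  })
  names(out) <- .region_levels
  out
}

#' Per-pixel ground-truth region labels for a whole study
#'
#' @param truth A `phantom_truth`.
#' @param type `"emitted"` (default): the dominant region each *acquired*
#'   pixel actually contains, i.e. after the recorded misalignment was
#'   applied; `"ideal"`: the labels of the undistorted geometry.
#' @return Character vector in study pixel order (see [pixel_keys()]).
#' @export
truth_labels <- function(truth, type = c("emitted", "ideal")) {
  type <- match.arg(type)
  field <- if (type == "emitted") "labels_emitted" else "labels"
  unlist(lapply(truth$sections, function(t) as.character(t[[field]])),
         use.names = FALSE)
}

#' Per-pixel region purity (dominant-region occupancy) of the emitted study
#'
#' Boundary pixels mix regions once the per-section misalignment is
#' resampled; purity is the occupancy weight of the dominant region
#' (1 = pure pixel).
#'
#' @param truth A `phantom_truth`.
#' @return Numeric vector in study pixel order.
#' @export
truth_purity <- function(truth) {
  unlist(lapply(truth$sections, function(t) as.numeric(t$purity)),
         use.names = FALSE)
}

#' Write the ground-truth sidecar as JSON
#' @param truth A `phantom_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    config = truth$config[setdiff(names(truth$config), "segments")],
    segments = truth$config$segments,
    planted_peaks = truth$planted_peaks,
    sections = lapply(truth$sections, function(t) {
      list(segment = t$segment, timepoint_days = t$timepoint_days,
           z_index = t$z_index,
           transform = list(theta = t$transform$theta, dx = t$transform$dx,
                            dy = t$transform$dy),
           profile = t$profile,
           labels = as.integer(factor(as.character(t$labels),
                                      levels = .region_levels)) - 1L,
           labels_emitted = as.integer(
             factor(as.character(t$labels_emitted),
                    levels = .region_levels)) - 1L,
           purity = round(as.numeric(t$purity), 4),
           label_levels = .region_levels,
           grid = dim(t$labels))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export ground-truth masks as single-channel TIFFs
#' @param truth A `phantom_truth`.
#' @param dir Output directory.
#' @export
export_masks_tiff <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(truth$sections)) {
    t <- truth$sections[[i]]
    lab <- (as.integer(factor(as.character(t$labels),
                              levels = .region_levels)) - 1L) / 4
    tiff::writeTIFF(matrix(lab, nrow(t$labels), ncol(t$labels)),
                    file.path(dir, sprintf(
                      "mask_day%g_%s_z%02d.tif", t$timepoint_days,
                      t$segment, t$z_index)))
  }
  invisible(dir)
}
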