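# Synthetic spinal-cord phantom: geometry, spectra, study generation.

cfg_small <- phantom_config(grid_size = 24, sections_per_segment = 2,
                            mz_range = c(350, 700), mz_bin_width = 0.5,
                            seed = 5)

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(grid_size = 8))
  expect_error(phantom_config(mz_bin_width = 0))
  expect_error(phantom_config(sections_per_segment = 0))
  expect_error(phantom_config(noise_sd = -1))
  cfg <- phantom_config()
  expect_equal(cfg$grid_size, 64L)
  expect_equal(cfg$mz_range, c(300, 1100))
  expect_equal(cfg$z_spacing, 204)
})

test_that("region masks partition the grid everywhere", {
  for (z in c(0, 0.3, 0.5, 0.9)) for (tp in c(3, 7, 10)) {
    g <- make_section_geometry(z, tp, "L", cfg_small)
    tot <- Reduce(`+`, lapply(g$masks, function(m) m * 1L))
    expect_true(all(tot == 1L), info = paste(z, tp))
  }
})

test_that("lesion localization follows the time course", {
  # day 7: no lesion outside the L segment
  for (z in c(0.1, 0.5, 0.9)) {
    g <- make_section_geometry(z, 7, "R1", cfg_small)
    expect_equal(sum(g$masks$lesion_core) + sum(g$masks$lesion_margin), 0)
  }
  # day 3: lesion reaches the caudal end of R1
  gg <- make_section_geometry(0.95, 3, "R1", cfg_small)
  expect_gt(sum(gg$masks$lesion_margin), 0)
  # far outside the lesion: no lesion masks, gray present
  g0 <- make_section_geometry(0.1, 3, "R1", cfg_small)
  expect_equal(sum(g0$masks$lesion_core) + sum(g0$masks$lesion_margin), 0)
  expect_gt(sum(g0$masks$gray), 0)
  expect_error(make_section_geometry(0.5, 3, "XX", cfg_small),
               class = "msi3d_input_error")
})

test_that("margin ring grows from the rostral entry to the center", {
  entry <- make_section_geometry(0.92, 3, "R1", cfg_small)
  center <- make_section_geometry(0.5, 3, "L", cfg_small)
  expect_gt(sum(center$masks$lesion_margin),
            sum(entry$masks$lesion_margin))
})

test_that("margin thickness is non-decreasing to its caudal maximum, then collapses", {
  zs <- seq(0.02, 0.98, by = 0.04)
  prof <- do.call(rbind, lapply(zs, function(z)
    make_section_geometry(z, 3, "L", cfg_small)$profile))
  th <- prof$r_out_px - prof$r_in_px
  peak <- which.max(th)
  expect_true(all(diff(th[1:peak]) >= -1e-9))
  expect_true(all(diff(th[peak:length(th)]) <= 1e-9))
  expect_true(all(prof$r_out_px >= prof$r_in_px))
  expect_true(all(prof$r_in_px >= 0))
})

test_that("planted peaks lie in range and heme fades with time", {
  for (tp in c(3, 7, 10)) {
    tab <- phantom_peaks(tp)
    expect_true(all(tab$mz > 300 & tab$mz < 1100))
    amp_cols <- c("gray", "white", "lesion_core", "lesion_margin",
                  "background")
    expect_true(all(as.matrix(tab[, amp_cols]) >= 0))
  }
  heme_amp <- vapply(c(3, 7, 10), function(tp) {
    tab <- phantom_peaks(tp)
    tab$lesion_core[tab$class == "heme"]
  }, numeric(1))
  expect_true(all(diff(heme_amp) < 0))
  expect_lt(heme_amp[3], 0.05 * heme_amp[1])
})

test_that("single-pixel synthesis honors the noise-free limits", {
  cfg0 <- phantom_config(grid_size = 16, noise_sd = 0,
                         baseline_amplitude = 0, tic_variation_cv = 0,
                         mz_range = c(350, 700), mz_bin_width = 0.5)
  tab <- phantom_peaks(3)
  zero_tab <- tab
  for (r in c("gray", "white", "lesion_core", "lesion_margin")) {
    zero_tab[[r]] <- 0
  }
  w <- c(lesion_margin = 1)
  expect_equal(synthesize_spectrum(w, zero_tab, cfg0),
               numeric(length(phantom_mz_axis(cfg0))))
  # pure margin pixel: support only near its planted peaks
  spec <- synthesize_spectrum(w, tab, cfg0)
  mz <- phantom_mz_axis(cfg0)
  near_peak <- Reduce(`|`, lapply(tab$mz[tab$lesion_margin > 0], function(m)
    abs(mz - m) <= 5 * width_model()(m) + 0.5))
  expect_true(all(spec[!near_peak] < 1e-6 * max(spec)))
  expect_gt(max(spec[near_peak]), 0)
  expect_error(synthesize_spectrum(c(gray = 0.5), tab, cfg0), "sum to 1")
  bad <- tab; bad$gray[1] <- -1
  expect_error(synthesize_spectrum(w, bad, cfg0),
               class = "msi3d_config_error")
})

test_that("synthesis is deterministic under a fixed RNG state", {
  cfg <- phantom_config(grid_size = 16, mz_range = c(350, 700),
                        mz_bin_width = 0.5)
  set.seed(99); a <- synthesize_spectrum(c(white = 1), phantom_peaks(3), cfg)
  set.seed(99); b <- synthesize_spectrum(c(white = 1), phantom_peaks(3), cfg)
  expect_identical(a, b)
})

test_that("study generation emits the full section grid deterministically", {
  r1 <- generate_study(cfg_small)
  expect_equal(length(r1$study$sections),
               2L * 3L * 3L) # sections_per_segment x segments x timepoints
  r2 <- generate_study(cfg_small)
  expect_identical(r1$study, r2$study)
  expect_identical(r1$truth$sections, r2$truth$sections)
  # misalignments bounded by the configured maxima
  for (t in r1$truth$sections) {
    expect_lte(abs(t$transform$theta), cfg_small$misalignment_max[[2]])
    expect_lte(max(abs(c(t$transform$dx, t$transform$dy))),
               cfg_small$misalignment_max[[1]])
  }
})

test_that("ground-truth sidecars are byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- phantom_config(grid_size = 16, sections_per_segment = 1,
                        segments = "L", timepoints = 3,
                        mz_range = c(350, 450), mz_bin_width = 1, seed = 8)
  generate_study(cfg, outdir = d1)
  generate_study(cfg, outdir = d2)
  b1 <- readBin(file.path(d1, "ground_truth.json"), "raw", 10^7)
  b2 <- readBin(file.path(d2, "ground_truth.json"), "raw", 10^7)
  expect_identical(b1, b2)
  # and the sidecar reloads into an equivalent truth object
  tr <- read_ground_truth(file.path(d1, "ground_truth.json"))
  expect_equal(length(tr$sections), 1L)
  expect_equal(tr$sections[[1]]$labels,
               generate_study(cfg)$truth$sections[[1]]$labels)
})
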