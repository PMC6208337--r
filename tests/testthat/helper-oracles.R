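# Independent oracles and shared phantom fixtures for the test suite.

# --- oracles -----------------------------------------------------------

# AUC by exhaustive pair counting (1/2 credit per tie)
auc_bruteforce <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# Pearson r from the raw covariance formula
pearson_direct <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# globally optimal 2-partition by enumeration; returns minimal total WCSS
best_2partition_wcss <- function(x) {
  n <- nrow(x)
  wcss <- function(m) {
    if (nrow(m) <= 1L) return(0)
    sum(sweep(m, 2L, colMeans(m))^2)
  }
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1L))))
    if (!any(grp) || all(grp)) next
    w <- wcss(x[grp, , drop = FALSE]) + wcss(x[!grp, , drop = FALSE])
    if (w < best) best <- w
  }
  best
}

# adjusted Rand index (permutation-model expectation correction)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  max_idx <- (ai + bj) / 2
  if (max_idx == exp_idx) return(0)
  (nij - exp_idx) / (max_idx - exp_idx)
}

# 3D connected components, 26-connectivity; returns integer label array
concomp3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nl <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nl <- nl + 1L
    queue <- s
    lab[s] <- nl
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      z <- (cur - 1L) %/% (d[1L] * d[2L])
      rem <- (cur - 1L) %% (d[1L] * d[2L])
      x <- rem %/% d[1L]; y <- rem %% d[1L]
      for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
        if (dz == 0L && dx == 0L && dy == 0L) next
        nz <- z + dz; nx <- x + dx; ny <- y + dy
        if (nz < 0L || nz >= d[3L] || nx < 0L || nx >= d[2L] ||
            ny < 0L || ny >= d[1L]) next
        ni <- nz * d[1L] * d[2L] + nx * d[1L] + ny + 1L
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- nl
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# numeric trapezoid on a uniform grid
trapz_num <- function(y, delta) delta * (sum(y) - (y[1] + y[length(y)]) / 2)

# --- shared phantom fixtures (built once per session) ------------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# day-3 study at fine m/z binning: peak picking / feature / stats checks
phantom_day3 <- function() fixture("day3", function() {
  cfg <- phantom_config(grid_size = 32, sections_per_segment = 3,
                        timepoints = 3, mz_range = c(350, 900),
                        mz_bin_width = 0.1, seed = 11)
  r <- generate_study(cfg)
  st <- preprocess_study(r$study)
  ms <- remove_baseline(mean_spectrum(st), st$mz)
  pl <- detect_peaks_omp(ms, st$mz)
  fm <- align_to_mean(st, pl)
  list(config = cfg, study = st, truth = r$truth, mean_spec = ms,
       peaks = pl, features = fm,
       labels = truth_labels(r$truth), purity = truth_purity(r$truth),
       segments = vapply(seq_len(nrow(fm$keys)), function(i)
         st$sections[[fm$keys$section[i]]]$meta$segment, character(1)))
})

# all-timepoint study at coarser binning: Fig-1-style overview clustering
phantom_overview <- function() fixture("overview", function() {
  cfg <- phantom_config(grid_size = 32, sections_per_segment = 2,
                        timepoints = c(3, 7, 10), mz_range = c(350, 900),
                        mz_bin_width = 0.25, seed = 21)
  r <- generate_study(cfg)
  st <- preprocess_study(r$study)
  ptab <- phantom_peaks(3)
  pl <- peaklist(ptab$mz, width_model()(ptab$mz), rep(1, nrow(ptab)))
  fm <- align_to_mean(st, pl)
  list(config = cfg, study = st, truth = r$truth, features = fm,
       labels = truth_labels(r$truth), purity = truth_purity(r$truth))
})

# unlesioned serial stack with known misalignments: registration accuracy
phantom_stack <- function() fixture("stack", function() {
  cfg <- phantom_config(grid_size = 48, sections_per_segment = 6,
                        segments = "R1", timepoints = 7,
                        mz_range = c(350, 900), mz_bin_width = 1, seed = 31)
  r <- generate_study(cfg)
  st <- preprocess_study(r$study)
  list(config = cfg, study = st, truth = r$truth)
})

# day-3 three-segment stack at coarse binning: 3D volume assembly
phantom_volume <- function() fixture("volume", function() {
  cfg <- phantom_config(grid_size = 40, sections_per_segment = 5,
                        timepoints = 3, mz_range = c(350, 900),
                        mz_bin_width = 1, seed = 41)
  r <- generate_study(cfg)
  st <- preprocess_study(r$study)
  tfs <- register_stack(st)
  wm <- width_model()
  volM <- build_volume(st, tfs, center = 400.3421, sigma = wm(400.3421),
                       z_spacing = cfg$z_spacing)
  volC <- build_volume(st, tfs, center = 518.3217, sigma = wm(518.3217),
                       z_spacing = cfg$z_spacing)
  list(config = cfg, study = st, truth = r$truth, transforms = tfs,
       vol_margin = volM, vol_core = volC)
})

# tiny two-pixel study built from explicit spectra (io/preprocess tests)
tiny_study <- function(spec_list, mz, ...) {
  coords <- data.frame(x = seq_along(spec_list) - 1L, y = 0L)
  msi_study(list(msi_section(mz, do.call(rbind, spec_list), coords, ...)))
}
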