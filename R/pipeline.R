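# Workflow orchestration: configuration, stage dependency handling,
# manifests. Stages: simulate -> preprocess -> peaks -> segment / stats /
# register -> volume -> annotate. Every stage writes a manifest (inputs,
# parameters, derived seed, package version) so a run is auditable and
# reproducible; the global seed fans out to per-stage seeds by stable
# hashing of the stage name.

#' Build a pipeline configuration
#'
#' @param config Optional YAML path or named list overriding the defaults;
#'   blocks: `phantom`, `preprocess`, `peaks`, `segment`, `stats`,
#'   `volume`, `annotate`, plus global `seed` and `outdir`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    outdir = "msi3d_out",
    phantom = list(),   # passed to phantom_config()
    preprocess = list(kernel_sigma = 5, iterations = 30, tic_target = 1),
    peaks = list(max_peaks = 60L, residual_fraction = 0.01),
    segment = list(n_leaves = 4L, depth = 1L, restarts = 5L),
    stats = list(ci_level = 0.95, auc_threshold = 0.75),
    volume = list(targets = c(400.3421, 518.3217, 616.1767),
                  colors = c("red", "blue", "green"), interpolate_z = 1L),
    annotate = list(tolerance_da = 0.3)
  )
  user <- if (is.character(config)) yaml::read_yaml(config) else
    (config %||% list())
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_lists(a[[nm]], b[[nm]])
      } else b[[nm]]
    }
    a
  }
  structure(merge_lists(defaults, user), class = "pipeline_config")
}

write_manifest <- function(outdir, stage, params, inputs, seed) {
  dir.create(file.path(outdir, "manifests"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list(
    stage = stage, parameters = params, inputs = inputs, seed = seed,
    package_version = tryCatch(
      as.character(utils::packageVersion("msi3d")),
      error = function(e) "dev"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       file.path(outdir, "manifests",
                                 paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

dependency_error <- function(stage, needed) {
  msi_stop("stage '", stage, "' is missing its input artifacts; run stage '",
           needed, "' first", class = "msi3d_dependency_error")
}

#' Read a ground-truth sidecar written by [write_ground_truth()]
#' @param path JSON path.
#' @return A `phantom_truth` object.
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  secs <- lapply(seq_len(nrow(j$sections)), function(i) {
    row <- j$sections[i, ]
    lv <- unlist(row$label_levels)
    dims <- unlist(row$grid)
    list(
      segment = row$segment, timepoint_days = row$timepoint_days,
      z_index = as.integer(row$z_index),
      labels = matrix(lv[unlist(row$labels) + 1L], dims[1L], dims[2L]),
      labels_emitted = matrix(lv[unlist(row$labels_emitted) + 1L],
                              dims[1L], dims[2L]),
      purity = matrix(unlist(row$purity), dims[1L], dims[2L]),
      transform = rigid_transform(row$transform$theta, row$transform$dx,
                                  row$transform$dy),
      profile = as.data.frame(row$profile)
    )
  })
  structure(list(sections = secs, planted_peaks = j$planted_peaks,
                 config = c(j$config, list(segments = j$segments))),
            class = "phantom_truth")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order against one artifact
#' directory. Stage state is held in memory within one call and reloaded
#' from the artifact directory across calls where possible; a stage whose
#' upstream artifacts are absent raises a dependency error naming the
#' stage to run first.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced to one).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "peaks", "segment", "stats", "register",
#'   "volume", "annotate")`, or `"all"`.
#' @return Invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  all_stages <- c("simulate", "preprocess", "peaks", "segment", "stats",
                  "register", "volume", "annotate")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) msi_stop("unknown stage(s): ",
                                paste(unknown, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())

  need_study <- function(stage) {
    if (!is.null(state$study)) return(invisible())
    gt <- file.path(outdir, "ground_truth.json")
    files <- list.files(outdir, pattern = "\\.imzML$", full.names = TRUE)
    if (!length(files)) dependency_error(stage, "simulate")
    secs <- list()
    for (f in files) {
      nm <- sub("\\.imzML$", "", basename(f))
      parts <- strsplit(nm, "_")[[1L]]
      tp <- as.numeric(sub("^day", "", parts[1L]))
      read <- read_imzml(f)
      for (s in read) {
        s$meta$segment <- parts[2L]
        s$meta$timepoint_days <- tp
        secs[[length(secs) + 1L]] <- s
      }
    }
    state$study <- msi_study(secs)
    if (file.exists(gt)) state$truth <- read_ground_truth(gt)
    invisible()
  }
  need_features <- function(stage) {
    if (!is.null(state$features)) return(invisible())
    f <- file.path(outdir, "features.csv")
    if (!file.exists(f)) dependency_error(stage, "peaks")
    state$features <- read_feature_matrix(f)
    p <- file.path(outdir, "peaks.csv")
    if (file.exists(p)) {
      tab <- utils::read.csv(p)
      state$peaks <- peaklist(tab$center, tab$sigma, tab$amplitude)
    }
    invisible()
  }

  for (stage in stages) {
    seed <- derive_seed(config$seed, stage)
    switch(stage,
      simulate = {
        ph <- do.call(phantom_config,
                      c(config$phantom, list(seed = seed)))
        res <- generate_study(ph, outdir = outdir)
        state$study <- res$study
        state$truth <- res$truth
        write_manifest(outdir, stage, config$phantom, list(), seed)
      },
      preprocess = {
        need_study(stage)
        pp <- do.call(preprocess_params, config$preprocess)
        state$study <- preprocess_study(state$study, pp)
        write_manifest(outdir, stage, config$preprocess,
                       list(sections = length(state$study$sections)), seed)
      },
      peaks = {
        if (is.null(state$study) ||
            !isTRUE(attr(state$study, "preprocessed"))) {
          dependency_error(stage, "preprocess")
        }
        ms <- mean_spectrum(state$study)
        state$peaks <- detect_peaks_omp(
          ms, state$study$mz,
          max_peaks = config$peaks$max_peaks,
          residual_fraction = config$peaks$residual_fraction)
        state$features <- align_to_mean(state$study, state$peaks)
        export_peaklist(state$peaks, file.path(outdir, "peaks.csv"))
        export_feature_matrix(state$features,
                              file.path(outdir, "features.csv"))
        write_manifest(outdir, stage, config$peaks,
                       list(n_peaks = nrow(state$peaks)), seed)
      },
      segment = {
        need_features(stage)
        tree <- bisecting_kmeans(state$features,
                                 n_leaves = config$segment$n_leaves,
                                 seed = seed,
                                 restarts = config$segment$restarts)
        labels <- cut_tree(tree, config$segment$depth)
        write_tree_json(tree, file.path(outdir, "segmentation_tree.json"))
        utils::write.csv(
          cbind(state$features$keys, label = as.integer(labels)),
          file.path(outdir, "segmentation_labels.csv"), row.names = FALSE)
        maps <- label_maps(labels)
        dir.create(file.path(outdir, "label_maps"), showWarnings = FALSE)
        for (i in seq_along(maps)) {
          tiff::writeTIFF(maps[[i]] / max(1, max(maps[[i]])),
                          file.path(outdir, "label_maps",
                                    sprintf("section%03d.tif", i)))
        }
        state$tree <- tree
        write_manifest(outdir, stage, config$segment,
                       list(n_pixels = length(labels)), seed)
      },
      stats = {
        need_features(stage)
        tryCatch(need_study(stage), error = function(e) NULL)
        arts <- list()
        if (is.null(state$truth) &&
            file.exists(file.path(outdir, "ground_truth.json"))) {
          state$truth <- read_ground_truth(
            file.path(outdir, "ground_truth.json"))
        }
        keys <- state$features$keys
        if (!is.null(state$truth)) {
          labs <- truth_labels(state$truth)
          # reference vector aligned to the feature rows
          all_keys <- do.call(rbind, lapply(
            seq_along(state$truth$sections), function(i) {
              d <- dim(state$truth$sections[[i]]$labels)
              data.frame(section = i,
                         x = rep(seq_len(d[2L]) - 1L, each = d[1L]),
                         y = rep(seq_len(d[1L]) - 1L, times = d[2L]))
            }))
          id_all <- paste(all_keys$section, all_keys$x, all_keys$y)
          id_feat <- paste(keys$section, keys$x, keys$y)
          labs_feat <- labs[match(id_feat, id_all)]
          ref <- as.numeric(labs_feat == "lesion_margin")
          if (stats::var(ref) > 0) {
            co <- pearson_colocalization(state$features, ref)
            utils::write.csv(co, file.path(outdir,
                                           "pearson_lesion_margin.csv"),
                             row.names = FALSE)
            arts$pearson <- "pearson_lesion_margin.csv"
          }
        }
        segs <- if (is.null(state$study)) character(0) else
          vapply(seq_len(nrow(keys)), function(i)
            state$study$sections[[keys$section[i]]]$meta$segment %||%
              NA_character_, character(1))
        if (!is.null(state$study) && all(c("R1", "L", "C1") %in% segs)) {
          iL <- which(segs == "L")
          iR <- which(segs == "R1"); iC <- which(segs == "C1")
          nb <- min(length(iL), length(iR) + length(iC))
          ref_set <- balanced_subsample(iR, iC, nb, seed = seed)
          roc <- roc_discriminative(state$features, iL, ref_set)
          utils::write.csv(roc, file.path(outdir, "roc_L_vs_R1C1.csv"),
                           row.names = FALSE)
          arts$roc <- "roc_L_vs_R1C1.csv"
        }
        if (!is.null(state$study)) {
          tps <- vapply(seq_len(nrow(keys)), function(i)
            state$study$sections[[keys$section[i]]]$meta$timepoint_days,
            numeric(1))
          gs <- group_intensity_summary(state$features, tps,
                                        config$stats$ci_level)
          utils::write.csv(gs$summary,
                           file.path(outdir, "group_summary_timepoint.csv"),
                           row.names = FALSE)
          gseg <- group_intensity_summary(state$features, segs,
                                          config$stats$ci_level)
          utils::write.csv(gseg$summary,
                           file.path(outdir, "group_summary_segment.csv"),
                           row.names = FALSE)
          arts$groups <- c("group_summary_timepoint.csv",
                           "group_summary_segment.csv")
        }
        write_manifest(outdir, stage, config$stats, arts, seed)
      },
      register = {
        need_study(stage)
        state$transforms <- register_stack(state$study)
        write_transforms_csv(state$transforms,
                             file.path(outdir, "transforms.csv"))
        write_manifest(outdir, stage, list(),
                       list(sections = length(state$transforms)), seed)
      },
      volume = {
        need_study(stage)
        tf_file <- file.path(outdir, "transforms.csv")
        if (is.null(state$transforms)) {
          if (!file.exists(tf_file)) dependency_error(stage, "register")
          tab <- utils::read.csv(tf_file)
          state$transforms <- lapply(seq_len(nrow(tab)), function(i)
            rigid_transform(tab$theta_deg[i], tab$dx_px[i], tab$dy_px[i]))
        }
        wm <- width_model()
        vols <- lapply(config$volume$targets, function(ctr) {
          build_volume(state$study, state$transforms, center = ctr,
                       sigma = wm(ctr),
                       z_spacing = state$truth$config$z_spacing %||% 204,
                       interpolate_z = config$volume$interpolate_z)
        })
        for (v in vols) {
          write_volume_nrrd(v, file.path(outdir, sprintf("volume_mz%.1f.nrrd",
                                                         v$center)))
        }
        comp <- composite_channels(
          vols, config$volume$colors[seq_along(vols)])
        mip <- mip_composite(comp, "z")
        tiff::writeTIFF(mip, file.path(outdir, "composite_mip_z.tif"))
        state$volumes <- vols
        write_manifest(outdir, stage, config$volume,
                       list(n_volumes = length(vols)), seed)
      },
      annotate = {
        need_features(stage)
        if (is.null(state$peaks)) dependency_error(stage, "peaks")
        asn <- match_peaks(state$peaks,
                           tolerance_da = config$annotate$tolerance_da)
        utils::write.csv(asn, file.path(outdir, "assignments.csv"),
                         row.names = FALSE)
        write_manifest(outdir, stage, config$annotate,
                       list(n_assigned = nrow(asn)), seed)
      }
    )
  }
  invisible(outdir)
}
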