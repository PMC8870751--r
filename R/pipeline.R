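# End-to-end orchestration: simulate -> morphometry/densitometry ->
# features -> group statistics -> classification, with a serializable run
# configuration. The numbered scripts under analysis/ drive these stages
# narratively; run_pipeline() executes them all for one configuration.

#' Default run configuration
#'
#' Carries the pipeline's fixed constants: the 0-300 HU cartilage window,
#' the 20 mm^2 hole-grade cutoff, k = 5 cross-validation folds, the default
#' STD weights (wall 0.5/0.5/0.5 and 0.3 lateral, curvature 5), default
#' phantom calibration pairs, voxel spacing and cohort sizes.
#'
#' @param seed master seed.
#' @return a named list; serializes round-trip stable via
#'   [config_to_json()] / [config_from_json()].
#' @export
default_config <- function(seed = 42) {
  list(seed = as.integer(seed),
       n_d = 24L, n_t = 15L, n_c = 8L,
       spacing = 0.5,
       hu_noise_sd = 10,
       cartilage_hu = c(0, 300),
       grade_cutoff = 20,
       calibration_pairs = data.frame(hu = c(0, 1000),
                                      density = c(1.0, 1.8)),
       alphas = default_alphas(),
       alpha_grid = seq(0, 3, by = 0.1),
       k_folds = 5L,
       cv_threshold = 5,
       target_edge = 2.5,
       max_wall_elements = 8000L,
       hyper = default_hyperparameters(),
       algorithms = c("RF", "GB", "DT"),
       selections = c("Bone", "Cartilage", "B-C", "WT-C", "TOT"))
}

#' @rdname default_config
#' @param config configuration list.
#' @param path JSON file path.
#' @export
config_to_json <- function(config, path) {
  config$alphas <- lapply(config$alphas, as.list)   # keep names in JSON
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$calibration_pairs <- as.data.frame(cfg$calibration_pairs)
  cfg$seed <- as.integer(cfg$seed)
  for (nm in c("n_d", "n_t", "n_c", "k_folds"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$alphas <- lapply(cfg$alphas, unlist)
  cfg
}

#' Extract the full feature row for one subject
#'
#' Runs the densitometric (voxel) and morphometric (mesh) measurements on a
#' realized subject and assembles the named feature vector: 8 bone features
#' (BMD-scale densities, patella volume/surface), 16 cartilage features
#' (HU densities within the 0-300 window, volumes, mesh surfaces), the
#' 48-parameter wall-thickness/curvature block, and the hole bookkeeping
#' (count, fitted total area, grade per compartment; excluded from all
#' classifier selections).
#'
#' @param subject a `synthetic_subject` realized with meshes and voxels.
#' @param config see [default_config()].
#' @return one-row data.frame.
#' @export
subject_features <- function(subject, config = default_config()) {
  cal <- calibrate_bmd(config$calibration_pairs)
  vol <- subject$volume
  if (is.null(vol) || is.null(subject$meshes))
    stop("subject must be realized with both meshes and voxels")
  row <- data.frame(subject_id = subject$subject_id, group = subject$group)

  # bone block (densities on the BMD scale)
  vv <- prod(vol$spacing)
  for (b in c("Femur", "Tibia", "Patella")) {
    hv <- vol$hu[vol$labels == match(paste0(b, "Bone"), vol$mask_names)]
    row[[paste0(b, "DENS")]] <- apply_bmd(cal, mean(hv))
    row[[paste0(b, "STD")]] <- cal$slope * stats::sd(hv)
    if (b == "Patella") {
      row$PatellaVOL <- length(hv) * vv
      row$PatellaSURF <- mask_surface_area(
        compartment_mask(vol, "PatellaBone"), spacing = vol$spacing)$area_mm2
    }
  }

  # cartilage block (HU scale, 0-300 window inclusive; surfaces from meshes)
  for (cc in cart_comps) {
    hv <- vol$hu[vol$labels == match(cc, vol$mask_names)]
    kept <- hv[hv >= config$cartilage_hu[1] & hv <= config$cartilage_hu[2]]
    if (!length(kept)) stop("empty thresholded mask for ", cc)
    row[[paste0(cc, "DENS")]] <- mean(kept)
    row[[paste0(cc, "STD")]] <- stats::sd(kept)
    row[[paste0(cc, "VOL")]] <- length(hv) * vv
    row[[paste0(cc, "SURF")]] <- surface_area(subject$meshes[[cc]]$outer_patch)
  }

  # wall-thickness / curvature block + hole bookkeeping
  analyses <- list()
  for (cc in cart_comps) {
    mesh <- subject$meshes[[cc]]
    n_outer <- nrow(mesh$outer_patch$faces)
    # on hole-refined meshes, measure a deterministic element subsample to
    # bound the ray-casting cost; statistics are over the measured elements
    wface <- seq_len(n_outer)
    mx <- config$max_wall_elements
    if (!is.null(mx) && n_outer > mx)
      wface <- sort(withr::with_seed(config$seed + match(cc, cart_comps),
                                     sample.int(n_outer, mx)))
    wt <- wall_thickness(mesh$closed, faces = wface)
    cv <- gaussian_curvature(mesh$outer_patch)
    sh <- cart_short[[cc]]
    analyses[[paste0(sh, ".wall")]] <- normalize_by_area(wt)
    analyses[[paste0(sh, ".curvature")]] <- normalize_by_area(cv)
    holes <- detect_holes(mesh$outer_patch, grade_cutoff = config$grade_cutoff)
    gr <- grade_compartment(holes, cutoff = config$grade_cutoff)
    row[[paste0("HoleCount", sh)]] <- gr$n_holes
    row[[paste0("HoleArea", sh)]] <- gr$total_area
    row[[paste0("HoleGrade", sh)]] <- gr$grade
  }
  wtc <- assemble_wtc_block(analyses, alphas = config$alphas)
  for (nm in names(wtc)) row[[nm]] <- wtc[[nm]]
  row
}

#' Parameter-level bone and cartilage features
#'
#' Builds the 24 bone + cartilage feature columns directly from the drawn
#' (ground-truth) subject parameters, bypassing voxel painting and mesh
#' measurement. Used for classifier calibration experiments where the
#' measurement layer is not under test.
#'
#' @param manifest the manifest of [generate_cohort()].
#' @param calibration unused placeholder for signature stability.
#' @return data.frame with `subject_id`, `group` and the B-C columns.
#' @export
parameter_features <- function(manifest, calibration = NULL) {
  out <- data.frame(subject_id = manifest$subject_id, group = manifest$group)
  out$FemurDENS <- manifest$bmd_Femur
  out$TibiaDENS <- manifest$bmd_Tibia
  out$PatellaDENS <- manifest$bmd_Patella
  out$FemurSTD <- out$TibiaSTD <- out$PatellaSTD <- 0.008
  out$PatellaVOL <- manifest$patella_volume
  out$PatellaSURF <- manifest$patella_surface
  for (cc in cart_comps) {
    sh <- cart_short[[cc]]
    out[[paste0(cc, "DENS")]] <- manifest[[paste0("dens_", sh)]]
    out[[paste0(cc, "STD")]] <- 10
    out[[paste0(cc, "VOL")]] <- manifest[[paste0("vol_", sh)]]
    out[[paste0(cc, "SURF")]] <- manifest[[paste0("surf_", sh)]]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort (streaming subject by subject), extracts all
#' features, runs the group-comparison battery and the classification
#' stage, and writes every artifact (manifest, feature table, statistics,
#' classification reports, resolved configuration, log) into `out_dir`.
#' Deterministic for a fixed config seed.
#'
#' @param config see [default_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param stages subset of `c("simulate", "stats", "classify")`.
#' @param verbose print progress lines.
#' @return list with `manifest`, `features`, `stats`, `reports`,
#'   `unstable`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         stages = c("simulate", "stats", "classify"),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(...))
    log_lines <<- c(log_lines, msg)
    say("%s", msg)
  }

  note("pipeline start: seed %d, cohort %d/%d/%d", config$seed,
       config$n_d, config$n_t, config$n_c)
  cal <- calibrate_bmd(config$calibration_pairs)
  coh <- generate_cohort(
    config$n_d, config$n_t, config$n_c, seed = config$seed,
    realize = c("mesh", "voxel"),
    callback = function(subj) subject_features(subj, config),
    spacing = config$spacing, hu_noise_sd = config$hu_noise_sd,
    target_edge = config$target_edge, calibration = cal)
  features <- do.call(rbind, coh$subjects)
  manifest <- coh$manifest
  note("simulated %d subjects, %d feature columns", nrow(features),
       ncol(features) - 2L)

  stats_tab <- NULL
  if ("stats" %in% stages && nrow(features) > 0) {
    fb <- feature_blocks()
    stat_cols <- intersect(c(fb$bone, fb$cartilage, fb$wtc), names(features))
    stat_cols <- stat_cols[vapply(features[stat_cols],
                                  function(v) stats::sd(v) > 0, logical(1))]
    stats_tab <- compare_groups(features[, stat_cols, drop = FALSE],
                                features$group)
    note("group statistics on %d features; %d significant omnibus",
         nrow(stats_tab), sum(stats_tab$significant))
  }

  reports <- list()
  unstable <- character(0)
  if ("classify" %in% stages && nrow(features) > 0) {
    unstable <- unstable_wtc_features(features, config$cv_threshold)
    labels <- factor(features$group)
    for (selname in config$selections) {
      sub <- build_selection(features, selname, unstable = unstable)
      for (alg in config$algorithms) {
        rep_ <- crossval_classify(sub, labels, algorithm = alg,
                                  k = config$k_folds, seed = config$seed,
                                  hyper = config$hyper, selection = selname)
        reports[[paste(selname, alg, sep = "_")]] <- rep_
        note("%s / %s: accuracy %.1f%%", selname, alg, rep_$accuracy)
      }
    }
  }

  out <- list(manifest = manifest, features = features, stats = stats_tab,
              reports = reports, unstable = unstable, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
                       row.names = FALSE)
    if (length(reports)) {
      summ <- do.call(rbind, lapply(reports, function(r) {
        data.frame(selection = r$selection, algorithm = r$algorithm,
                   accuracy = r$accuracy,
                   sens_D = r$sensitivity[["D"]],
                   spec_D = r$specificity[["D"]],
                   sens_T = r$sensitivity[["T"]],
                   spec_T = r$specificity[["T"]],
                   sens_C = r$sensitivity[["C"]],
                   spec_C = r$specificity[["C"]])
      }))
      utils::write.csv(summ, file.path(out_dir, "classification_metrics.csv"),
                       row.names = FALSE)
      rf_bc <- reports[["B-C_RF"]]
      if (!is.null(rf_bc) && !is.null(rf_bc$importance))
        utils::write.csv(rf_bc$importance,
                         file.path(out_dir, "feature_importance_BC_RF.csv"),
                         row.names = FALSE)
    }
    config_to_json(config, file.path(out_dir, "config.json"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    note("outputs written to %s", out_dir)
  }
  out
}

#' Import a directory of element field files
#'
#' Reads every file in `dir` matching `pattern` with
#' [read_element_field()], inferring the analysis kind from the file name
#' ("curv" -> curvature, otherwise wall) unless given.
#'
#' @param dir directory of element text files.
#' @param pattern file-name regular expression.
#' @param analysis_kind `NULL` to infer per file, or "wall"/"curvature".
#' @return named list of [element_field()]s.
#' @export
import_field_files <- function(dir, pattern = "\\.(txt|dat)$",
                               analysis_kind = NULL) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no element files found in ", dir)
  out <- lapply(files, function(f) {
    kind <- if (!is.null(analysis_kind)) analysis_kind
            else if (grepl("curv", basename(f), ignore.case = TRUE))
              "curvature" else "wall"
    read_element_field(f, analysis_kind = kind)
  })
  names(out) <- sub("\\.[^.]*$", "", basename(files))
  out
}
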