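#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' `run_pipeline()` drives a full run from a validated configuration:
#' phantom generation for all six stages, one projective image per stage,
#' a sinogram and filtered-back-projection slice for one stage, ROI texture
#' features, per-specimen PCA reports, pooled cross-stage scores, and the
#' 10-fold cross-validated SVM report. Every artifact is written under one
#' run directory and listed in a manifest together with all seeds, so an
#' identical configuration reproduces byte-identical tables.
NULL

#' Default run configuration
#'
#' All randomness derives from `seed`: stage phantoms use `seed + k`
#' (k = 1..6), Poisson noise `seed + 50 + k`, ROI sampling `seed + 70 + k`
#' and the CV partition `seed + 101`. Projective images for texture
#' analysis use fixed-reference, attenuation-bright (inverted) 8-bit
#' quantization so gray levels are comparable across stages; the choice is
#' recorded in each image's metadata.
#'
#' @param seed Master integer seed.
#' @param size Phantom side in pixels.
#' @param ct_stage Stage imaged tomographically.
#' @param ct_angles Number of sinogram angles over [0, 180).
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1, size = 256, ct_stage = "d5",
                               ct_angles = 180) {
  list(
    seed = seed,
    physics = list(
      energy_kev = 13, propagation_distance = 0.85,
      pixel_size = 9e-6, photon_count = 1e4
    ),
    phantom = list(
      size = size,
      stages = default_stage_specs(seed),
      tissue = tissue_defaults()
    ),
    imaging = list(
      quantize = "fixed", qrange = c(0, 2.5), invert = TRUE,
      noise = TRUE, noise_seeds = stats::setNames(as.list(seed + 50 + 1:6), stage_levels())
    ),
    ct = list(
      stage = ct_stage, n_angles = ct_angles, filter = "ram-lak",
      neglog = TRUE, seed = seed + 99
    ),
    glcm = list(
      K = 16, d = 1, symmetric = TRUE, n_rois = 20, roi_size = 50,
      roi_seeds = stats::setNames(as.list(seed + 70 + 1:6), stage_levels())
    ),
    pca = list(
      ccr_threshold = 0.80, score_threshold = 8.5,
      score_features = "raw", orientation = "uniformity"
    ),
    cv = list(k = 10, C = 1, seed = seed + 101)
  )
}

#' Validate a run configuration
#'
#' Checks the section structure and that every random stage carries an
#' explicit seed, before anything executes.
#'
#' @param cfg Configuration list (see [default_run_config()]) or the path of
#'   a YAML/JSON file holding one.
#' @return The validated configuration, invisibly.
#' @export
validate_run_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    cfg <- if (grepl("\\.json$", cfg)) {
      jsonlite::read_json(cfg, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(cfg)
    }
  }
  need <- c("seed", "physics", "phantom", "imaging", "ct", "glcm", "pca", "cv")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop(sprintf("config: missing section(s): %s", paste(miss, collapse = ", ")))
  }
  if (is.null(cfg$seed) || is.null(cfg$cv$seed) || is.null(cfg$ct$seed)) {
    stop("config: every random stage requires an explicit seed")
  }
  for (g in stage_levels()) {
    sp <- cfg$phantom$stages[[g]]
    if (is.null(sp) || is.null(sp$seed)) {
      stop(sprintf("config: phantom stage %s lacks a seed", g))
    }
    if (is.null(cfg$imaging$noise_seeds[[g]]) || is.null(cfg$glcm$roi_seeds[[g]])) {
      stop(sprintf("config: imaging/ROI seed missing for stage %s", g))
    }
  }
  invisible(cfg)
}

write_float_tiff <- function(mat, path) {
  tiff::writeTIFF(mat, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' @param cfg Validated configuration, see [default_run_config()].
#' @param out_dir Run directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Path of the manifest JSON, invisibly. Artifacts per stage:
#'   `phantom_<stage>_{delta,beta}.tif` + sidecar JSON,
#'   `projection_<stage>.tif` (8-bit) + metadata JSON,
#'   `features_<stage>.csv`; plus `sinogram_<ct-stage>.tif`,
#'   `slice_<ct-stage>.tif`, `pca_<stage>.json`, `pooled_scores.json`,
#'   `cv_report.json`, `confusion.csv` and `manifest.json`.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir, quiet = FALSE) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pc <- cfg$physics
  phys <- physics_config(
    energy_kev = pc$energy_kev, propagation_distance = pc$propagation_distance,
    pixel_size = pc$pixel_size, photon_count = pc$photon_count
  )
  files <- character(0)
  add <- function(p) files <<- c(files, basename(p))

  mats <- list()
  for (g in stage_levels()) {
    sp <- cfg$phantom$stages[[g]]
    if (!inherits(sp, "stage_texture_spec")) {
      sp <- do.call(stage_texture_spec, sp)
    }
    map <- make_stage_phantom(g, cfg$phantom$size, sp, phys, cfg$phantom$tissue)
    for (part in c("delta", "beta")) {
      p <- file.path(out_dir, sprintf("phantom_%s_%s.tif", g, part))
      write_float_tiff(map[[part]] / max(map[[part]]), p)
      add(p)
    }
    sidecar <- file.path(out_dir, sprintf("phantom_%s.json", g))
    jsonlite::write_json(
      list(
        stage = g, seed = sp$seed, pixel_size = map$pixel_size,
        size = cfg$phantom$size, spec = unclass(sp),
        delta_max = max(map$delta), beta_max = max(map$beta)
      ),
      sidecar,
      auto_unbox = TRUE, digits = NA
    )
    add(sidecar)

    img <- acquire_projection(
      map,
      angle = 0, cfg = phys,
      seed = cfg$imaging$noise_seeds[[g]],
      geometry = "screen", noise = isTRUE(cfg$imaging$noise),
      quantize = cfg$imaging$quantize, qrange = unlist(cfg$imaging$qrange),
      invert = isTRUE(cfg$imaging$invert)
    )
    pimg <- file.path(out_dir, sprintf("projection_%s.tif", g))
    tiff::writeTIFF(img$gray / 255, pimg, bits.per.sample = 8)
    add(pimg)
    pmeta <- file.path(out_dir, sprintf("projection_%s.json", g))
    jsonlite::write_json(img$meta, pmeta, auto_unbox = TRUE, digits = NA)
    add(pmeta)

    rois <- sample_rois(
      img,
      mask = map$interior_mask,
      n = cfg$glcm$n_rois, size = cfg$glcm$roi_size,
      seed = cfg$glcm$roi_seeds[[g]], image_id = sprintf("projection_%s", g)
    )
    fm <- feature_matrix(
      rois,
      K = cfg$glcm$K, symmetric = isTRUE(cfg$glcm$symmetric), d = cfg$glcm$d
    )
    fcsv <- file.path(out_dir, sprintf("features_%s.csv", g))
    write_features_csv(fm, g, fcsv)
    add(fcsv)
    mats[[g]] <- fm
    say("stage %-6s: phantom, projection and %d ROI features written", g, nrow(fm))

    if (g == cfg$ct$stage) {
      angles <- seq(0, 180, length.out = cfg$ct$n_angles + 1)[seq_len(cfg$ct$n_angles)]
      sino <- acquire_sinogram(map, angles, phys, seed = cfg$ct$seed, noise = isTRUE(cfg$imaging$noise))
      psin <- file.path(out_dir, sprintf("sinogram_%s.tif", g))
      write_float_tiff(sino$data / max(sino$data), psin)
      add(psin)
      jsonlite::write_json(
        list(
          stage = g, n_angles = cfg$ct$n_angles, seed = cfg$ct$seed,
          pixel_size = sino$pixel_size, neglog = isTRUE(cfg$ct$neglog),
          filter = cfg$ct$filter
        ),
        file.path(out_dir, sprintf("sinogram_%s.json", g)),
        auto_unbox = TRUE, digits = NA
      )
      add(file.path(out_dir, sprintf("sinogram_%s.json", g)))
      rec_in <- if (isTRUE(cfg$ct$neglog)) {
        suppressMessages(neglog(sino, phys$photon_count))
      } else {
        sino
      }
      slice <- fbp_reconstruct(rec_in, filter = cfg$ct$filter)
      pslice <- file.path(out_dir, sprintf("slice_%s.tif", g))
      rng <- range(slice$values)
      write_float_tiff((slice$values - rng[1]) / diff(rng), pslice)
      add(pslice)
      say("stage %-6s: CT branch reconstructed (%d angles, %s filter)", g, cfg$ct$n_angles, cfg$ct$filter)
    }
  }

  for (g in names(mats)) {
    rep <- pca_report(
      mats[[g]],
      ccr_threshold = cfg$pca$ccr_threshold,
      score_threshold = cfg$pca$score_threshold,
      score_features = cfg$pca$score_features,
      orientation = cfg$pca$orientation
    )
    pj <- file.path(out_dir, sprintf("pca_%s.json", g))
    jsonlite::write_json(rep, pj, auto_unbox = TRUE, digits = NA)
    add(pj)
  }

  pooled <- pooled_stage_scores(mats, orientation = cfg$pca$orientation)
  ppool <- file.path(out_dir, "pooled_scores.json")
  jsonlite::write_json(
    list(
      table = pooled$table, eigenvalues = pooled$eigenvalues,
      ccr = pooled$ccr, orientation = pooled$orientation
    ),
    ppool,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  add(ppool)

  ds <- build_dataset(mats, n_per_stage = cfg$glcm$n_rois)
  cv <- tenfold_cv(ds, seed = cfg$cv$seed, k = cfg$cv$k, C = cfg$cv$C)
  pcv <- file.path(out_dir, "cv_report.json")
  jsonlite::write_json(
    list(
      fold_accuracies = cv$fold_accuracies, mean_accuracy = cv$mean_accuracy,
      n_correct = cv$n_correct, n = cv$n, k = cv$k, C = cv$C, seed = cv$seed,
      fold_assignment = cv$fold_assignment
    ),
    pcv,
    auto_unbox = TRUE, digits = NA
  )
  add(pcv)
  pconf <- file.path(out_dir, "confusion.csv")
  utils::write.csv(as.data.frame.matrix(cv$confusion), pconf)
  add(pconf)
  say("cross-validation: mean accuracy %.1f%%", 100 * cv$mean_accuracy)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serializable_config(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  add(cfg_path)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(
      package = "phasetex",
      version = as.character(utils::packageVersion("phasetex")),
      config_file = "config.json",
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = cfg$seed,
      stages = stage_levels(),
      n_feature_rows = sum(vapply(mats, nrow, 0L)),
      files = files
    ),
    manifest,
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

serializable_config <- function(cfg) {
  cfg$phantom$stages <- lapply(cfg$phantom$stages, unclass)
  cfg
}

#' Summary table of the per-specimen PCA reports of a run
#'
#' One row per stage with F1 and F2 mean +/- sd, their sum, the CCR of the
#' selected components and the discriminant label.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return data.frame with one row per stage found; warns when stages are
#'   missing, errors when the directory has no PCA reports at all.
#' @export
report_table <- function(run_dir) {
  paths <- file.path(run_dir, sprintf("pca_%s.json", stage_levels()))
  have <- file.exists(paths)
  if (!any(have)) {
    stop(sprintf("report_table: no PCA reports found in %s", run_dir))
  }
  if (!all(have)) {
    warning(sprintf(
      "report_table: missing stage(s): %s",
      paste(stage_levels()[!have], collapse = ", ")
    ))
  }
  rows <- lapply(which(have), function(k) {
    r <- jsonlite::read_json(paths[k], simplifyVector = TRUE)
    data.frame(
      stage = stage_levels()[k],
      F1 = sprintf("%.2f +/- %.2f", r$F1_mean, r$F1_sd),
      F2 = sprintf("%.2f +/- %.2f", r$F2_mean, r$F2_sd),
      F1_plus_F2 = sprintf("%.2f +/- %.2f", r$sum_mean, r$sum_sd),
      CCR = sprintf("%.2f%%", 100 * r$ccr_selected),
      n_components = r$n_components,
      label = r$label
    )
  })
  do.call(rbind, rows)
}
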