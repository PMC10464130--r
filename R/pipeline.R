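# End-to-end pipeline: phantom/ingest -> localize -> patches -> radon ->
# features -> dissimilarity -> train, with every intermediate written to an
# output directory and full determinism under a fixed config.

#' Pipeline configuration
#'
#' All knobs of the end-to-end run with documented defaults. Either a phantom
#' is generated (`image_path = NULL`) or an image + myocardium mask pair is
#' read from disk.
#'
#' @param phantom A [phantom_spec()] used when no input image is given.
#' @param image_path,myocardium_path Optional input files (any dialect
#'   [read_hu_image()] / [read_mask()] accept); when set, the phantom is not
#'   used and no ground-truth Dice is reported.
#' @param k Scar-threshold SD multiplier (default 3).
#' @param se `"square3"` or `"cross3"` cleanup structuring element.
#' @param morph_order `"open-close"` or `"close-open"`.
#' @param n_per_class Patches per class (default 50).
#' @param patch_size Tile side (default 25).
#' @param overlap_policy `"any"` or `"disjoint"`.
#' @param angles Radon projection angles, degrees.
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed for every random stage.
#' @param models Model families to train.
#' @param hyper Hyperparameter overrides, see [run_models()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            image_path = NULL, myocardium_path = NULL,
                            k = 3, se = c("square3", "cross3"),
                            morph_order = c("open-close", "close-open"),
                            n_per_class = 50, patch_size = 25,
                            overlap_policy = c("any", "disjoint"),
                            angles = 0:179, folds = 5, seed = 1L,
                            models = MODEL_NAMES, hyper = list()) {
  cfg <- list(
    phantom = phantom, image_path = image_path, myocardium_path = myocardium_path,
    k = k, se = match.arg(se), morph_order = match.arg(morph_order),
    n_per_class = as.integer(n_per_class), patch_size = as.integer(patch_size),
    overlap_policy = match.arg(overlap_policy), angles = as.numeric(angles),
    folds = as.integer(folds), seed = as.integer(seed),
    models = match.arg(models, MODEL_NAMES, several.ok = TRUE), hyper = hyper
  )
  structure(cfg, class = "pipeline_config")
}

stage_fail <- function(stage, msg, ...) {
  stop(errorCondition(
    sprintf("stage '%s': %s", stage, sprintf(msg, ...)),
    class = c(paste0("radonscar_stage_", stage), "radonscar_stage_error",
              "radonscar_error")
  ))
}

run_stage <- function(stage, code) {
  tryCatch(code, radonscar_stage_error = function(e) stop(e),
           error = function(e) stage_fail(stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes every stage, writing all intermediates (image, masks, region
#' statistics, patch manifest, sinograms, feature table, dissimilarity and
#' evaluation metrics, plus a config echo and run log) into `out_dir`.
#' Re-running with the same config and directory is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a manifest: named list of written file paths plus the
#'   in-memory `metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note("radonscar %s | R %s", as.character(utils::packageVersion("radonscar")),
       paste(R.version$major, R.version$minor, sep = "."))
  note("seed %d", config$seed)

  # config echo (drop non-serializable defaults cleanly)
  cfg_echo <- unclass(config)
  cfg_echo$phantom <- unclass(cfg_echo$phantom)
  paths$config <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_echo, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  # ---- ingest / phantom ----
  truth_scar <- NULL
  if (is.null(config$image_path)) {
    ph <- run_stage("phantom", generate_phantom(config$phantom))
    image <- ph$image; myocardium <- ph$myocardium; truth_scar <- ph$scar
    paths$truth_scar <- file.path(out_dir, "truth_scar.csv")
    write_mask(truth_scar, paths$truth_scar, "csv")
    note("stage phantom: %dx%d image, %d myocardium px, %d scar px",
         nrow(image), ncol(image), sum(myocardium), sum(truth_scar))
  } else {
    image <- run_stage("ingest", read_hu_image(config$image_path))
    myocardium <- run_stage("ingest", read_mask(config$myocardium_path))
    run_stage("ingest", check_same_shape(image, myocardium))
    note("stage ingest: %s", config$image_path)
  }
  paths$image <- file.path(out_dir, "image.csv")
  write_hu_image(image, paths$image, "csv")
  paths$myocardium <- file.path(out_dir, "myocardium.csv")
  write_mask(myocardium, paths$myocardium, "csv")

  # ---- localize ----
  se <- if (config$se == "square3") se_square3() else se_cross3()
  healthy <- run_stage("localize", estimate_healthy_stats(image, myocardium))
  scar_mask <- run_stage("localize",
    scar_pipeline(image, myocardium, healthy, k = config$k,
                  se = se, order = config$morph_order))
  paths$region_stats <- file.path(out_dir, "region_stats.json")
  write_metrics_json(list(mean = healthy$mean, sd = healthy$sd,
                          n_pixels = healthy$n_pixels), paths$region_stats)
  paths$scar_mask <- file.path(out_dir, "scar_mask.csv")
  write_mask(scar_mask, paths$scar_mask, "csv")
  dice <- if (!is.null(truth_scar)) dice_coefficient(scar_mask, truth_scar) else NULL
  note("stage localize: %d candidate px%s", sum(scar_mask),
       if (is.null(dice)) "" else sprintf(", Dice vs truth %.4f", dice))
  if (sum(scar_mask) == 0L) {
    stage_fail("patches", "no positive class: scar-candidate mask is empty")
  }

  # ---- patches ----
  patches <- run_stage("patches", {
    normal_mask <- myocardium & !scar_mask
    scar_p <- extract_patches(image, scar_mask, "scar", config$n_per_class,
                              config$patch_size, seed = config$seed + 1L,
                              overlap_policy = config$overlap_policy,
                              source_id = "pipeline")
    normal_p <- extract_patches(image, normal_mask, "normal", config$n_per_class,
                                config$patch_size, seed = config$seed + 2L,
                                overlap_policy = config$overlap_policy,
                                source_id = "pipeline")
    c(scar_p, normal_p)
  })
  paths$patches <- run_stage("patches", write_patches(patches, file.path(out_dir, "patches")))
  note("stage patches: %d patches (%d per class)", length(patches), config$n_per_class)

  # ---- radon + features ----
  features <- run_stage("features", patch_features(patches, config$angles))
  sino_dir <- file.path(out_dir, "sinograms")
  dir.create(sino_dir, showWarnings = FALSE)
  run_stage("radon", {
    sinos <- radon_transform_batch(patches, config$angles)
    for (i in seq_along(sinos)) {
      write_sinogram(sinos[[i]], file.path(sino_dir, sprintf("p%04d", i)))
    }
  })
  paths$sinograms <- sino_dir
  paths$features <- file.path(out_dir, "features.csv")
  write_feature_table(features, paths$features)
  note("stage features: %d x 10 feature table", nrow(features))

  # ---- dissimilarity ----
  diss <- run_stage("dissimilarity", class_dissimilarity(features))
  paths$dissimilarity <- file.path(out_dir, "dissimilarity.json")
  write_metrics_json(list(scar_vs_normal_wasserstein = diss$distance,
                          scar_mean_histogram = unname(diss$scar_mean),
                          normal_mean_histogram = unname(diss$normal_mean)),
                     paths$dissimilarity)
  note("stage dissimilarity: Wasserstein %.4f", diss$distance)

  # ---- train ----
  reports <- run_stage("train", run_models(features, k = config$folds,
                                           seed = config$seed,
                                           models = config$models,
                                           hyper = config$hyper))
  metrics <- lapply(reports, function(r) {
    r[c("model", "sensitivity", "specificity", "accuracy", "folds", "seed", "counts")]
  })
  if (!is.null(dice)) metrics$localization_dice <- dice
  metrics$wasserstein <- diss$distance
  paths$metrics_json <- file.path(out_dir, "metrics.json")
  write_metrics_json(metrics, paths$metrics_json)
  for (r in reports) {
    note("stage train: %s acc %.4f sens %.4f spec %.4f",
         r$model, r$accuracy, r$sensitivity, r$specificity)
  }

  paths$log <- file.path(out_dir, "run.log")
  writeLines(log_lines, paths$log)
  invisible(c(paths, list(metrics = metrics)))
}
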