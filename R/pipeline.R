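#' Pipeline configuration
#'
#' A single declarative object driving the end-to-end flow: data source
#' (phantom generator or an existing patient-wise directory), network spec,
#' training protocol, anomaly thresholds, sonification parameters, output
#' directory and the global seed.  Exactly one data source must be set.
#'
#' @param out_dir output directory; artifacts are organized under
#'   `out_dir/{masks,maps,audio,midi,reports,checkpoints}`.
#' @param phantom list of arguments for [generate_phantom_dataset()]
#'   (`n_patients`, `slices_per_patient`, `image_size`, `tumor_fraction`),
#'   or `NULL`.
#' @param data_dir existing dataset root for [index_dataset()], or `NULL`.
#' @param image_size network input side length.
#' @param model list of [model_spec()] arguments (`architecture`,
#'   `base_width`, ...).  The special architecture `"oracle"` replaces
#'   predictions with the ground-truth masks (used to exercise the
#'   perceptual back-ends without training).
#' @param train_cfg a [train_config()].
#' @param augment an [augmentation_config()] or `NULL`.
#' @param anomaly list: `min_size`, `severity_thresholds`.
#' @param sonification a [sonification_config()].
#' @param split_fractions train/val/test fractions.
#' @param seed global seed; all stage seeds derive from it.
#' @return an object of class `sonoseg_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            phantom = NULL,
                            data_dir = NULL,
                            image_size = 64L,
                            model = list(architecture = "unet",
                                         base_width = 16L),
                            train_cfg = train_config(),
                            augment = NULL,
                            anomaly = list(min_size = 5L,
                                           severity_thresholds =
                                             c(moderate = 2, high = 3)),
                            sonification = sonification_config(),
                            split_fractions = c(0.90, 0.05, 0.05),
                            seed = 1L) {
  if (is.null(phantom) == is.null(data_dir)) {
    abort_sonoseg("exactly one data source (phantom or data_dir) must be set",
                  class = "sonoseg_pipeline_error")
  }
  structure(list(out_dir = out_dir, phantom = phantom, data_dir = data_dir,
                 image_size = as.integer(image_size), model = model,
                 train_cfg = train_cfg, augment = augment, anomaly = anomaly,
                 sonification = sonification,
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "sonoseg_pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `train_cfg`,
#' `augment` and `sonification` sections are passed to their constructors.
#'
#' @param path YAML file.
#' @param overrides named list taking precedence over file values (e.g.
#'   command-line flags).
#' @return a `sonoseg_pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  args <- list(
    out_dir = y$out_dir %||% "sonoseg_out",
    phantom = y$phantom,
    data_dir = y$data_dir,
    image_size = y$image_size %||% 64L,
    model = y$model %||% list(architecture = "unet", base_width = 16L),
    train_cfg = do.call(train_config, y$train_cfg %||% list()),
    sonification = do.call(sonification_config, y$sonification %||% list()),
    seed = y$seed %||% 1L)
  if (!is.null(y$augment)) args$augment <- do.call(augmentation_config, y$augment)
  if (!is.null(y$anomaly)) args$anomaly <- y$anomaly
  if (!is.null(y$split_fractions)) args$split_fractions <- y$split_fractions
  do.call(pipeline_config, args)
}

pipeline_dirs <- function(out_dir) {
  dirs <- file.path(out_dir, c("masks", "maps", "audio", "midi", "reports",
                               "checkpoints"))
  names(dirs) <- c("masks", "maps", "audio", "midi", "reports", "checkpoints")
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  dirs
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(serialize_config(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(x) {
  if (is.list(x)) lapply(unclass(x), serialize_config) else x
}

#' Run the multimodal pipeline
#'
#' Executes the requested stages in order: `generate` (phantom dataset),
#' `train`, `predict`, `anomaly`, `color`, `sonify`, `midi`, `evaluate`.
#' Each stage writes its artifacts under the output directory and the run
#' ends with a `manifest.json` recording the configuration hash, seeds and
#' an MD5 checksum per artifact.  Stages are resumable: `predict` falls
#' back to the best checkpoint on disk when `train` is not part of the run,
#' and the perceptual stages fall back to predicted masks already on disk.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of the stage names above.
#' @param verbose print per-stage progress lines.
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config,
                         stages = c("train", "predict", "anomaly", "color",
                                    "sonify", "midi", "evaluate"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "sonoseg_pipeline_config"))
  known <- c("generate", "train", "predict", "anomaly", "color", "sonify",
             "midi", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort_sonoseg(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                  class = "sonoseg_pipeline_error")
  }
  stages <- known[known %in% stages]
  dirs <- pipeline_dirs(config$out_dir)
  oracle <- identical(config$model$architecture, "oracle")
  artifacts <- character(0)
  note <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  # ---- data
  data_root <- config$data_dir
  if (!is.null(config$phantom)) {
    data_root <- file.path(config$out_dir, "phantoms")
    if ("generate" %in% stages || !dir.exists(data_root)) {
      note("stage generate: phantom dataset (seed %d)", config$seed)
      do.call(generate_phantom_dataset,
              c(config$phantom, list(out_dir = data_root, seed = config$seed)))
    }
  }
  index <- index_dataset(data_root)
  split <- split_patients(index, config$split_fractions, seed = config$seed)
  write_manifest(index, file.path(config$out_dir, "dataset_manifest.csv"),
                 split = split)
  artifacts <- c(artifacts, file.path(config$out_dir, "dataset_manifest.csv"))
  test_data <- load_split(index, split, "test", size = config$image_size)

  model <- NULL
  fit <- NULL
  if (!oracle) {
    spec <- do.call(model_spec, c(config$model, list(
      input_size = c(config$image_size, config$image_size, 3L),
      seed = config$seed)))
  }

  if ("train" %in% stages) {
    if (oracle) {
      abort_sonoseg("the oracle model cannot be trained",
                    class = "sonoseg_pipeline_error")
    }
    note("stage train: %s (seed %d)", spec$architecture, config$seed)
    train_data <- load_split(index, split, "train", size = config$image_size)
    val_data <- load_split(index, split, "val", size = config$image_size)
    model <- build_model(spec)
    fit <- train(model, train_data, val_data, config$train_cfg,
                 augment = config$augment, checkpoint_dir = dirs["checkpoints"],
                 verbose = verbose)
    model <- fit$model
    utils::write.csv(fit$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, file.path(config$out_dir, "history.csv"))
    write_parameter_manifest(model, file.path(dirs["checkpoints"],
                                              "parameter_manifest.json"))
    artifacts <- c(artifacts,
                   file.path(dirs["checkpoints"], "parameter_manifest.json"))
  }

  preds <- NULL
  pred_stage_needed <- any(c("predict", "anomaly", "color", "sonify",
                             "midi", "evaluate") %in% stages)
  if (pred_stage_needed) {
    if (oracle) {
      preds <- test_data$masks
    } else if (!is.null(model)) {
      preds <- predict_probs(model, test_data$images)
    } else {
      ck <- file.path(dirs["checkpoints"], "best.rds")
      if (!file.exists(ck)) {
        abort_sonoseg(sprintf(
          "stage '%s' needs predictions, which need a trained model: run the 'train' stage first (no checkpoint at %s)",
          setdiff(stages, "train")[1], ck),
          class = "sonoseg_pipeline_error")
      }
      note("stage predict: restoring %s", ck)
      model <- load_checkpoint(ck)
      preds <- predict_probs(model, test_data$images)
    }
    if (length(dim(preds)) == 2L) dim(preds) <- c(dim(preds), 1L)
  }

  n_test <- dim(test_data$masks)[3]
  slice_tag <- sprintf("%s_s%02d",
                       test_data$index$patient_id,
                       test_data$index$slice_index)

  if ("predict" %in% stages) {
    note("stage predict: %d test slice(s)", n_test)
    for (i in seq_len(n_test)) {
      p <- file.path(dirs["masks"], paste0(slice_tag[i], "_pred.png"))
      png::writePNG((preds[, , i] >= 0.5) * 1, p)
      artifacts <- c(artifacts, p)
    }
  }

  reports <- NULL
  if (any(c("anomaly", "sonify", "midi") %in% stages)) {
    reports <- vector("list", n_test)
    for (i in seq_len(n_test)) {
      img <- to_gray(test_data$images[, , , i])
      mask <- (preds[, , i] >= 0.5) * 1
      reports[[i]] <- anomaly_report(
        img, mask, min_size = config$anomaly$min_size %||% 5L,
        severity_thresholds = config$anomaly$severity_thresholds %||%
          c(moderate = 2, high = 3))
    }
  }

  if ("anomaly" %in% stages) {
    note("stage anomaly: %d report(s)", n_test)
    for (i in seq_len(n_test)) {
      p <- file.path(dirs["reports"], paste0(slice_tag[i], "_anomaly.json"))
      write_anomaly_report(reports[[i]], p)
      artifacts <- c(artifacts, p)
    }
  }

  if ("color" %in% stages) {
    note("stage color: overlays")
    for (i in seq_len(n_test)) {
      img <- to_gray(test_data$images[, , , i])
      p <- file.path(dirs["maps"], paste0(slice_tag[i], "_overlay.png"))
      write_rgb_png(render_overlay(img, preds[, , i]), p)
      artifacts <- c(artifacts, p)
    }
  }

  if ("sonify" %in% stages) {
    note("stage sonify: stereo WAV")
    for (i in seq_len(n_test)) {
      img <- to_gray(test_data$images[, , , i])
      mask <- (preds[, , i] >= 0.5) * 1
      au <- create_advanced_brain_sonification(img, mask, reports[[i]],
                                               config$sonification)
      p <- file.path(dirs["audio"], paste0(slice_tag[i], ".wav"))
      write_wav(au, p)
      pj <- file.path(dirs["audio"], paste0(slice_tag[i], "_params.json"))
      jsonlite::write_json(serialize_config(config$sonification), pj,
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, p, pj)
    }
  }

  if ("midi" %in% stages) {
    note("stage midi: SMF")
    for (i in seq_len(n_test)) {
      mid <- create_advanced_midi_from_brain(reports[[i]],
                                             config$sonification)
      p <- file.path(dirs["midi"], paste0(slice_tag[i], ".mid"))
      write_midi(mid, p)
      artifacts <- c(artifacts, p)
    }
  }

  if ("evaluate" %in% stages) {
    note("stage evaluate")
    predfun <- function(images) preds
    rep_ <- evaluate(predfun, test_data)
    paths <- write_metric_report(rep_, dirs["reports"], "metrics")
    artifacts <- c(artifacts, unname(paths))
  }

  manifest <- list(
    package = "sonoseg",
    config_hash = config_hash(config),
    seed = config$seed,
    split = list(train = split$train_ids, val = split$val_ids,
                 test = split$test_ids),
    stages = stages,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
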