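# End-to-end pipeline: synthesise -> preprocess -> patch -> augment ->
# train -> evaluate, with stage-level caching keyed on the resolved
# configuration and a manifest recording the patch arithmetic.

#' Pipeline run configuration
#'
#' A single nested configuration covering every stage.  Unknown keys are
#' rejected, and the resolved configuration is written next to the outputs
#' of every run for provenance.
#'
#' @param synth list of [synth_config()] overrides plus `n_train`,
#'   `n_test`.
#' @param preprocess list: `patch_size`, `clip_limit`, `gamma`,
#'   `nlm_strength`, `augment` (logical).
#' @param model list of [model_config()] overrides.
#' @param train list of [train_config()] overrides.
#' @param evaluate list: `threshold`.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory.
#' @return a `masegnet_run_config` list.
#' @export
run_config <- function(synth = list(), preprocess = list(), model = list(),
                       train = list(), evaluate = list(), seed = 1L,
                       out_dir = tempfile("masegnet_run_")) {
  base <- list(
    synth = list(n_train = 8L, n_test = 2L, image_size = 512L,
                 n_lesions = c(3L, 20L), lesion_radius = c(1, 4),
                 lesion_contrast = c(0.1, 0.4), n_vessels = c(4L, 10L),
                 vessel_width = c(2, 6), fov_radius_frac = 0.95,
                 noise_sigma = 3),
    preprocess = list(patch_size = 64L, clip_limit = 2, gamma = 0.9,
                      nlm_strength = 10, augment = TRUE),
    model = list(in_channels = 1L, base_filters = 32L, depth = 4L,
                 reduction_ratio = 16L, use_cbam = TRUE, use_ag = TRUE),
    train = list(batch_size = 16L, epochs = 40L, lr_init = 1e-3,
                 lr_factor = 0.5, lr_patience = 5L, lr_floor = 1e-5,
                 loss = "bce", val_fraction = 0.1),
    evaluate = list(threshold = 0.5))
  merge_strict <- function(defaults, user, path) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown configuration key", if (length(bad) > 1) "s", " under '",
           path, "': ", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(synth = merge_strict(base$synth, synth, "synth"),
              preprocess = merge_strict(base$preprocess, preprocess,
                                        "preprocess"),
              model = merge_strict(base$model, model, "model"),
              train = merge_strict(base$train, train, "train"),
              evaluate = merge_strict(base$evaluate, evaluate, "evaluate"),
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "masegnet_run_config")
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file.
#' @return a `masegnet_run_config` (`read_run_config`); `path`
#'   (`write_run_config`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("synth", "preprocess", "model", "train", "evaluate", "seed",
             "out_dir")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown top-level configuration key",
         if (length(bad) > 1) "s", ": ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a `masegnet_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

stage_cached <- function(dir, stage, hash) {
  meta <- file.path(dir, paste0(stage, ".hash"))
  rds <- file.path(dir, paste0(stage, ".rds"))
  file.exists(meta) && file.exists(rds) && readLines(meta, warn = FALSE)[1] == hash
}

stage_store <- function(dir, stage, hash, value) {
  saveRDS(value, file.path(dir, paste0(stage, ".rds")))
  writeLines(hash, file.path(dir, paste0(stage, ".hash")))
  value
}

stage_load <- function(dir, stage) readRDS(file.path(dir, paste0(stage, ".rds")))

patch_stack <- function(tiles) {
  p <- dim(tiles[[1L]])[1L]
  array(unlist(tiles, use.names = FALSE), c(p, p, length(tiles)))
}

#' Run the full pipeline
#'
#' Executes synthesis, preprocessing, patch extraction, augmentation,
#' training and evaluation.  Every stage is cached under `out_dir` keyed on
#' the configuration that produced it, so a rerun with an unchanged
#' configuration loads all stages from cache.  A `manifest.json` in
#' `out_dir` records stage hashes and the patch arithmetic
#' (patches per image, train/test patch counts, count after augmentation).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list with `metrics`, `history`, `model`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "masegnet_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
  stage_hashes <- list()
  run_stage <- function(stage, cfg_slice, fn) {
    h <- config_hash(cfg_slice)
    stage_hashes[[stage]] <<- h
    if (stage_cached(config$out_dir, stage, h)) {
      say(stage, ": cache hit")
      stage_load(config$out_dir, stage)
    } else {
      say(stage, ": running")
      tryCatch(stage_store(config$out_dir, stage, h, fn()),
               error = function(e) stop("stage '", stage, "' failed: ",
                                        conditionMessage(e), call. = FALSE))
    }
  }
  # synthesis
  sy <- config$synth
  data <- run_stage("synth", list(sy, config$seed), function() {
    sc <- synth_config(image_size = sy$image_size, n_lesions = sy$n_lesions,
                       lesion_radius = sy$lesion_radius,
                       lesion_contrast = sy$lesion_contrast,
                       n_vessels = sy$n_vessels,
                       vessel_width = sy$vessel_width,
                       fov_radius_frac = sy$fov_radius_frac,
                       noise_sigma = sy$noise_sigma, seed = config$seed)
    n <- sy$n_train + sy$n_test
    lapply(seq_len(n), function(i) {
      ci <- sc; ci$seed <- sc$seed + i
      fx <- generate_fundus(ci)
      fx$split <- if (i <= sy$n_train) "train" else "test"
      fx
    })
  })
  # preprocessing
  pp <- config$preprocess
  prep <- run_stage("preprocess", list(sy, pp[setdiff(names(pp), "augment")],
                                       config$seed), function() {
    lapply(data, function(d) {
      pr <- preprocess_pair(d$image, d$mask, size = sy$image_size,
                            clip_limit = pp$clip_limit, gamma = pp$gamma,
                            nlm_strength = pp$nlm_strength)
      pr$split <- d$split
      pr
    })
  })
  # patch extraction
  patches <- run_stage("patches", list(stage_hashes$preprocess,
                                       pp$patch_size), function() {
    per_image <- lapply(prep, function(d) {
      list(img = extract_patches(d$image, pp$patch_size)$patches,
           msk = extract_patches(d$mask, pp$patch_size)$patches,
           split = d$split)
    })
    tr <- per_image[vapply(per_image, `[[`, "", "split") == "train"]
    te <- per_image[vapply(per_image, `[[`, "", "split") == "test"]
    list(train_img = do.call(c, lapply(tr, `[[`, "img")),
         train_msk = do.call(c, lapply(tr, `[[`, "msk")),
         test_img = do.call(c, lapply(te, `[[`, "img")),
         test_msk = do.call(c, lapply(te, `[[`, "msk")),
         patches_per_image = length(per_image[[1L]]$img))
  })
  # augmentation
  aug <- run_stage("augment", list(stage_hashes$patches, pp$augment),
                   function() {
    if (pp$augment)
      augment_pairs(patches$train_img, patches$train_msk)
    else
      list(images = patches$train_img, masks = patches$train_msk,
           op = rep("original", length(patches$train_img)))
  })
  manifest <- list(
    stages = stage_hashes,
    n_images = length(data),
    n_train_images = sum(vapply(data, `[[`, "", "split") == "train"),
    n_test_images = sum(vapply(data, `[[`, "", "split") == "test"),
    patches_per_image = patches$patches_per_image,
    n_train_patches = length(patches$train_img),
    n_test_patches = length(patches$test_img),
    n_train_patches_augmented = length(aug$images))
  # training
  tr_cfg <- config$train
  trained <- run_stage("train", list(stage_hashes$augment, tr_cfg,
                                     config$model, config$seed), function() {
    mc <- do.call(model_config, config$model)
    model <- build_model(mc, seed = config$seed)
    tc <- train_config(batch_size = tr_cfg$batch_size,
                       epochs = tr_cfg$epochs, lr_init = tr_cfg$lr_init,
                       lr_factor = tr_cfg$lr_factor,
                       lr_patience = tr_cfg$lr_patience,
                       lr_floor = tr_cfg$lr_floor, loss = tr_cfg$loss,
                       val_fraction = tr_cfg$val_fraction,
                       seed = config$seed)
    fit <- train_model(model, patch_stack(aug$images),
                       patch_stack(aug$masks), tc)
    utils::write.csv(fit$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    fit
  })
  # evaluation
  ev <- config$evaluate
  metrics <- run_stage("evaluate", list(stage_hashes$train, ev), function() {
    probs <- lapply(seq_along(patches$test_img), function(i) {
      model_forward(trained$model,
                    as_batch1(patches$test_img[[i]]))$out[, , 1L, 1L]
    })
    evaluate_predictions(probs, patches$test_msk, threshold = ev$threshold)
  })
  metrics_to_json(metrics, file.path(config$out_dir, "metrics.json"))
  manifest$metrics <- list(dice = metrics$dice, iou = metrics$iou,
                           accuracy = metrics$accuracy, auc = metrics$auc)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(metrics = metrics, history = trained$history, model = trained$model,
       manifest = manifest)
}

#' Ablation driver
#'
#' Runs the pipeline once per configuration variant and collects
#' pixel-level Dice/IoU in a comparison table.  The default grid covers
#' the four structural variants (attention gates on/off crossed with the
#' 512- and 256-filter bottlenecks).
#'
#' @param config base [run_config()].
#' @param grid data.frame with any of the columns `use_ag` (logical),
#'   `bottleneck` (512 or 256), `batch_size`, `patch_size`, `loss`.
#' @param verbose print progress.
#' @return data.frame: one row per variant with `label`, `dice`, `iou`,
#'   `n_parameters`; also written to `ablation.csv` under the base
#'   `out_dir`.
#' @export
run_ablation <- function(config = run_config(),
                         grid = data.frame(
                           use_ag = c(TRUE, FALSE, TRUE, FALSE),
                           bottleneck = c(512L, 512L, 256L, 256L)),
                         verbose = FALSE) {
  stopifnot(inherits(config, "masegnet_run_config"))
  if (!nrow(grid)) stop("empty ablation grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- config
    lab <- character(0)
    if ("use_ag" %in% names(grid)) {
      ci$model$use_ag <- grid$use_ag[i]
      lab <- c(lab, if (grid$use_ag[i]) "CBAM+AG" else "CBAM")
    }
    if ("bottleneck" %in% names(grid)) {
      bn <- grid$bottleneck[i]
      base <- bn / 2^ci$model$depth
      if (base < 1 || base != round(base))
        stop("bottleneck ", bn, " incompatible with depth ", ci$model$depth)
      ci$model$base_filters <- as.integer(base)
      lab <- c(lab, paste0("bottleneck ", bn))
    }
    if ("batch_size" %in% names(grid)) {
      ci$train$batch_size <- grid$batch_size[i]
      lab <- c(lab, paste0("batch ", grid$batch_size[i]))
    }
    if ("patch_size" %in% names(grid)) {
      ps <- grid$patch_size[i]
      if (ps %% 2^ci$model$depth != 0)
        stop("patch size ", ps, " not divisible by 2^depth")
      ci$preprocess$patch_size <- as.integer(ps)
      lab <- c(lab, paste0("patch ", ps))
    }
    if ("loss" %in% names(grid)) {
      ci$train$loss <- grid$loss[i]
      lab <- c(lab, paste0("loss ", grid$loss[i]))
    }
    ci$out_dir <- file.path(config$out_dir, paste0("ablation_", i))
    res <- run_pipeline(ci, verbose = verbose)
    data.frame(label = paste(lab, collapse = ", "),
               dice = res$metrics$dice, iou = res$metrics$iou,
               auc = res$metrics$auc,
               n_parameters = n_parameters(res$model))
  })
  out <- do.call(rbind, rows)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(config$out_dir, "ablation.csv"),
                   row.names = FALSE)
  out
}
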