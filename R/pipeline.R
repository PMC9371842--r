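# Pipeline orchestration: validated run configs, the three stages
# (pretrain -> train -> evaluate/detect), self-describing checkpoints, run
# manifests, and the toy-scale mask-ratio ablation.

#' Build and validate a run configuration
#'
#' Merges user settings over the desk-scale defaults and validates ranges.
#' Settings (defaults): generator — `n_images` (200), `width`/`height` (64),
#' `n_classes` (1), `noise_sigma` (0.05), `lesions_range` (c(1, 3)),
#' `axes_range` (c(2, 8)); patching — `patch_size` (16), `mask_ratio` (0.75);
#' reconstruction — `enc_width` (32), `enc_depth` (2), `dec_width` (16),
#' `dec_depth` (1), `pretrain_epochs` (20), `loss_on` ("all");
#' backbone/detector — `base_channels` (32), `stage_depths` (c(1, 1)),
#' `window_size` (4), `heads` (1), `attention_scale` ("sqrt"), `neck_width`
#' (32), `n_anchors` (3), `backbone_init` ("pretrained" or "random");
#' optimizer — `lr` (1e-4), `batch_size` (32), `weight_decay` (5e-4),
#' `train_epochs` (40); misc — `seed` (1), `conf_thr` (0.25), `nms_iou` (0.45).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list of class `lesiondet_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n_images = 200, width = 64, height = 64, n_classes = 1,
    noise_sigma = 0.05, lesions_range = c(1, 3), axes_range = c(2, 8),
    patch_size = 8, mask_ratio = 0.75,
    enc_width = 32, enc_depth = 2, dec_width = 16, dec_depth = 1,
    pretrain_epochs = 20, loss_on = "all",
    base_channels = 32, stage_depths = c(1, 1), window_size = 4, heads = 1,
    attention_scale = "sqrt", neck_width = 32, n_anchors = 3,
    backbone_init = "pretrained",
    lr = 1e-4, pretrain_lr = NULL, train_lr = NULL,
    batch_size = 32, weight_decay = 5e-4, train_epochs = 40,
    loss_weights = c(iou = 2, cls = 1, obj = 1, pos = 10),
    seed = 1, conf_thr = 0.25, nms_iou = 0.45, eval_conf_thr = 0.001,
    eval_every = 10
  ), config)
  if (cfg$mask_ratio <= 0 || cfg$mask_ratio >= 1) {
    stopf("mask_ratio must be in (0,1), got %g", cfg$mask_ratio)
  }
  if (cfg$lr <= 0) stopf("lr must be positive")
  if (is.null(cfg$pretrain_lr)) cfg$pretrain_lr <- cfg$lr
  if (is.null(cfg$train_lr)) cfg$train_lr <- cfg$lr
  lw <- unlist(cfg$loss_weights)
  if (is.null(names(lw)) || !all(nzchar(names(lw)))) {
    names(lw) <- c("iou", "cls", "obj", "pos")[seq_along(lw)]
  }
  cfg$loss_weights <- lw
  if (cfg$patch_size < 1) stopf("patch_size must be >= 1")
  if (!cfg$backbone_init %in% c("pretrained", "random", "reconstructed")) {
    stopf("backbone_init must be pretrained, random or reconstructed")
  }
  if (!cfg$attention_scale %in% c("sqrt", "linear")) {
    stopf("attention_scale must be sqrt or linear")
  }
  structure(cfg, class = "lesiondet_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash over the JSON text, kept within 32-bit range
  h <- 216613626
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(path, cfg, metrics = NULL) {
  man <- list(config = unclass(cfg), config_hash = config_hash(cfg),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("lesiondet")),
              metrics = metrics)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Detach ad parameter nodes to plain values for serialization, and restore.
detach_params <- function(x) {
  if (inherits(x, "ad")) return(structure(list(value = ad_value(x)), class = "ad_detached"))
  if (is.list(x)) {
    out <- lapply(x, detach_params)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

restore_params <- function(x) {
  if (inherits(x, "ad_detached")) return(ad_param(x$value))
  if (is.list(x)) {
    out <- lapply(x, restore_params)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

#' Save / load a self-describing checkpoint
#'
#' Checkpoints embed the detached parameter values, the full run config and the
#' seed, so evaluation and detection never need the original YAML. The
#' container round-trips exactly.
#'
#' @param object A `lesiondet_mae` or `lesiondet_fit`.
#' @param path File path.
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` the object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(detach_params(object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  restore_params(readRDS(path))
}

pipeline_bundle <- function(cfg) {
  gen <- generator_config(width = cfg$width, height = cfg$height,
                          n_classes = cfg$n_classes,
                          lesions_range = cfg$lesions_range,
                          noise_sigma = cfg$noise_sigma,
                          axes_range = cfg$axes_range)
  generate_dataset(cfg$n_images, gen, seed = cfg$seed)
}

#' Run the pretraining stage
#'
#' Generates (or accepts) the dataset and pretrains the masked autoencoder.
#'
#' @param config A [run_config()] (list or YAML path accepted).
#' @param data Optional `lesiondet_bundle`; generated from the config when NULL.
#' @param out Optional checkpoint path; a manifest is written next to it.
#' @return A `lesiondet_mae`.
#' @export
run_pretrain <- function(config = list(), data = NULL, out = NULL) {
  cfg <- run_config(config)
  if (is.null(data)) data <- pipeline_bundle(cfg)
  mae <- pretrain(data, list(
    patch_size = cfg$patch_size, mask_ratio = cfg$mask_ratio,
    enc_width = cfg$enc_width, enc_depth = cfg$enc_depth,
    dec_width = cfg$dec_width, dec_depth = cfg$dec_depth, heads = cfg$heads,
    epochs = cfg$pretrain_epochs, batch_size = cfg$batch_size,
    lr = cfg$pretrain_lr,
    weight_decay = cfg$weight_decay, loss_on = cfg$loss_on,
    seed = derive_seed(cfg$seed, 101)))
  if (!is.null(out)) {
    save_checkpoint(mae, out)
    write_manifest(paste0(out, ".manifest.json"), cfg,
                   metrics = list(final_loss = utils::tail(mae$loss_trace, 1)))
  }
  mae
}

#' Run the detector-training stage
#'
#' @param config A [run_config()].
#' @param pretrain_ckpt A `lesiondet_mae`, a checkpoint path, or NULL. Required
#'   when `backbone_init = "pretrained"` or `"reconstructed"`.
#' @param data Optional bundle (regenerated from the config when NULL).
#' @param out Optional checkpoint path.
#' @return A `lesiondet_fit`.
#' @export
run_train <- function(config = list(), pretrain_ckpt = NULL, data = NULL,
                      out = NULL) {
  cfg <- run_config(config)
  if (is.null(data)) data <- pipeline_bundle(cfg)
  mae <- NULL
  if (!is.null(pretrain_ckpt)) {
    mae <- if (is.character(pretrain_ckpt)) load_checkpoint(pretrain_ckpt) else pretrain_ckpt
  }
  if (cfg$backbone_init %in% c("pretrained", "reconstructed") && is.null(mae)) {
    stopf("backbone_init='%s' requires a pretraining checkpoint", cfg$backbone_init)
  }
  train_data <- data
  if (cfg$backbone_init == "reconstructed" && !is.null(mae)) {
    # wire-up (b): feed the denoised reconstruction to the detector
    recon_split <- function(split, off) lapply(seq_along(split), function(i) {
      im <- split[[i]]
      im$pixels <- clamp(reconstruct_image(im, mae,
                                           seed = derive_seed(cfg$seed, off + i)), 0, 1)
      im
    })
    train_data$train <- recon_split(data$train, 5000)
    train_data$val <- recon_split(data$val, 6000)
    train_data$test <- recon_split(data$test, 7000)
  }
  fit <- train_detector(
    train_data,
    backbone_init = if (cfg$backbone_init == "pretrained") mae else NULL,
    config = list(
      patch_size = cfg$patch_size, base_channels = cfg$base_channels,
      stage_depths = cfg$stage_depths, window_size = cfg$window_size,
      heads = cfg$heads, attention_scale = cfg$attention_scale,
      neck_width = cfg$neck_width, n_classes = cfg$n_classes,
      n_anchors = cfg$n_anchors, epochs = cfg$train_epochs,
      batch_size = cfg$batch_size, lr = cfg$train_lr,
      loss_weights = cfg$loss_weights,
      weight_decay = cfg$weight_decay, eval_every = cfg$eval_every,
      seed = derive_seed(cfg$seed, 202), conf_thr = cfg$conf_thr,
      nms_iou = cfg$nms_iou, eval_conf_thr = cfg$eval_conf_thr))
  if (!is.null(out)) {
    save_checkpoint(fit, out)
    last <- utils::tail(fit$metrics_trace, 1)
    write_manifest(paste0(out, ".manifest.json"), cfg,
                   metrics = list(final_loss = last$loss, val_ap50 = last$ap50))
  }
  fit
}

#' Evaluate a trained detector on the test split
#'
#' @param config A [run_config()].
#' @param fit A `lesiondet_fit` or checkpoint path.
#' @param data Optional bundle (regenerated when NULL).
#' @param split Which split to evaluate (default "test").
#' @param out Optional JSON report path.
#' @return A `lesiondet_eval`.
#' @export
run_evaluate <- function(config = list(), fit, data = NULL, split = "test",
                         out = NULL) {
  cfg <- run_config(config)
  if (is.character(fit)) fit <- load_checkpoint(fit)
  if (is.null(data)) data <- pipeline_bundle(cfg)
  images <- data[[split]]
  dets <- detect_images(fit$detector, images, conf_thr = cfg$eval_conf_thr,
                        iou_thr = cfg$nms_iou)
  rep <- evaluate_detections(dets, gts_as_df(images))
  if (!is.null(out)) {
    jsonlite::write_json(unclass(rep), out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' Detect lesions in a directory of PNG images
#'
#' @param config A [run_config()].
#' @param fit A `lesiondet_fit` or checkpoint path.
#' @param images_dir Directory of PNG files.
#' @param out Output file; format by extension: `.json` for COCO-results JSON,
#'   anything else one YOLO-style text file per image
#'   (`class conf cx cy w h`, normalized) in directory `out`.
#' @return data.frame of detections with a `file` column, invisibly.
#' @export
run_detect <- function(config = list(), fit, images_dir, out = NULL) {
  cfg <- run_config(config)
  if (is.character(fit)) fit <- load_checkpoint(fit)
  files <- sort(list.files(images_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stopf("no PNG images in %s", images_dir)
  images <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3) px <- px[, , 1]
    structure(list(pixels = px, boxes = matrix(numeric(0), ncol = 4),
                   labels = integer(0)), class = "lesiondet_image")
  })
  dets <- detect_images(fit$detector, images, conf_thr = cfg$conf_thr,
                        iou_thr = cfg$nms_iou)
  dets$file <- basename(files)[dets$image_id]
  if (!is.null(out)) {
    if (grepl("\\.json$", out)) {
      res <- lapply(seq_len(nrow(dets)), function(i) {
        d <- dets[i, ]
        list(image_id = d$image_id, category_id = d$class_id,
             bbox = c(d$x1, d$y1, d$x2 - d$x1, d$y2 - d$y1), score = d$conf)
      })
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
    } else {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(files)) {
        di <- dets[dets$image_id == i, , drop = FALSE]
        im <- images[[i]]
        w <- ncol(im$pixels); h <- nrow(im$pixels)
        lines <- if (nrow(di) == 0) character(0) else {
          sprintf("%d %.6f %.6f %.6f %.6f %.6f", di$class_id, di$conf,
                  (di$x1 + di$x2) / 2 / w, (di$y1 + di$y2) / 2 / h,
                  (di$x2 - di$x1) / w, (di$y2 - di$y1) / h)
        }
        writeLines(lines, file.path(out, sub("\\.png$", ".txt", basename(files)[i])))
      }
    }
  }
  invisible(dets)
}

#' Toy-scale mask-ratio ablation
#'
#' For every mask ratio, runs the full pipeline (pretrain with that ratio,
#' train the detector from the pretrained embedding, evaluate validation AP50)
#' under shared seeds, one row per (ratio, seed).
#'
#' @param mask_ratios Strictly increasing ratios in (0,1), length >= 2.
#' @param config Base [run_config()] (its `mask_ratio` is overridden).
#' @param seeds Integer vector of seeds (default the config seed).
#' @param out Optional CSV path.
#' @return data.frame with columns `mask_ratio`, `seed`, `val_ap50`,
#'   `final_pretrain_loss`, `final_train_loss`.
#' @export
run_ablation <- function(mask_ratios, config = list(), seeds = NULL, out = NULL) {
  if (length(mask_ratios) < 2) stopf("need at least 2 mask ratios")
  if (any(diff(mask_ratios) <= 0) || any(mask_ratios <= 0) || any(mask_ratios >= 1)) {
    stopf("mask_ratios must be strictly increasing within (0,1)")
  }
  base <- run_config(config)
  if (is.null(seeds)) seeds <- base$seed
  rows <- list()
  for (seed in seeds) {
    cfg <- base; cfg$seed <- seed
    data <- pipeline_bundle(cfg)
    for (r in mask_ratios) {
      cfg_r <- cfg; cfg_r$mask_ratio <- r
      mae <- run_pretrain(cfg_r, data = data)
      fit <- run_train(cfg_r, pretrain_ckpt = mae, data = data)
      vd <- detect_images(fit$detector, data$val, conf_thr = cfg_r$eval_conf_thr,
                          iou_thr = cfg_r$nms_iou)
      ap50 <- ap_at(vd, gts_as_df(data$val), 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        mask_ratio = r, seed = seed, val_ap50 = ap50,
        final_pretrain_loss = utils::tail(mae$loss_trace, 1),
        final_train_loss = utils::tail(fit$metrics_trace$loss, 1))
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Plot an ablation table (validation AP50 against mask ratio)
#' @param tab data.frame from [run_ablation()].
#' @return A ggplot object.
#' @export
plot_ablation <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mask_ratio, y = .data$val_ap50,
                                    group = .data$seed)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "mask ratio", y = "validation AP50") +
    ggplot2::theme_minimal()
}
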