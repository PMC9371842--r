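# Synthetic small-lesion image generator.
#
# Emulates the regime the detector targets: low-resolution, noisy grayscale
# images containing a handful of small elliptical targets on a smoothly varying
# background. Classes differ in appearance (bright/dark, filled/ring) so the
# classification head has a learnable signal. Everything is seed-deterministic.

#' Generator configuration
#'
#' Bundles the knobs of the synthetic image generator. Defaults describe the
#' desk-scale study conditions used throughout the package: 64x64 grayscale
#' images, 1-3 small bright/dark elliptical lesions of 2 classes, additive
#' Gaussian noise with sd 0.05 on a low-frequency cosine-mixture background.
#'
#' @param width,height Image size in pixels.
#' @param n_classes Number of lesion classes (1-4; classes differ in rendered
#'   appearance).
#' @param lesions_range Integer length-2: inclusive range of lesions per image.
#' @param noise_sigma Standard deviation of the additive Gaussian pixel noise.
#' @param axes_range Length-2: range of ellipse semi-axes in pixels (used when
#'   `size_mode = "custom"`).
#' @param size_mode `"custom"` uses `axes_range`; `"small"` guarantees every
#'   emitted box area < 32^2 px; `"medium"` guarantees 32^2 <= area < 96^2 px
#'   (the small/medium bands of the size-banded AP metrics).
#' @param max_overlap_iou Maximum IoU allowed between two lesion boxes in one
#'   image (placements violating it are rejection-sampled, at most 100 tries).
#' @return A list of class `lesiondet_gencfg`.
#' @export
generator_config <- function(width = 64, height = 64, n_classes = 2,
                             lesions_range = c(1, 3), noise_sigma = 0.05,
                             axes_range = c(2, 8), size_mode = c("custom", "small", "medium"),
                             max_overlap_iou = 0.3) {
  size_mode <- match.arg(size_mode)
  stopifnot(width >= 16, height >= 16, n_classes >= 1, n_classes <= 4,
            length(lesions_range) == 2, lesions_range[1] >= 0,
            lesions_range[2] <= 5, noise_sigma >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_classes = as.integer(n_classes),
                 lesions_range = as.integer(lesions_range),
                 noise_sigma = noise_sigma, axes_range = axes_range,
                 size_mode = size_mode, max_overlap_iou = max_overlap_iou),
            class = "lesiondet_gencfg")
}

# Smooth background: mean grey + 3-component 2-D cosine mixture.
render_background <- function(width, height) {
  xs <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  bg <- matrix(0.45, nrow = height, ncol = width)
  for (k in 1:3) {
    amp <- stats::runif(1, 0.02, 0.06)
    fx <- stats::runif(1, 0.2, 1.5) / width
    fy <- stats::runif(1, 0.2, 1.5) / height
    ph <- stats::runif(1, 0, 2 * pi)
    bg <- bg + amp * cos(2 * pi * (fx * xs + fy * ys) + ph)
  }
  bg
}

# Anti-aliased coverage of a rotated ellipse: alpha ~ signed distance to the
# boundary in pixels, ramped over one pixel. Ring classes hollow the interior.
ellipse_alpha <- function(width, height, cx, cy, a, b, rot, ring = FALSE) {
  xs <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  r <- sqrt((u / a)^2 + (v / b)^2)
  m <- min(a, b)
  alpha <- clamp((1 - r) * m + 0.5, 0, 1)
  if (ring) {
    inner <- clamp((0.55 - r) * m + 0.5, 0, 1)
    alpha <- pmax(alpha - inner, 0)
  }
  alpha
}

# Tight half-open 0-based box around the lit pixels of an alpha mask.
tight_box <- function(alpha) {
  lit <- which(alpha > 1e-6, arr.ind = TRUE)
  if (nrow(lit) == 0) return(NULL)
  c(min(lit[, 2]) - 1, min(lit[, 1]) - 1, max(lit[, 2]), max(lit[, 1]))
}

class_appearance <- function(class_id) {
  # class 0: bright filled; 1: dark filled; 2: bright ring; 3: dark ring
  list(sign = if (class_id %% 2 == 0) 1 else -1, ring = class_id >= 2)
}

sample_axes <- function(cfg) {
  rng <- switch(cfg$size_mode,
                custom = cfg$axes_range,
                small = c(2, 13),
                medium = c(18, 38))
  stats::runif(2, rng[1], rng[2])
}

area_band_ok <- function(area, size_mode) {
  switch(size_mode,
         custom = TRUE,
         small = area < 32^2,
         medium = area >= 32^2 && area < 96^2)
}

#' Generate one synthetic annotated image
#'
#' Renders a smoothly varying background plus additive Gaussian noise, places
#' `n_lesions` anti-aliased elliptical lesions by rejection sampling (pairwise
#' box IoU capped at `max_overlap_iou`, at most 100 attempts per lesion), and
#' emits one tight bounding box per lesion, obtained by scanning the rendered
#' lesion mask for its lit extent.
#'
#' @param width,height Image size in pixels (at least 16).
#' @param n_lesions Number of lesions, 0-5.
#' @param classes Number of classes; class ids are sampled uniformly.
#' @param noise_sigma Gaussian noise sd.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param config Optional [generator_config()] supplying size mode / axes range
#'   and the overlap cap; size-related arguments there override the defaults.
#' @return A list of class `lesiondet_image` with elements `pixels` (height x
#'   width matrix in `[0,1]`), `boxes` (n x 4 matrix, 0-based half-open
#'   `x_min, y_min, x_max, y_max`), `labels` (integer class ids, 0-based).
#' @export
generate_image <- function(width, height, n_lesions, classes, noise_sigma, seed,
                           config = NULL) {
  if (is.null(config)) {
    config <- generator_config(width = max(width, 16), height = max(height, 16),
                               n_classes = classes, noise_sigma = noise_sigma)
  }
  stopifnot(width >= 16, height >= 16, n_lesions >= 0, n_lesions <= 5,
            noise_sigma >= 0, classes >= 1)
  with_seed(seed, {
    bg <- render_background(width, height)
    pixels <- bg
    boxes <- matrix(numeric(0), ncol = 4)
    labels <- integer(0)
    if (n_lesions > 0) {
      for (li in seq_len(n_lesions)) {
        placed <- FALSE
        for (try in seq_len(100)) {
          ax <- sample_axes(config)
          a <- ax[1]; b <- ax[2]
          rot <- stats::runif(1, 0, pi)
          # analytic extent of the rotated ellipse, + 1 px AA margin
          ex <- sqrt((a * cos(rot))^2 + (b * sin(rot))^2) + 1
          ey <- sqrt((a * sin(rot))^2 + (b * cos(rot))^2) + 1
          if (2 * ex + 2 >= width || 2 * ey + 2 >= height) next
          cx <- stats::runif(1, ex + 1, width - ex - 2)
          cy <- stats::runif(1, ey + 1, height - ey - 2)
          cls <- sample.int(classes, 1) - 1L
          app <- class_appearance(cls)
          alpha <- ellipse_alpha(width, height, cx, cy, a, b, rot, ring = app$ring)
          bx <- tight_box(alpha)
          if (is.null(bx)) next
          if (!area_band_ok(box_area(bx), config$size_mode)) next
          if (nrow(boxes) > 0 &&
              any(iou_one_many(bx, boxes) > config$max_overlap_iou)) next
          delta <- app$sign * stats::runif(1, 0.3, 0.5)
          pixels <- pixels + delta * alpha
          boxes <- rbind(boxes, bx)
          labels <- c(labels, cls)
          placed <- TRUE
          break
        }
        if (!placed) {
          stopf("lesion placement failed after 100 rejection samples (image %dx%d, lesion %d)",
                width, height, li)
        }
      }
    }
    if (noise_sigma > 0) {
      pixels <- pixels + matrix(stats::rnorm(width * height, 0, noise_sigma),
                                nrow = height)
    }
    pixels <- clamp(pixels, 0, 1)
    dimnames(boxes) <- NULL
    structure(list(pixels = pixels, boxes = boxes, labels = labels),
              class = "lesiondet_image")
  })
}

#' Generate a train/val/test dataset bundle
#'
#' Splits `n_images` into train/val/test in the fixed 70/15/15 proportion
#' (sizes `round(0.70 n)`, `round(0.15 n)`, remainder). Each image gets its own
#' seed derived deterministically from the master seed, so the bundle is
#' reproducible image-by-image.
#'
#' @param n_images Total number of images (>= 10).
#' @param config A [generator_config()].
#' @param seed Master integer seed.
#' @return A list of class `lesiondet_bundle` with elements `train`, `val`,
#'   `test` (lists of `lesiondet_image`), `class_names`, and `split_fractions`.
#' @export
generate_dataset <- function(n_images, config = generator_config(), seed = 1) {
  if (n_images < 10) stopf("n_images must be >= 10 to give nonempty splits")
  n_train <- round(0.70 * n_images)
  n_val <- round(0.15 * n_images)
  n_test <- n_images - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) stopf("splits would be empty for n_images=%d", n_images)
  imgs <- lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, i)
    nles <- with_seed(derive_seed(seed, i + n_images), {
      sample(config$lesions_range[1]:config$lesions_range[2], 1)
    })
    generate_image(config$width, config$height, nles, config$n_classes,
                   config$noise_sigma, s, config = config)
  })
  cn <- c("bright", "dark", "bright_ring", "dark_ring")[seq_len(config$n_classes)]
  structure(list(train = imgs[seq_len(n_train)],
                 val = imgs[n_train + seq_len(n_val)],
                 test = imgs[n_train + n_val + seq_len(n_test)],
                 class_names = cn,
                 split_fractions = c(0.70, 0.15, 0.15)),
            class = "lesiondet_bundle")
}

box_to_yolo_line <- function(box, label, width, height) {
  cx <- (box[1] + box[3]) / 2 / width
  cy <- (box[2] + box[4]) / 2 / height
  w <- (box[3] - box[1]) / width
  h <- (box[4] - box[2]) / height
  sprintf("%d %.6f %.6f %.6f %.6f", label, cx, cy, w, h)
}

yolo_line_to_box <- function(line, width, height) {
  v <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  cx <- v[2] * width; cy <- v[3] * height
  w <- v[4] * width; h <- v[5] * height
  list(label = as.integer(v[1]),
       box = c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2))
}

#' Write a dataset bundle to disk
#'
#' Writes one 8-bit grayscale PNG per image under `<dir>/<split>/images/` and
#' annotations in either YOLO text format (`<dir>/<split>/labels/<stem>.txt`,
#' one normalized `class cx cy w h` line per box; lesion-free images get an
#' empty file) or a single COCO-style JSON per split. A `manifest.yaml` records
#' the format, class names and per-split file lists.
#'
#' @param bundle A `lesiondet_bundle`.
#' @param directory Output directory (created if needed).
#' @param format `"yolo"` or `"coco"`.
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(bundle, directory, format = c("yolo", "coco")) {
  format <- match.arg(format)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = format, class_names = bundle$class_names, splits = list())
  for (split in c("train", "val", "test")) {
    imgs <- bundle[[split]]
    img_dir <- file.path(directory, split, "images")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    stems <- sprintf("img_%05d", seq_along(imgs))
    coco <- list(images = list(), annotations = list(),
                 categories = lapply(seq_along(bundle$class_names), function(k) {
                   list(id = k - 1L, name = bundle$class_names[k])
                 }))
    ann_id <- 0L
    if (format == "yolo") {
      lab_dir <- file.path(directory, split, "labels")
      dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_along(imgs)) {
      im <- imgs[[i]]
      h <- nrow(im$pixels); w <- ncol(im$pixels)
      png::writePNG(im$pixels, file.path(img_dir, paste0(stems[i], ".png")))
      if (format == "yolo") {
        lines <- character(0)
        if (nrow(im$boxes) > 0) {
          lines <- vapply(seq_len(nrow(im$boxes)), function(j) {
            box_to_yolo_line(im$boxes[j, ], im$labels[j], w, h)
          }, character(1))
        }
        writeLines(lines, file.path(directory, split, "labels", paste0(stems[i], ".txt")))
      } else {
        coco$images[[i]] <- list(id = i, file_name = paste0(stems[i], ".png"),
                                 width = w, height = h)
        if (nrow(im$boxes) > 0) {
          for (j in seq_len(nrow(im$boxes))) {
            ann_id <- ann_id + 1L
            b <- im$boxes[j, ]
            coco$annotations[[ann_id]] <- list(
              id = ann_id, image_id = i, category_id = im$labels[j],
              bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
              area = (b[3] - b[1]) * (b[4] - b[2]), iscrowd = 0L)
          }
        }
      }
    }
    if (format == "coco") {
      jsonlite::write_json(coco, file.path(directory, split, "annotations.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest$splits[[split]] <- list(n = length(imgs), files = paste0(stems, ".png"))
  }
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param directory Dataset directory containing `manifest.yaml`.
#' @return A `lesiondet_bundle` (boxes recovered up to the float precision of
#'   the normalized coordinates for the YOLO format).
#' @export
read_dataset <- function(directory) {
  manifest <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  format <- manifest$format
  out <- list(class_names = unlist(manifest$class_names),
              split_fractions = c(0.70, 0.15, 0.15))
  for (split in c("train", "val", "test")) {
    files <- unlist(manifest$splits[[split]]$files)
    coco <- NULL
    if (format == "coco") {
      coco <- jsonlite::read_json(file.path(directory, split, "annotations.json"))
      by_img <- split(coco$annotations,
                      vapply(coco$annotations, function(a) a$image_id, numeric(1)))
    }
    out[[split]] <- lapply(seq_along(files), function(i) {
      px <- png::readPNG(file.path(directory, split, "images", files[i]))
      if (length(dim(px)) == 3) px <- px[, , 1]
      h <- nrow(px); w <- ncol(px)
      boxes <- matrix(numeric(0), ncol = 4); labels <- integer(0)
      if (format == "yolo") {
        stem <- sub("\\.png$", "", files[i])
        lines <- readLines(file.path(directory, split, "labels", paste0(stem, ".txt")))
        lines <- lines[nzchar(trimws(lines))]
        for (ln in lines) {
          p <- yolo_line_to_box(ln, w, h)
          boxes <- rbind(boxes, p$box); labels <- c(labels, p$label)
        }
      } else {
        anns <- by_img[[as.character(i)]]
        for (a in anns) {
          bb <- unlist(a$bbox)
          boxes <- rbind(boxes, c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]))
          labels <- c(labels, as.integer(a$category_id))
        }
      }
      dimnames(boxes) <- NULL
      structure(list(pixels = px, boxes = boxes, labels = labels),
                class = "lesiondet_image")
    })
  }
  structure(out[c("train", "val", "test", "class_names", "split_fractions")],
            class = "lesiondet_bundle")
}

#' Plot an annotated image with its boxes
#'
#' @param image A `lesiondet_image`.
#' @return A ggplot object (raster image with box outlines, y axis pointing down).
#' @export
plot_annotated_image <- function(image) {
  px <- image$pixels
  df <- data.frame(x = rep(seq_len(ncol(px)) - 0.5, each = nrow(px)),
                   y = rep(seq_len(nrow(px)) - 0.5, times = ncol(px)),
                   v = as.vector(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (nrow(image$boxes) > 0) {
    bx <- as.data.frame(image$boxes)
    names(bx) <- c("x1", "y1", "x2", "y2")
    bx$label <- factor(image$labels)
    p <- p + ggplot2::geom_rect(
      data = bx,
      ggplot2::aes(xmin = .data$x1, xmax = .data$x2, ymin = .data$y1,
                   ymax = .data$y2, colour = .data$label),
      inherit.aes = FALSE, fill = NA, linewidth = 0.4)
  }
  p
}
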