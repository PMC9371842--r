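# Single-stage detection: FPN+PAN neck over the backbone's stage maps,
# anchor-based per-cell prediction heads, YOLO-style box encode/decode,
# class-wise greedy NMS, and the training losses: -ln(IoU) box regression,
# per-class binary cross-entropy classification, and IoU-weighted objectness.

#' Negative-log IoU bounding-box loss
#'
#' `-ln(max(IoU(pred, gt), eps))` with `eps = 1e-7`: zero at perfect overlap,
#' monotone decreasing in IoU, finite (`-ln eps`) for disjoint boxes.
#'
#' @param pred,gt Length-4 boxes `(x_min, y_min, x_max, y_max)`.
#' @return Nonnegative scalar.
#' @export
iou_loss <- function(pred, gt) {
  -log(max(iou(pred, gt), 1e-7))
}

#' Per-class binary cross-entropy classification loss
#'
#' `-sum_k [y_k log p_k + (1 - y_k) log(1 - p_k)]` with `p` clamped to
#' `[eps, 1 - eps]`.
#'
#' @param p Class probabilities (vector on the simplex).
#' @param y One-hot truth vector of the same length.
#' @param eps Clamp bound (default 1e-7).
#' @return Nonnegative scalar; ~0 iff `p == y` before clamping.
#' @export
classification_loss <- function(p, y, eps = 1e-7) {
  stopifnot(length(p) == length(y))
  p <- clamp(p, eps, 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Derive anchor priors from training boxes by k-means
#'
#' Clusters ground-truth (width, height) pairs into `3 * n_levels` priors and
#' assigns them to pyramid levels by ascending area (finest level gets the
#' smallest priors). Falls back to stride-proportional fixed priors when there
#' are too few distinct boxes to cluster.
#'
#' @param boxes Matrix of `(x1, y1, x2, y2)` ground-truth boxes.
#' @param strides Pixel stride of each pyramid level (ascending).
#' @param per_level Priors per level (default 3).
#' @param seed Seed for the k-means restarts.
#' @return List of `n_levels` matrices, each `per_level x 2` of `(w, h)` priors.
#' @export
anchors_from_boxes <- function(boxes, strides, per_level = 3, seed = 1) {
  n_levels <- length(strides)
  k <- per_level * n_levels
  fallback <- lapply(strides, function(s) {
    cbind(w = s * c(0.8, 1.6, 3.2), h = s * c(0.8, 1.6, 3.2))
  })
  if (is.null(boxes) || nrow(boxes) < k) return(fallback)
  wh <- cbind(boxes[, 3] - boxes[, 1], boxes[, 4] - boxes[, 2])
  if (nrow(unique(wh)) < k) return(fallback)
  km <- with_seed(seed, stats::kmeans(wh, centers = k, nstart = 5))
  cen <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(seq_len(n_levels), function(l) {
    m <- cen[(l - 1) * per_level + seq_len(per_level), , drop = FALSE]
    colnames(m) <- c("w", "h")
    m
  })
}

# IoU between two (w,h) shapes centered at the same point.
shape_iou <- function(wh_a, wh_b) {
  inter <- pmin(wh_a[1], wh_b[, 1]) * pmin(wh_a[2], wh_b[, 2])
  inter / (wh_a[1] * wh_a[2] + wh_b[, 1] * wh_b[, 2] - inter)
}

#' Assign ground-truth boxes to (level, cell, anchor) predictors
#'
#' Every ground truth is assigned to the anchor prior (across all levels) with
#' the highest shape IoU against the ground truth's (w, h); the grid cell
#' containing the box center at that level is responsible. Additionally, every
#' other prior with shape IoU >= `multi_iou` also receives the ground truth
#' (set `multi_iou = 1` to disable multi-anchor assignment).
#'
#' @param boxes `n x 4` ground-truth box matrix.
#' @param labels Integer class ids (0-based), length n.
#' @param anchors From [anchors_from_boxes()].
#' @param strides Pixel strides per level.
#' @param grid_shapes List of `(h, w)` grid shapes per level.
#' @param multi_iou Threshold for extra assignments (default 0.5).
#' @return data.frame with columns `gt, level, cell_i, cell_j, anchor` (1-based
#'   except `gt` labels; `cell_i` is the row, `cell_j` the column, 0-based).
#' @export
assign_targets <- function(boxes, labels, anchors, strides, grid_shapes,
                           multi_iou = 0.5) {
  if (is.null(boxes) || nrow(boxes) == 0) {
    return(data.frame(gt = integer(0), level = integer(0), cell_i = integer(0),
                      cell_j = integer(0), anchor = integer(0)))
  }
  out <- list()
  for (g in seq_len(nrow(boxes))) {
    b <- boxes[g, ]
    wh <- c(b[3] - b[1], b[4] - b[2])
    cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
    sious <- numeric(0); lv <- integer(0); an <- integer(0)
    for (l in seq_along(anchors)) {
      s <- shape_iou(wh, anchors[[l]])
      sious <- c(sious, s)
      lv <- c(lv, rep(l, nrow(anchors[[l]])))
      an <- c(an, seq_len(nrow(anchors[[l]])))
    }
    pick <- union(which.max(sious), which(sious >= multi_iou))
    for (p in pick) {
      l <- lv[p]
      ci <- min(floor(cy / strides[l]), grid_shapes[[l]][1] - 1)
      cj <- min(floor(cx / strides[l]), grid_shapes[[l]][2] - 1)
      out[[length(out) + 1L]] <- data.frame(gt = g, level = l, cell_i = ci,
                                            cell_j = cj, anchor = an[p])
    }
  }
  unique(do.call(rbind, out))
}

#' Initialise FPN+PAN neck parameters
#' @param in_channels Channel dims of the backbone stage maps (fine to coarse).
#' @param width Unified neck channel width.
#' @return Parameter list for the neck.
#' @export
neck_params <- function(in_channels, width = 32) {
  n <- length(in_channels)
  list(width = as.integer(width), n_levels = n,
       lateral = lapply(in_channels, function(c) linear_init(c, width)),
       td_fuse = lapply(seq_len(n - 1), function(i) linear_init(width, width)),
       down = lapply(seq_len(n - 1), function(i) linear_init(width, width)),
       bu_fuse = lapply(seq_len(n - 1), function(i) linear_init(width, width)))
}

# nearest-neighbour 2x upsample as a row gather (coarse grid hc x wc -> 2hc x 2wc)
upsample_idx <- function(hc, wc) {
  hf <- 2L * hc; wf <- 2L * wc
  rf <- rep(seq_len(hf), each = wf); cf <- rep(seq_len(wf), times = hf)
  rc <- (rf + 1L) %/% 2L; cc <- (cf + 1L) %/% 2L
  (rc - 1L) * wc + cc
}

# 2x2 average-pool downsample index sets (fine grid hf x wf -> hf/2 x wf/2)
downsample_idx <- function(hf, wf) {
  hc <- hf %/% 2L; wc <- wf %/% 2L
  rf <- rep(seq_len(hc) * 2L - 1L, each = wc)
  cf <- rep(seq_len(wc) * 2L - 1L, times = hc)
  list(tl = (rf - 1L) * wf + cf, tr = (rf - 1L) * wf + cf + 1L,
       bl = rf * wf + cf, br = rf * wf + cf + 1L)
}

# Tape-level FPN+PAN. `maps` is a list of (node, h, w), fine to coarse.
build_neck_node <- function(maps, params) {
  n <- length(maps)
  lat <- lapply(seq_len(n), function(l) {
    list(node = linear_apply(params$lateral[[l]], maps[[l]]$node),
         h = maps[[l]]$h, w = maps[[l]]$w)
  })
  # top-down: coarse-to-fine, upsample + add + fuse
  td <- lat
  for (l in seq(n - 1, 1)) {
    up <- ad_gather_rows(td[[l + 1]]$node, upsample_idx(td[[l + 1]]$h, td[[l + 1]]$w))
    if (2L * td[[l + 1]]$h != td[[l]]$h || 2L * td[[l + 1]]$w != td[[l]]$w) {
      stopf("neck level shapes not in 2x relation: (%d,%d) above (%d,%d)",
            td[[l + 1]]$h, td[[l + 1]]$w, td[[l]]$h, td[[l]]$w)
    }
    fused <- ad_gelu(linear_apply(params$td_fuse[[l]], ad_add(td[[l]]$node, up)))
    td[[l]] <- list(node = fused, h = td[[l]]$h, w = td[[l]]$w)
  }
  # bottom-up: fine-to-coarse, 2x2-mean downsample + add + fuse
  out <- td
  for (l in seq(2, n)) {
    di <- downsample_idx(out[[l - 1]]$h, out[[l - 1]]$w)
    pooled <- ad_scale(ad_add(ad_add(ad_gather_rows(out[[l - 1]]$node, di$tl),
                                     ad_gather_rows(out[[l - 1]]$node, di$tr)),
                              ad_add(ad_gather_rows(out[[l - 1]]$node, di$bl),
                                     ad_gather_rows(out[[l - 1]]$node, di$br))),
                       0.25)
    down <- linear_apply(params$down[[l - 1]], pooled)
    fused <- ad_gelu(linear_apply(params$bu_fuse[[l - 1]],
                                  ad_add(out[[l]]$node, down)))
    out[[l]] <- list(node = fused, h = out[[l]]$h, w = out[[l]]$w)
  }
  out
}

#' Build the FPN+PAN feature pyramid from backbone stage maps
#'
#' Laterals project every stage to the neck width; a top-down pathway
#' (nearest-neighbour upsample + merge) propagates coarse semantics to fine
#' levels, then a bottom-up pathway (2x2 mean-pool downsample + merge)
#' propagates localisation back up. One output per input level.
#'
#' @param stage_maps List of `lesiondet_fmap`, fine to coarse, each half the
#'   previous grid.
#' @param params From [neck_params()].
#' @return List of `lesiondet_fmap`, same grids, all of the neck width.
#' @export
build_neck <- function(stage_maps, params) {
  if (length(stage_maps) < 2) stopf("need at least 2 stage maps")
  maps <- lapply(stage_maps, function(m) {
    list(node = ad_const(m$tokens), h = m$h, w = m$w)
  })
  out <- build_neck_node(maps, params)
  res <- lapply(out, function(o) feature_map(ad_value(o$node), o$h, o$w))
  ad_tape_reset()
  res
}

#' Initialise detection head parameters
#' @param width Neck channel width.
#' @param n_anchors Priors per level.
#' @param n_classes Number of classes.
#' @param n_levels Number of pyramid levels.
#' @return Parameter list: one linear map per level to
#'   `n_anchors * (5 + n_classes)` raw outputs per cell.
#' @export
head_params <- function(width, n_anchors, n_classes, n_levels) {
  list(n_anchors = as.integer(n_anchors), n_classes = as.integer(n_classes),
       maps = lapply(seq_len(n_levels), function(l) {
         list(fc = linear_init(width, width),
              out = linear_init(width, n_anchors * (5 + n_classes), sd = 0.01))
       }))
}

# one hidden GELU layer then the per-cell output map
head_apply <- function(map, x) linear_apply(map$out, ad_gelu(linear_apply(map$fc, x)))

# raw-output column layout for anchor a (1-based), K classes:
# (a-1)*(5+K) + 1:4 = tx,ty,tw,th ; +5 = objectness ; +5+1:K = class logits
head_cols <- function(a, K) {
  base <- (as.integer(a) - 1L) * (5L + as.integer(K))
  list(box = base + 1:4, obj = base + 5L, cls = base + 5L + seq_len(K))
}

#' Decode raw head outputs into detections
#'
#' Per cell and anchor: center `= (cell + sigmoid(t_xy)) * stride`, size
#' `= prior * exp(t_wh)`, objectness `= sigmoid(t_obj)`, class probabilities
#' via softmax. Boxes are clipped to the (padded) image; confidence is
#' `objectness * max class probability`.
#'
#' @param pyramid List of `lesiondet_fmap` from [build_neck()].
#' @param anchors Priors per level (list of `A x 2` matrices).
#' @param head From [head_params()].
#' @param strides Pixel stride per level.
#' @param image_size `(width, height)` for clipping.
#' @param conf_thr Drop detections below this confidence (applied before NMS by
#'   [nms()]; here 0 keeps everything).
#' @return data.frame with `x1,y1,x2,y2,conf,class_id,objectness` plus one
#'   `p<k>` column per class.
#' @export
predict_and_decode <- function(pyramid, anchors, head, strides, image_size,
                               conf_thr = 0) {
  K <- head$n_classes
  rows <- list()
  for (l in seq_along(pyramid)) {
    fm <- pyramid[[l]]
    raw <- ad_run(head_apply(head$maps[[l]], ad_const(fm$tokens)))
    h <- fm$h; w <- fm$w; s <- strides[l]
    cell_i <- rep(seq_len(h) - 1L, each = w)
    cell_j <- rep(seq_len(w) - 1L, times = h)
    for (a in seq_len(head$n_anchors)) {
      cols <- head_cols(a, K)
      t_box <- raw[, cols$box, drop = FALSE]
      obj <- 1 / (1 + exp(-raw[, cols$obj]))
      logits <- raw[, cols$cls, drop = FALSE]
      lmax <- apply(logits, 1, max)
      pe <- exp(logits - lmax)
      probs <- pe / rowSums(pe)
      cx <- (cell_j + 1 / (1 + exp(-t_box[, 1]))) * s
      cy <- (cell_i + 1 / (1 + exp(-t_box[, 2]))) * s
      bw <- anchors[[l]][a, 1] * exp(clamp(t_box[, 3], -6, 6))
      bh <- anchors[[l]][a, 2] * exp(clamp(t_box[, 4], -6, 6))
      x1 <- clamp(cx - bw / 2, 0, image_size[1])
      x2 <- clamp(cx + bw / 2, 0, image_size[1])
      y1 <- clamp(cy - bh / 2, 0, image_size[2])
      y2 <- clamp(cy + bh / 2, 0, image_size[2])
      cls_id <- max.col(probs, ties.method = "first") - 1L
      pmax_cls <- probs[cbind(seq_len(nrow(probs)), cls_id + 1L)]
      conf <- obj * pmax_cls
      df <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, conf = conf,
                       class_id = cls_id, objectness = obj)
      for (k in seq_len(K)) df[[paste0("p", k - 1)]] <- probs[, k]
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$conf >= conf_thr & out$x2 > out$x1 & out$y2 > out$y1, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode a ground-truth box into raw head targets (inverse of decoding)
#' @param box Length-4 ground-truth box.
#' @param cell `(i, j)` 0-based cell of the box center.
#' @param prior `(w, h)` anchor prior.
#' @param stride Level stride.
#' @return Numeric `(tx, ty, tw, th)`.
#' @export
encode_box <- function(box, cell, prior, stride) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  fx <- clamp(cx / stride - cell[2], 1e-6, 1 - 1e-6)
  fy <- clamp(cy / stride - cell[1], 1e-6, 1 - 1e-6)
  c(stats::qlogis(fx), stats::qlogis(fy),
    log((box[3] - box[1]) / prior[1]), log((box[4] - box[2]) / prior[2]))
}

#' Class-wise greedy non-maximum suppression
#'
#' Drops detections below `conf_thr`, sorts by confidence (ties by original
#' index), and iteratively keeps the top detection while removing same-class
#' detections overlapping it with IoU > `iou_thr`.
#'
#' @param dets data.frame with `x1,y1,x2,y2,conf,class_id` (per image).
#' @param iou_thr Suppression overlap threshold in (0,1) (default 0.45).
#' @param conf_thr Confidence floor (default 0.25).
#' @return The surviving rows of `dets`, in descending confidence order.
#' @export
nms <- function(dets, iou_thr = 0.45, conf_thr = 0.25) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  if (is.null(dets) || nrow(dets) == 0) return(dets)
  dets <- dets[dets$conf >= conf_thr, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  alive <- rep(TRUE, nrow(dets))
  B <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(dets))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(nrow(dets)) > i &
                     dets$class_id == dets$class_id[i])
    if (length(later) > 0) {
      ious <- iou_one_many(B[i, ], B[later, , drop = FALSE])
      alive[later[ious > iou_thr]] <- FALSE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- differentiable -ln(IoU) loss on raw box outputs -----------------------

# Custom tape op: t_raw is a P x 4 node of (tx,ty,tw,th); meta holds, per row,
# the cell (i,j), stride, prior (w,h) and ground-truth box. Value is the mean
# -ln(max(IoU, eps)); the gradient is analytic (zero where boxes are disjoint).
ad_box_iou_loss <- function(t_raw, meta) {
  t_raw <- as_ad(t_raw)
  tv <- t_raw$value
  P <- nrow(tv)
  eps <- 1e-7
  sx <- 1 / (1 + exp(-tv[, 1])); sy <- 1 / (1 + exp(-tv[, 2]))
  w <- meta$prior[, 1] * exp(clamp(tv[, 3], -6, 6))
  h <- meta$prior[, 2] * exp(clamp(tv[, 4], -6, 6))
  cx <- (meta$cell[, 2] + sx) * meta$stride
  cy <- (meta$cell[, 1] + sy) * meta$stride
  px1 <- cx - w / 2; px2 <- cx + w / 2
  py1 <- cy - h / 2; py2 <- cy + h / 2
  g <- meta$gt
  ix1 <- pmax(px1, g[, 1]); ix2 <- pmin(px2, g[, 3])
  iy1 <- pmax(py1, g[, 2]); iy2 <- pmin(py2, g[, 4])
  iw <- ix2 - ix1; ih <- iy2 - iy1
  inter <- ifelse(iw > 0 & ih > 0, iw * ih, 0)
  pa <- w * h
  ga <- (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
  uni <- pa + ga - inter
  iouv <- ifelse(inter > 0, inter / uni, 0)
  val <- mean(-log(pmax(iouv, eps)))
  node <- ad_node(val, list(t_raw), function(gout) {
    gt_mat <- matrix(0, P, 4)
    pos <- which(inter > 0)
    for (p in pos) {
      dLdI <- -(1 / inter[p] + 1 / uni[p])
      dLdpa <- 1 / uni[p]
      gpx1 <- dLdI * (-ih[p]) * (px1[p] > g[p, 1]) + dLdpa * (-h[p])
      gpx2 <- dLdI * (ih[p]) * (px2[p] < g[p, 3]) + dLdpa * (h[p])
      gpy1 <- dLdI * (-iw[p]) * (py1[p] > g[p, 2]) + dLdpa * (-w[p])
      gpy2 <- dLdI * (iw[p]) * (py2[p] < g[p, 4]) + dLdpa * (w[p])
      gt_mat[p, 1] <- (gpx1 + gpx2) * meta$stride * sx[p] * (1 - sx[p])
      gt_mat[p, 2] <- (gpy1 + gpy2) * meta$stride * sy[p] * (1 - sy[p])
      gt_mat[p, 3] <- (gpx2 - gpx1) * w[p] / 2
      gt_mat[p, 4] <- (gpy2 - gpy1) * h[p] / 2
    }
    list(gout * gt_mat / P)
  })
  attr(node, "iou_values") <- iouv
  node
}

# ---- full detector ---------------------------------------------------------

#' Initialise a full detector (backbone + neck + head)
#'
#' @param cfg Detector config list; recognised fields with defaults:
#'   `image_size` c(64, 64), `patch_size` 16, `base_channels` 32,
#'   `stage_depths` c(1, 1), `window_size` 4, `heads` 1,
#'   `attention_scale` "sqrt", `neck_width` 32, `n_classes` 1,
#'   `n_anchors` 3.
#' @param anchors Optional anchors (else stride-proportional defaults).
#' @return A list of class `lesiondet_detector` with `backbone`, `neck`,
#'   `head`, `anchors`, `strides`, `cfg`.
#' @export
detector_init <- function(cfg = list(), anchors = NULL) {
  cfg <- utils::modifyList(list(
    image_size = c(64, 64), patch_size = 16, base_channels = 32,
    stage_depths = c(1, 1), window_size = 4, heads = 1,
    attention_scale = "sqrt", neck_width = 32, n_classes = 1, n_anchors = 3
  ), cfg)
  grid <- c(ceiling(cfg$image_size[2] / cfg$patch_size),
            ceiling(cfg$image_size[1] / cfg$patch_size))
  S <- length(cfg$stage_depths)
  strides <- cfg$patch_size * 2^(seq_len(S) - 1)
  backbone <- backbone_params(cfg$patch_size^2, grid,
                              base_channels = cfg$base_channels,
                              stage_depths = cfg$stage_depths,
                              M = cfg$window_size, heads = cfg$heads,
                              attention_scale = cfg$attention_scale)
  in_ch <- cfg$base_channels * 2^(seq_len(S) - 1)
  neck <- neck_params(in_ch, cfg$neck_width)
  head <- head_params(cfg$neck_width, cfg$n_anchors, cfg$n_classes, S)
  if (is.null(anchors)) {
    anchors <- lapply(strides, function(s) {
      cbind(w = s * c(0.5, 1.0, 2.0), h = s * c(0.5, 1.0, 2.0))[seq_len(cfg$n_anchors), , drop = FALSE]
    })
  }
  structure(list(backbone = backbone, neck = neck, head = head,
                 anchors = anchors, strides = strides, cfg = cfg),
            class = "lesiondet_detector")
}

# Tape-level forward from patch tokens to per-level raw head outputs.
detector_forward_node <- function(tokens, det) {
  stages <- hierarchical_forward_node(tokens, det$backbone)
  pyr <- build_neck_node(stages, det$neck)
  lapply(seq_along(pyr), function(l) {
    list(node = head_apply(det$head$maps[[l]], pyr[[l]]$node),
         h = pyr[[l]]$h, w = pyr[[l]]$w)
  })
}

#' Run a detector on one image
#'
#' Full forward pass: patchify, backbone, neck, head, decode, NMS.
#'
#' @param det A `lesiondet_detector`.
#' @param image A `lesiondet_image` or pixel matrix.
#' @param conf_thr,iou_thr NMS thresholds.
#' @return data.frame of surviving detections.
#' @export
detect_image <- function(det, image, conf_thr = 0.25, iou_thr = 0.45) {
  px <- if (inherits(image, "lesiondet_image")) image$pixels else image
  seq <- patchify(px, det$cfg$patch_size)
  stages <- hierarchical_forward(seq, det$backbone)
  pyramid <- build_neck(stages, det$neck)
  dets <- predict_and_decode(pyramid, det$anchors, det$head, det$strides,
                             det$cfg$image_size)
  nms(dets, iou_thr = iou_thr, conf_thr = conf_thr)
}

#' Run a detector over a list of images
#' @param det A `lesiondet_detector`.
#' @param images List of `lesiondet_image`.
#' @param conf_thr,iou_thr NMS thresholds.
#' @return data.frame of detections with an `image_id` column.
#' @export
detect_images <- function(det, images, conf_thr = 0.25, iou_thr = 0.45) {
  rows <- lapply(seq_along(images), function(i) {
    d <- detect_image(det, images[[i]], conf_thr, iou_thr)
    if (nrow(d) == 0) return(NULL)
    cbind(image_id = i, d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), conf = numeric(0),
                      class_id = integer(0), objectness = numeric(0))
  }
  out
}

#' Train the single-stage detector
#'
#' Minimises `w_iou * (-ln IoU) + w_cls * BCE(class) + w_obj * BCE(objectness)`
#' by Adam. Objectness targets are IoU-weighted: a positive predictor's target
#' is its current decoded IoU with its ground truth; all other predictors have
#' target 0. Anchors default to k-means priors over the training boxes.
#' Deterministic given the seed (single-threaded).
#'
#' @param data A `lesiondet_bundle`.
#' @param backbone_init Optional `lesiondet_mae` from [pretrain()]; its patch
#'   projection (and first-stage width) initialises the backbone embedding.
#' @param config List; recognised fields with defaults: the [detector_init()]
#'   fields plus `epochs` (40), `batch_size` (32), `lr` (1e-4),
#'   `weight_decay` (5e-4), `loss_weights` c(iou = 1, cls = 1, obj = 1, pos = 5)
#'   (`pos` is the objectness-BCE weight on positive predictors),
#'   `eval_every` (5), `seed` (1), `conf_thr` (0.25), `nms_iou` (0.45),
#'   `eval_conf_thr` (0.001, the confidence floor used for the validation AP
#'   trace), `multi_anchor_iou` (0.5).
#' @return A list of class `lesiondet_fit`: `detector`, `metrics_trace`
#'   (data.frame epoch/loss and val AP50 at evaluation epochs), `config`.
#' @export
train_detector <- function(data, backbone_init = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    image_size = NULL, patch_size = 16, base_channels = 32,
    stage_depths = c(1, 1), window_size = 4, heads = 1,
    attention_scale = "sqrt", neck_width = 32, n_classes = NULL, n_anchors = 3,
    epochs = 40, batch_size = 32, lr = 1e-4, weight_decay = 5e-4,
    loss_weights = c(iou = 1, cls = 1, obj = 1, pos = 5), eval_every = 5,
    seed = 1, conf_thr = 0.25, nms_iou = 0.45, eval_conf_thr = 0.001,
    multi_anchor_iou = 0.5
  ), config)
  train <- data$train
  if (length(train) == 0) stopf("empty train split")
  if (is.null(cfg$image_size)) {
    cfg$image_size <- c(ncol(train[[1]]$pixels), nrow(train[[1]]$pixels))
  }
  if (is.null(cfg$n_classes)) cfg$n_classes <- length(data$class_names)
  all_boxes <- do.call(rbind, lapply(train, function(im) im$boxes))
  S <- length(cfg$stage_depths)
  strides <- cfg$patch_size * 2^(seq_len(S) - 1)
  anchors <- anchors_from_boxes(all_boxes, strides, cfg$n_anchors,
                                seed = derive_seed(cfg$seed, 17))
  det <- with_seed(derive_seed(cfg$seed, 23), detector_init(cfg, anchors))
  if (!is.null(backbone_init)) {
    mp <- backbone_init$params
    if (mp$enc_width == det$backbone$base_channels &&
        mp$patch_dim == nrow(ad_value(det$backbone$proj$W))) {
      det$backbone$proj$W$value <- ad_value(mp$patch_proj$W)
      det$backbone$proj$b$value <- ad_value(mp$patch_proj$b)
      # transfer encoder transformer blocks into the first-stage block pair:
      # encoder block i -> the W-MSA (odd i) / SW-MSA (even i) halves
      copy_lin <- function(dst, src) {
        if (identical(dim(ad_value(dst$W)), dim(ad_value(src$W)))) {
          dst$W$value <- ad_value(src$W); dst$b$value <- ad_value(src$b)
        }
      }
      copy_ln <- function(dst, src) {
        dst$gamma$value <- ad_value(src$gamma); dst$beta$value <- ad_value(src$beta)
      }
      copy_attn <- function(dst, src) {
        for (nm in c("Wf", "Wg", "Wh", "Wv")) dst[[nm]]$value <- ad_value(src[[nm]])
      }
      bp1 <- det$backbone$stages[[1]]$blocks[[1]]
      enc <- mp$enc_blocks
      if (length(enc) >= 1 && ncol(ad_value(enc[[1]]$attn$Wf)) == bp1$C) {
        copy_ln(bp1$ln1, enc[[1]]$ln1); copy_attn(bp1$attn_w, enc[[1]]$attn)
        copy_ln(bp1$ln2, enc[[1]]$ln2)
        copy_lin(bp1$mlp1$fc1, enc[[1]]$mlp$fc1); copy_lin(bp1$mlp1$fc2, enc[[1]]$mlp$fc2)
        src2 <- if (length(enc) >= 2) enc[[2]] else enc[[1]]
        copy_ln(bp1$ln3, src2$ln1); copy_attn(bp1$attn_sw, src2$attn)
        copy_ln(bp1$ln4, src2$ln2)
        copy_lin(bp1$mlp2$fc1, src2$mlp$fc1); copy_lin(bp1$mlp2$fc2, src2$mlp$fc2)
      }
    } else {
      warning("pretrained embedding width/patch_dim mismatch; using random init",
              call. = FALSE)
    }
  }
  grid_shapes <- lapply(seq_len(S), function(l) {
    c(ceiling(cfg$image_size[2] / strides[l]), ceiling(cfg$image_size[1] / strides[l]))
  })
  seqs <- lapply(train, function(im) patchify(im$pixels, cfg$patch_size))
  assigns <- lapply(train, function(im) {
    assign_targets(im$boxes, im$labels, anchors, strides, grid_shapes,
                   multi_iou = cfg$multi_anchor_iou)
  })
  K <- cfg$n_classes
  params <- list(det$backbone, det$neck, det$head)
  opt <- adam_init(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  trace <- data.frame(epoch = integer(0), loss = numeric(0), ap50 = numeric(0))
  lw <- cfg$loss_weights
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 3000 + ep), sample(length(train)))
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      ad_zero_grad(params)
      for (bi in batch) {
        loss <- detection_loss_node(seqs[[bi]], assigns[[bi]],
                                    train[[bi]], det, K, lw)
        lv <- ad_value(loss)
        if (!is.finite(lv)) stopf("detector training diverged at epoch %d", ep)
        ad_backward(ad_scale(loss, 1 / length(batch)))
        ep_loss <- ep_loss + lv; n_seen <- n_seen + 1
      }
      opt <- adam_step(opt)
    }
    ap50 <- NA_real_
    if (ep %% cfg$eval_every == 0 || ep == cfg$epochs) {
      vd <- detect_images(det, data$val, conf_thr = cfg$eval_conf_thr,
                          iou_thr = cfg$nms_iou)
      ap50 <- ap_at(vd, gts_as_df(data$val), 0.5)
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / max(n_seen, 1),
                                     ap50 = ap50))
  }
  structure(list(detector = det, metrics_trace = trace, config = cfg),
            class = "lesiondet_fit")
}

# Per-image detection loss on the tape:
#   lw_iou * mean over positives of -ln IoU
# + lw_cls * mean over positives of per-class BCE (sum over classes)
# + lw_obj * mean over all cells/anchors of objectness BCE.
detection_loss_node <- function(seq, assign, image, det, K, lw) {
  raws <- detector_forward_node(ad_const(seq$tokens), det)
  box_terms <- list(); cls_terms <- list(); obj_terms <- list()
  n_pos <- max(nrow(assign), 1)
  total_cells <- 0
  for (l in seq_along(raws)) {
    raw <- raws[[l]]
    nc <- raw$h * raw$w
    A <- det$head$n_anchors
    total_cells <- total_cells + nc * A
    pos_l <- assign[assign$level == l, , drop = FALSE]
    obj_t <- matrix(0, nc, A)
    if (nrow(pos_l) > 0) {
      cell_rows <- pos_l$cell_i * raw$w + pos_l$cell_j + 1L
      for (a in sort(unique(pos_l$anchor))) {
        sel <- which(pos_l$anchor == a)
        cols <- head_cols(a, K)
        tb <- ad_cols(ad_gather_rows(raw$node, cell_rows[sel]), cols$box)
        meta <- list(cell = cbind(pos_l$cell_i[sel], pos_l$cell_j[sel]),
                     stride = det$strides[l],
                     prior = det$anchors[[l]][rep(a, length(sel)), , drop = FALSE],
                     gt = image$boxes[pos_l$gt[sel], , drop = FALSE])
        bl <- ad_box_iou_loss(tb, meta)
        box_terms[[length(box_terms) + 1L]] <- ad_scale(bl, length(sel))
        obj_t[cbind(cell_rows[sel], rep(a, length(sel)))] <-
          pmax(attr(bl, "iou_values"), 0.05)
        cls_logits <- ad_cols(ad_gather_rows(raw$node, cell_rows[sel]), cols$cls)
        y <- matrix(0, length(sel), K)
        y[cbind(seq_along(sel), image$labels[pos_l$gt[sel]] + 1L)] <- 1
        cls_terms[[length(cls_terms) + 1L]] <-
          ad_scale(ad_bce_logits(cls_logits, y), length(sel) * K)
      }
    }
    obj_cols <- vapply(seq_len(A), function(a) head_cols(a, K)$obj, integer(1))
    obj_node <- ad_cols(raw$node, obj_cols)
    # positive predictors weighted up against the background majority
    obj_w <- matrix(1, nc, A)
    obj_w[obj_t > 0] <- lw["pos"]
    obj_terms[[length(obj_terms) + 1L]] <-
      ad_scale(ad_bce_logits(obj_node, obj_t, weight = obj_w), nc * A)
  }
  sum_terms <- function(ts) {
    tot <- ts[[1]]
    if (length(ts) > 1) for (i in 2:length(ts)) tot <- ad_add(tot, ts[[i]])
    tot
  }
  total <- ad_scale(sum_terms(obj_terms), unname(lw["obj"]) / total_cells)
  if (length(box_terms) > 0) {
    total <- ad_add(total, ad_scale(sum_terms(box_terms), unname(lw["iou"]) / n_pos))
  }
  if (length(cls_terms) > 0) {
    total <- ad_add(total, ad_scale(sum_terms(cls_terms), unname(lw["cls"]) / n_pos))
  }
  total
}
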