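# Detection evaluation: greedy confidence-descending matching, 101-point
# interpolated average precision, size-banded AP variants, and the composite
# mAP (arithmetic mean of AP50, AP75, AP_S, AP_M, AP_L).
#
# Detections are data.frames with columns image_id, x1, y1, x2, y2, conf and
# optionally class_id; ground truths have image_id, x1, y1, x2, y2 and
# optionally class_id. Boxes are 0-based half-open pixel coordinates.

#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the true label.
#'
#' @param pred_labels,true_labels Equal-length nonempty vectors.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(pred_labels, true_labels) {
  if (length(pred_labels) == 0 || length(pred_labels) != length(true_labels)) {
    stopf("label vectors must be nonempty and of equal length")
  }
  ok <- !is.na(pred_labels) & pred_labels == true_labels
  sum(ok) / length(true_labels)
}

as_det_df <- function(dets) {
  if (is.null(dets) || nrow(dets) == 0) {
    return(data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), conf = numeric(0)))
  }
  if (!"image_id" %in% names(dets)) dets$image_id <- 1L
  dets
}

#' Greedy-match detections to ground truths and build the PR curve
#'
#' Detections are sorted by confidence descending (ties broken by original
#' index); each is matched, within its image, to the not-yet-matched ground
#' truth of highest IoU, provided that IoU >= `iou_thr` (ties: lowest ground
#' truth index). Matched detections are true positives, the rest false
#' positives. Cumulative precision/recall follow, plus the monotone smoothed
#' precision envelope (running maximum from the right).
#'
#' @param dets data.frame with `x1,y1,x2,y2,conf` (+ optional `image_id`,
#'   `class_id`).
#' @param gts data.frame with `x1,y1,x2,y2` (+ optional `image_id`, `class_id`).
#' @param iou_thr Match threshold in (0,1).
#' @param class_aware If TRUE and both frames carry `class_id`, a detection can
#'   only match a ground truth of the same class.
#' @return A list: `order` (row indices of `dets` in rank order), `tp` (logical
#'   per ranked detection), `matched_gt` (index into `gts` or NA), `precision`,
#'   `recall`, `smoothed` (envelope), `n_gt`.
#' @export
pr_points <- function(dets, gts, iou_thr = 0.5, class_aware = FALSE) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  dets <- as_det_df(dets)
  if (is.null(gts)) gts <- data.frame()
  if (nrow(gts) > 0 && !"image_id" %in% names(gts)) gts$image_id <- 1L
  n_gt <- nrow(gts)
  if (nrow(dets) == 0) {
    return(list(order = integer(0), tp = logical(0), matched_gt = integer(0),
                precision = numeric(0), recall = numeric(0),
                smoothed = numeric(0), n_gt = n_gt))
  }
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  gt_taken <- rep(FALSE, n_gt)
  tp <- logical(length(ord))
  matched_gt <- rep(NA_integer_, length(ord))
  for (r in seq_along(ord)) {
    d <- dets[ord[r], ]
    if (n_gt == 0) next
    cand <- which(!gt_taken & gts$image_id == d$image_id)
    if (class_aware && "class_id" %in% names(gts) && "class_id" %in% names(dets)) {
      cand <- cand[gts$class_id[cand] == d$class_id]
    }
    if (length(cand) == 0) next
    ious <- iou_one_many(c(d$x1, d$y1, d$x2, d$y2),
                         as.matrix(gts[cand, c("x1", "y1", "x2", "y2")]))
    best <- which(ious >= iou_thr)
    if (length(best) == 0) next
    # highest IoU, ties to lowest gt index (cand is ascending)
    j <- cand[best[which.max(ious[best])]]
    gt_taken[j] <- TRUE
    tp[r] <- TRUE
    matched_gt[r] <- j
  }
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(ord)
  recall <- if (n_gt > 0) ctp / n_gt else rep(0, length(ord))
  smoothed <- rev(cummax(rev(precision)))
  list(order = ord, tp = tp, matched_gt = matched_gt, precision = precision,
       recall = recall, smoothed = smoothed, n_gt = n_gt)
}

#' Average precision at a fixed IoU threshold (101-point interpolation)
#'
#' The smoothed precision envelope is sampled at the 101 recall levels
#' 0.00, 0.01, ..., 1.00 (precision 0 at unreached recall) and averaged.
#' With no ground truths and no detections the AP is 0 by convention.
#'
#' @inheritParams pr_points
#' @return A number in `[0, 1]`.
#' @export
ap_at <- function(dets, gts, iou_thr = 0.5, class_aware = FALSE) {
  pr <- pr_points(dets, gts, iou_thr, class_aware = class_aware)
  if (pr$n_gt == 0) return(0)
  if (length(pr$recall) == 0) return(0)
  levels <- seq(0, 1, by = 0.01)
  prec_at <- vapply(levels, function(r) {
    ok <- pr$recall >= r - 1e-12
    if (!any(ok)) 0 else max(pr$smoothed[ok])
  }, numeric(1))
  mean(prec_at)
}

size_band <- function(area) {
  ifelse(area < 32^2, "S", ifelse(area < 96^2, "M", "L"))
}

#' Size-banded average precision (AP_S, AP_M, AP_L)
#'
#' AP at `iou_thr` restricted to ground-truth boxes whose pixel area falls in
#' the band: small `[0, 32^2)`, medium `[32^2, 96^2)`, large `[96^2, Inf)`
#' (half-open: area exactly 32^2 is medium). Matching runs on the full sets;
#' detections matched to an out-of-band ground truth are ignored, unmatched
#' detections count as false positives only if their own area lies in the band.
#' A band with no ground truths yields `NA` (undefined).
#'
#' @inheritParams pr_points
#' @return Named numeric vector `c(ap_s, ap_m, ap_l)`, entries `NA` where the
#'   band is empty.
#' @export
ap_by_size <- function(dets, gts, iou_thr = 0.5, class_aware = FALSE) {
  dets <- as_det_df(dets)
  if (is.null(gts)) gts <- data.frame()
  if (nrow(gts) > 0 && !"image_id" %in% names(gts)) gts$image_id <- 1L
  gt_band <- if (nrow(gts) > 0) {
    size_band(box_area(as.matrix(gts[, c("x1", "y1", "x2", "y2")])))
  } else character(0)
  det_band <- if (nrow(dets) > 0) {
    size_band(box_area(as.matrix(dets[, c("x1", "y1", "x2", "y2")])))
  } else character(0)
  pr <- pr_points(dets, gts, iou_thr, class_aware = class_aware)
  out <- c(ap_s = NA_real_, ap_m = NA_real_, ap_l = NA_real_)
  for (b in c("S", "M", "L")) {
    n_gt_b <- sum(gt_band == b)
    key <- paste0("ap_", tolower(b))
    if (n_gt_b == 0) next
    # walk ranked detections: keep TPs matched in-band, FPs whose own area is
    # in-band; ignore the rest
    tp_b <- logical(0); kept <- 0L
    for (r in seq_along(pr$order)) {
      if (pr$tp[r]) {
        if (gt_band[pr$matched_gt[r]] == b) tp_b <- c(tp_b, TRUE)
      } else if (det_band[pr$order[r]] == b) {
        tp_b <- c(tp_b, FALSE)
      }
    }
    if (length(tp_b) == 0) { out[key] <- 0; next }
    ctp <- cumsum(tp_b)
    precision <- ctp / seq_along(tp_b)
    recall <- ctp / n_gt_b
    smoothed <- rev(cummax(rev(precision)))
    levels <- seq(0, 1, by = 0.01)
    prec_at <- vapply(levels, function(rr) {
      ok <- recall >= rr - 1e-12
      if (!any(ok)) 0 else max(smoothed[ok])
    }, numeric(1))
    out[key] <- mean(prec_at)
  }
  out
}

#' Composite mAP: mean of AP50, AP75, AP_S, AP_M, AP_L
#'
#' Undefined components (`NA`, e.g. an empty size band) are dropped from the
#' mean with a warning; all-undefined input is an error.
#'
#' @param components Numeric vector (possibly named) of the five components,
#'   `NA` where undefined.
#' @return The arithmetic mean of the defined components.
#' @export
map_composite <- function(components) {
  def <- components[!is.na(components)]
  if (length(def) == 0) stopf("all mAP components are undefined")
  if (length(def) < length(components)) {
    warning(sprintf("dropping %d undefined mAP component(s) from the mean",
                    length(components) - length(def)), call. = FALSE)
  }
  mean(def)
}

#' Full evaluation report for a detection run
#'
#' Computes classification accuracy over ground truths (a ground truth counts
#' as correctly classified when a detection matched to it at IoU >= 0.5 carries
#' its class; unmatched ground truths count as wrong), AP50, AP75, the three
#' size-banded APs at IoU 0.5, and the composite mAP (mean of the defined
#' components). When `per_class = TRUE` the AP values are macro-averaged over
#' the classes present in the ground truth.
#'
#' @param dets,gts Detection / ground-truth data.frames (see [pr_points()]).
#' @param per_class Macro-average APs over ground-truth classes (default TRUE
#'   when class columns are present).
#' @return A list of class `lesiondet_eval` with fields `accuracy`, `ap50`,
#'   `ap75`, `ap_s`, `ap_m`, `ap_l`, `map_composite`, `n_gt`, `n_det`.
#' @export
evaluate_detections <- function(dets, gts,
                                per_class = !is.null(gts$class_id) &&
                                  length(unique(gts$class_id)) > 1) {
  dets <- as_det_df(dets)
  if (nrow(gts) > 0 && !"image_id" %in% names(gts)) gts$image_id <- 1L
  ap_fun <- function(thr) {
    if (per_class) {
      cls <- sort(unique(gts$class_id))
      mean(vapply(cls, function(k) {
        ap_at(dets[dets$class_id == k, , drop = FALSE],
              gts[gts$class_id == k, , drop = FALSE], thr)
      }, numeric(1)))
    } else {
      ap_at(dets, gts, thr)
    }
  }
  ap50 <- ap_fun(0.5)
  ap75 <- ap_fun(0.75)
  bands <- if (per_class) {
    cls <- sort(unique(gts$class_id))
    bb <- vapply(cls, function(k) {
      ap_by_size(dets[dets$class_id == k, , drop = FALSE],
                 gts[gts$class_id == k, , drop = FALSE], 0.5)
    }, numeric(3))
    apply(bb, 1, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  } else {
    ap_by_size(dets, gts, 0.5)
  }
  # classification accuracy via class-agnostic matching at IoU 0.5
  acc <- NA_real_
  if (nrow(gts) > 0 && "class_id" %in% names(gts) && "class_id" %in% names(dets)) {
    pr <- pr_points(dets, gts, 0.5, class_aware = FALSE)
    pred <- rep(NA_integer_, nrow(gts))
    hit <- which(pr$tp)
    pred[pr$matched_gt[hit]] <- dets$class_id[pr$order[hit]]
    acc <- accuracy(ifelse(is.na(pred), -1L, pred), gts$class_id)
  }
  comp <- suppressWarnings(map_composite(c(ap50, ap75, bands)))
  structure(list(accuracy = acc, ap50 = ap50, ap75 = ap75,
                 ap_s = unname(bands[1]), ap_m = unname(bands[2]),
                 ap_l = unname(bands[3]), map_composite = comp,
                 n_gt = nrow(gts), n_det = nrow(dets)),
            class = "lesiondet_eval")
}

#' @export
print.lesiondet_eval <- function(x, ...) {
  cat("Detection evaluation (", x$n_det, " detections vs ", x$n_gt,
      " ground truths)\n", sep = "")
  fmt <- function(v) if (is.na(v)) "  NA " else sprintf("%.4f", v)
  cat("  accuracy     ", fmt(x$accuracy), "\n")
  cat("  AP50         ", fmt(x$ap50), "\n")
  cat("  AP75         ", fmt(x$ap75), "\n")
  cat("  AP_S/M/L     ", fmt(x$ap_s), fmt(x$ap_m), fmt(x$ap_l), "\n")
  cat("  composite mAP", fmt(x$map_composite), "\n")
  invisible(x)
}

#' Ground truths of a bundle split as a data.frame
#' @param images List of `lesiondet_image`.
#' @return data.frame with image_id, x1, y1, x2, y2, class_id.
#' @export
gts_as_df <- function(images) {
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (nrow(im$boxes) == 0) return(NULL)
    data.frame(image_id = i, x1 = im$boxes[, 1], y1 = im$boxes[, 2],
               x2 = im$boxes[, 3], y2 = im$boxes[, 4], class_id = im$labels)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), class_id = integer(0))
  }
  out
}

#' Plot a precision-recall curve with its smoothed envelope
#' @param dets,gts As in [pr_points()].
#' @param iou_thr Match threshold.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(dets, gts, iou_thr = 0.5) {
  pr <- pr_points(dets, gts, iou_thr)
  df <- data.frame(recall = pr$recall, precision = pr$precision,
                   smoothed = pr$smoothed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$precision), colour = "grey50") +
    ggplot2::geom_step(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = sprintf("PR curve at IoU %.2f (red: smoothed envelope)",
                                  iou_thr)) +
    ggplot2::theme_minimal()
}
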