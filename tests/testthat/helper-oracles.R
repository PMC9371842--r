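# Brute-force reference implementations used as independent oracles. These are
# deliberately written as plain nested loops, separate from the package's
# vectorised code paths.

# Single-head scaled dot-product attention, triple loop over positions.
oracle_attention <- function(X, params, scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  Wf <- ad_value(params$Wf); Wg <- ad_value(params$Wg)
  Wh <- ad_value(params$Wh); Wv <- ad_value(params$Wv)
  n <- nrow(X); d <- ncol(Wf)
  den <- if (scale == "sqrt") sqrt(d) else d
  Z <- matrix(0, n, ncol(Wv))
  for (t in seq_len(n)) {
    e <- numeric(n)
    for (i in seq_len(n)) {
      ft <- as.numeric(X[t, ] %*% Wf)
      gi <- as.numeric(X[i, ] %*% Wg)
      e[i] <- sum(ft * gi) / den
    }
    a <- exp(e - max(e)); a <- a / sum(a)
    acc <- rep(0, ncol(Wh))
    for (i in seq_len(n)) acc <- acc + a[i] * as.numeric(X[i, ] %*% Wh)
    Z[t, ] <- as.numeric(acc %*% Wv)
  }
  Z
}

# Shifted-window attention by explicitly re-tiling the rolled grid into the
# contiguous sub-windows induced by the shift, then attending per sub-window
# with plain (unmasked) attention.
oracle_shifted_attention <- function(tokens, h, w, M, params) {
  shift <- M %/% 2
  out <- matrix(0, h * w, ncol(tokens))
  # boundaries of contiguous bands in the ORIGINAL grid under the shifted tiling
  bands <- function(n) {
    # window edges at shift + k*M in original coordinates, wrapped
    edges <- sort(unique(c(0, (seq(shift, n, by = M)) %% n, n)))
    edges <- edges[edges <= n]
    starts <- utils::head(edges, -1); ends <- edges[-1]
    Map(function(s, e) seq(s + 1, e), starts, ends)
  }
  for (rb in bands(h)) {
    for (cb in bands(w)) {
      idx <- as.vector(t(outer((rb - 1) * w, cb, "+")))
      sub <- tokens[idx, , drop = FALSE]
      out[idx, ] <- oracle_attention(sub, params)
    }
  }
  out
}

# O(n^2) exhaustive class-wise suppression.
oracle_nms <- function(dets, iou_thr, conf_thr) {
  dets <- dets[dets$conf >= conf_thr, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    for (k in kept) {
      if (dets$class_id[k] == dets$class_id[i] &&
          iou(as.numeric(dets[k, c("x1", "y1", "x2", "y2")]),
              as.numeric(dets[i, c("x1", "y1", "x2", "y2")])) > iou_thr) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- dets[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Greedy confidence-descending matching, plain loops.
oracle_match <- function(dets, gts, iou_thr) {
  if (!"image_id" %in% names(dets) && nrow(dets) > 0) dets$image_id <- 1L
  if (!"image_id" %in% names(gts) && nrow(gts) > 0) gts$image_id <- 1L
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(length(ord)); mg <- rep(NA_integer_, length(ord))
  for (r in seq_along(ord)) {
    d <- dets[ord[r], ]
    best_iou <- -1; best_j <- NA
    for (j in seq_len(nrow(gts))) {
      if (taken[j] || gts$image_id[j] != d$image_id) next
      v <- iou(as.numeric(d[c("x1", "y1", "x2", "y2")]),
               as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v >= iou_thr && v > best_iou + 1e-15) { best_iou <- v; best_j <- j }
    }
    if (!is.na(best_j)) { tp[r] <- TRUE; mg[r] <- best_j; taken[best_j] <- TRUE }
  }
  list(order = ord, tp = tp, matched_gt = mg)
}

# 101-point AP from scratch (loops, no envelope vector tricks).
oracle_ap <- function(dets, gts, iou_thr) {
  if (nrow(gts) == 0) return(0)
  if (nrow(dets) == 0) return(0)
  m <- oracle_match(dets, gts, iou_thr)
  ctp <- cumsum(m$tp)
  prec <- ctp / seq_along(m$tp)
  rec <- ctp / nrow(gts)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_along(rec)) if (rec[i] >= r - 1e-12 && prec[i] > best) best <- prec[i]
    total <- total + best
  }
  total / 101
}

# Random toy detection scene (boxes in a 100x100 image).
random_scene <- function(seed, n_img = 2, max_gt = 4, max_det = 6) {
  set.seed(seed)
  rand_box <- function() {
    x1 <- runif(1, 0, 80); y1 <- runif(1, 0, 80)
    c(x1, y1, x1 + runif(1, 4, 20), y1 + runif(1, 4, 20))
  }
  gts <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    n <- sample.int(max_gt, 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      b <- rand_box()
      data.frame(image_id = im, x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
                 class_id = sample(0:1, 1))
    }))
  }))
  dets <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    n <- sample.int(max_det, 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      # half the detections perturb a ground truth, half are random
      if (runif(1) < 0.5 && nrow(gts[gts$image_id == im, ]) > 0) {
        g <- gts[gts$image_id == im, ][sample.int(sum(gts$image_id == im), 1), ]
        b <- as.numeric(g[c("x1", "y1", "x2", "y2")]) + rnorm(4, 0, 3)
        b <- c(min(b[1], b[3] - 1), min(b[2], b[4] - 1), max(b[1] + 1, b[3]), max(b[2] + 1, b[4]))
      } else {
        b <- rand_box()
      }
      data.frame(image_id = im, x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
                 conf = runif(1), class_id = sample(0:1, 1))
    }))
  }))
  list(gts = gts, dets = dets)
}

# Small dataset bundle for training smoke tests.
tiny_bundle <- function(n = 12, w = 32, h = 32, classes = 1, seed = 1,
                        noise = 0.05) {
  gen <- generator_config(width = w, height = h, n_classes = classes,
                          lesions_range = c(1, 2), noise_sigma = noise,
                          axes_range = c(2, 5))
  generate_dataset(n, gen, seed = seed)
}
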