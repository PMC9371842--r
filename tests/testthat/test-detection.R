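test_that("iou matches forced arithmetic and is symmetric", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  set.seed(1)
  for (i in 1:20) {
    a <- c(runif(2, 0, 5), runif(2, 6, 12))
    b <- c(runif(2, 0, 5), runif(2, 6, 12))
    expect_equal(iou(a, b), iou(b, a))
    expect_gte(iou(a, b), 0); expect_lte(iou(a, b), 1)
  }
})

test_that("iou_loss is -ln(IoU), clamped and monotone", {
  expect_equal(iou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  expect_equal(iou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), -log(1 / 7))
  disjoint <- iou_loss(c(0, 0, 1, 1), c(5, 5, 6, 6))
  expect_equal(disjoint, -log(1e-7))
  expect_true(is.finite(disjoint))
  # monotone decreasing in IoU: slide one box away
  losses <- vapply(seq(0, 1.8, by = 0.2), function(dx) {
    iou_loss(c(dx, 0, 2 + dx, 2), c(0, 0, 2, 2))
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("classification loss matches closed forms and a loop oracle", {
  expect_lt(classification_loss(c(1, 0), c(1, 0)), 1e-5)
  expect_equal(classification_loss(c(0.5, 0.5), c(1, 0)), 2 * log(2),
               tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    K <- sample(2:4, 1)
    p <- runif(K); p <- p / sum(p)
    y <- as.numeric(seq_len(K) == sample.int(K, 1))
    acc <- 0
    for (k in seq_len(K)) {
      pk <- min(max(p[k], 1e-7), 1 - 1e-7)
      acc <- acc - (y[k] * log(pk) + (1 - y[k]) * log(1 - pk))
    }
    expect_lt(abs(classification_loss(p, y) - acc), 1e-6)
    expect_gte(classification_loss(p, y), 0)
  }
})

test_that("nms keeps the higher-confidence box and respects classes", {
  two <- data.frame(x1 = c(0, 0.5), y1 = c(0, 0.5), x2 = c(10, 10.5),
                    y2 = c(10, 10.5), conf = c(0.9, 0.8), class_id = c(0, 0))
  kept <- nms(two, iou_thr = 0.5, conf_thr = 0.25)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)
  two$class_id <- c(0, 1)
  expect_equal(nrow(nms(two, iou_thr = 0.5, conf_thr = 0.25)), 2)
})

test_that("nms agrees with the exhaustive suppression oracle", {
  for (s in 1:8) {
    set.seed(s)
    n <- 50
    x1 <- runif(n, 0, 60); y1 <- runif(n, 0, 60)
    dets <- data.frame(x1 = x1, y1 = y1, x2 = x1 + runif(n, 3, 25),
                       y2 = y1 + runif(n, 3, 25), conf = runif(n),
                       class_id = sample(0:1, n, replace = TRUE))
    got <- nms(dets, iou_thr = 0.45, conf_thr = 0.25)
    want <- oracle_nms(dets, iou_thr = 0.45, conf_thr = 0.25)
    expect_equal(got, want)
  }
})

test_that("box encode/decode round-trips within 1e-4 px", {
  set.seed(3)
  for (i in 1:50) {
    stride <- sample(c(8, 16), 1)
    prior <- runif(2, 4, 30)
    cell <- c(sample(0:6, 1), sample(0:6, 1))
    cx <- (cell[2] + runif(1, 0.02, 0.98)) * stride
    cy <- (cell[1] + runif(1, 0.02, 0.98)) * stride
    w <- runif(1, 3, 40); h <- runif(1, 3, 40)
    gt <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    t <- encode_box(gt, cell, prior, stride)
    dec_cx <- (cell[2] + 1 / (1 + exp(-t[1]))) * stride
    dec_cy <- (cell[1] + 1 / (1 + exp(-t[2]))) * stride
    dec_w <- prior[1] * exp(t[3]); dec_h <- prior[2] * exp(t[4])
    dec <- c(dec_cx - dec_w / 2, dec_cy - dec_h / 2,
             dec_cx + dec_w / 2, dec_cy + dec_h / 2)
    expect_lt(max(abs(dec - gt)), 1e-4)
  }
})

test_that("zero raw head outputs decode to prior-sized boxes at cell centers", {
  det <- suppressWarnings(detector_init(list(image_size = c(32, 32),
                                             patch_size = 8, base_channels = 8,
                                             neck_width = 8, stage_depths = c(1, 1))))
  # zero the head so raw outputs are exactly zero
  for (m in det$head$maps) {
    m$fc$W$value[] <- 0; m$fc$b$value[] <- 0
    m$out$W$value[] <- 0; m$out$b$value[] <- 0
  }
  fm1 <- feature_map(matrix(0, 16, 8), 4, 4)
  fm2 <- feature_map(matrix(0, 4, 8), 2, 2)
  dets <- predict_and_decode(list(fm1, fm2), det$anchors, det$head,
                             det$strides, c(32, 32))
  expect_true(all(abs(dets$objectness - 0.5) < 1e-12))
  d1 <- dets[1, ]  # cell (0,0), level 1, anchor 1
  s <- det$strides[1]; pr <- det$anchors[[1]][1, ]
  expect_equal(c(d1$x1, d1$y1, d1$x2, d1$y2),
               pmax(0, pmin(32, c(0.5 * s - pr[1] / 2, 0.5 * s - pr[2] / 2,
                                  0.5 * s + pr[1] / 2, 0.5 * s + pr[2] / 2))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # all decoded boxes lie inside the image
  expect_true(all(dets$x1 >= 0 & dets$y1 >= 0 & dets$x2 <= 32 & dets$y2 <= 32))
})

test_that("target assignment gives every ground truth at least one predictor", {
  anchors <- list(cbind(w = c(6, 12), h = c(6, 12)),
                  cbind(w = c(24, 40), h = c(24, 40)))
  strides <- c(8, 16)
  grids <- list(c(8, 8), c(4, 4))
  set.seed(4)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    x1 <- runif(n, 0, 40); y1 <- runif(n, 0, 40)
    boxes <- cbind(x1, y1, x1 + runif(n, 4, 22), y1 + runif(n, 4, 22))
    asg <- assign_targets(boxes, rep(0L, n), anchors, strides, grids)
    expect_true(all(seq_len(n) %in% asg$gt))
    expect_true(all(asg$cell_i >= 0 & asg$cell_j >= 0))
  }
  # a GT exactly matching a level-2 prior is assigned to level 2
  b <- matrix(c(0, 0, 24, 24), 1)
  asg <- assign_targets(b, 0L, anchors, strides, grids, multi_iou = 1)
  expect_equal(asg$level, 2L)
  expect_equal(asg$anchor, 1L)
})

test_that("the neck preserves shapes and propagates top-down information", {
  set.seed(5)
  np <- neck_params(c(8, 16), width = 8)
  m1 <- feature_map(matrix(rnorm(16 * 8), 16, 8), 4, 4)
  m2 <- feature_map(matrix(rnorm(4 * 16), 4, 16), 2, 2)
  pyr <- build_neck(list(m1, m2), np)
  expect_length(pyr, 2)
  expect_equal(c(pyr[[1]]$h, pyr[[1]]$w), c(4, 4))
  expect_equal(ncol(pyr[[1]]$tokens), 8)
  expect_equal(ncol(pyr[[2]]$tokens), 8)
  # coarsest input change must reach the finest output
  m2b <- m2; m2b$tokens[1, ] <- m2b$tokens[1, ] + 1
  pyr2 <- build_neck(list(m1, m2b), np)
  expect_false(identical(pyr[[1]]$tokens, pyr2[[1]]$tokens))
  # deterministic
  expect_identical(pyr[[1]]$tokens, build_neck(list(m1, m2), np)[[1]]$tokens)
  expect_error(build_neck(list(m1), np), "at least 2")
})

test_that("the differentiable box loss gradient matches finite differences", {
  set.seed(6)
  tv <- matrix(rnorm(8, 0, 0.5), 2, 4)
  meta <- list(cell = rbind(c(1, 2), c(0, 0)), stride = 8,
               prior = rbind(c(10, 8), c(6, 12)),
               gt = rbind(c(18, 10, 30, 20), c(1, 1, 9, 12)))
  tn <- ad_param(tv)
  node <- lesiondet:::ad_box_iou_loss(tn, meta)
  ad_backward(node)
  g <- tn$grad
  f0 <- function(x) {
    v <- ad_value(lesiondet:::ad_box_iou_loss(ad_const(x), meta))
    ad_tape_reset()
    v
  }
  for (i in seq_along(tv)) {
    e <- 1e-6
    xp <- tv; xm <- tv
    xp[i] <- xp[i] + e; xm[i] <- xm[i] - e
    num <- (f0(xp) - f0(xm)) / (2 * e)
    expect_lt(abs(g[i] - num), 1e-4 * max(1, abs(num)))
  }
})

test_that("detector training runs, is frozen at zero lr, and loss decreases", {
  b <- tiny_bundle(12, w = 32, h = 32, seed = 20)
  cfg <- list(patch_size = 8, base_channels = 8, neck_width = 8,
              stage_depths = c(1, 1), epochs = 2, batch_size = 4,
              eval_every = 2, seed = 1, lr = 0, weight_decay = 0)
  f0 <- train_detector(b, config = cfg)
  expect_lt(diff(range(f0$metrics_trace$loss)), 1e-9)
  cfg$lr <- 5e-3; cfg$epochs <- 6
  f1 <- train_detector(b, config = cfg)
  expect_lt(utils::tail(f1$metrics_trace$loss, 1), f1$metrics_trace$loss[1])
  # deterministic under a fixed seed
  f2 <- train_detector(b, config = cfg)
  expect_identical(f1$metrics_trace, f2$metrics_trace)
  # detections have the documented schema
  d <- detect_images(f1$detector, b$val, conf_thr = 0.001)
  expect_true(all(c("image_id", "x1", "y1", "x2", "y2", "conf", "class_id")
                  %in% names(d)))
})
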