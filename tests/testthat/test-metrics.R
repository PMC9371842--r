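test_that("accuracy is correct / total", {
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 9)), 0.75)
  expect_equal(accuracy(c(1, 1), c(1, 1)), 1)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_error(accuracy(integer(0), integer(0)), "nonempty")
})

test_that("pr_points handles the forced single and double detection cases", {
  gts <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  one <- data.frame(x1 = 0.5, y1 = 0.5, x2 = 10, y2 = 10, conf = 0.9)
  pr <- pr_points(one, gts, 0.5)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  two <- rbind(one, data.frame(x1 = 50, y1 = 50, x2 = 60, y2 = 60, conf = 0.4))
  pr2 <- pr_points(two, gts, 0.5)
  expect_equal(pr2$precision, c(1, 0.5))
  expect_equal(pr2$recall, c(1, 1))
  expect_equal(pr2$smoothed, c(1, 0.5))  # envelope: running max from the right
})

test_that("the smoothed envelope is monotone non-increasing", {
  for (s in 1:20) {
    sc <- random_scene(s)
    pr <- pr_points(sc$dets, sc$gts, 0.5)
    if (length(pr$smoothed) > 1) expect_true(all(diff(pr$smoothed) <= 1e-12))
  }
})

test_that("greedy matching agrees with the brute-force oracle", {
  for (s in 1:60) {
    sc <- random_scene(s)
    pr <- pr_points(sc$dets, sc$gts, 0.5)
    m <- oracle_match(sc$dets, sc$gts, 0.5)
    expect_identical(pr$order, m$order)
    expect_identical(pr$tp, m$tp)
    expect_identical(pr$matched_gt, m$matched_gt)
  }
})

test_that("ap_at matches forced values on canonical detectors", {
  # perfect detector: every GT found first, no false positives
  gts <- data.frame(image_id = 1, x1 = c(0, 20), y1 = c(0, 20),
                    x2 = c(10, 30), y2 = c(10, 30))
  perfect <- data.frame(image_id = 1, x1 = c(0, 20), y1 = c(0, 20),
                        x2 = c(10, 30), y2 = c(10, 30), conf = c(0.9, 0.8))
  expect_equal(ap_at(perfect, gts, 0.5), 1)
  # half the GTs found with perfect precision: AP = 51/101
  half <- perfect[1, , drop = FALSE]
  expect_equal(ap_at(half, gts, 0.5), 51 / 101)
  # no GTs and no detections: AP 0 by convention
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), conf = numeric(0))
  expect_equal(ap_at(empty, gts[0, ], 0.5), 0)
})

test_that("ap_at agrees with an independent loop implementation", {
  for (s in 1:50) {
    sc <- random_scene(s, n_img = 2)
    expect_equal(ap_at(sc$dets, sc$gts, 0.5), oracle_ap(sc$dets, sc$gts, 0.5),
                 tolerance = 1e-6)
    expect_equal(ap_at(sc$dets, sc$gts, 0.75), oracle_ap(sc$dets, sc$gts, 0.75),
                 tolerance = 1e-6)
  }
})

test_that("AP is invariant to strictly increasing confidence rescaling", {
  sc <- random_scene(7)
  base <- ap_at(sc$dets, sc$gts, 0.5)
  r1 <- sc$dets; r1$conf <- plogis(5 * r1$conf - 2)
  r2 <- sc$dets; r2$conf <- r2$conf^3
  expect_equal(ap_at(r1, sc$gts, 0.5), base)
  expect_equal(ap_at(r2, sc$gts, 0.5), base)
})

test_that("duplicating an already-matched detection never raises AP", {
  for (s in 1:10) {
    sc <- random_scene(s)
    base <- ap_at(sc$dets, sc$gts, 0.5)
    dup <- sc$dets[1, ]
    dup$conf <- dup$conf * 0.99
    expect_lte(ap_at(rbind(sc$dets, dup), sc$gts, 0.5), base + 1e-12)
  }
})

test_that("size-banded AP respects the half-open band convention", {
  # exactly 32^2 falls in the middle band
  gts <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(32, 55), y2 = c(32, 55))
  dets <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(32, 55), y2 = c(32, 55),
                     conf = c(0.9, 0.8))
  ap <- ap_by_size(dets, gts, 0.5)
  expect_equal(unname(ap["ap_m"]), 1)   # the 32^2 box
  expect_equal(unname(ap["ap_s"]), 1)   # the 5x5 box
  expect_true(is.na(ap["ap_l"]))
  # all GTs small: ap_s equals overall AP, other bands undefined
  small_gts <- data.frame(x1 = c(0, 20), y1 = c(0, 20), x2 = c(8, 26), y2 = c(8, 26))
  small_dets <- data.frame(x1 = c(0, 20), y1 = c(0.5, 20), x2 = c(8, 27),
                           y2 = c(8, 26), conf = c(0.7, 0.6))
  ap2 <- ap_by_size(small_dets, small_gts, 0.5)
  expect_equal(unname(ap2["ap_s"]), ap_at(small_dets, small_gts, 0.5))
  expect_true(is.na(ap2["ap_m"]) && is.na(ap2["ap_l"]))
})

test_that("size-banded AP agrees with a brute-force banding oracle", {
  band_of <- function(b) {
    a <- (b[3] - b[1]) * (b[4] - b[2])
    if (a < 32^2) "S" else if (a < 96^2) "M" else "L"
  }
  for (s in 1:30) {
    sc <- random_scene(s, n_img = 2, max_gt = 5, max_det = 8)
    got <- ap_by_size(sc$dets, sc$gts, 0.5)
    m <- oracle_match(sc$dets, sc$gts, 0.5)
    for (b in c("S", "M", "L")) {
      gt_in <- vapply(seq_len(nrow(sc$gts)), function(j) {
        band_of(as.numeric(sc$gts[j, c("x1", "y1", "x2", "y2")])) == b
      }, logical(1))
      key <- paste0("ap_", tolower(b))
      if (!any(gt_in)) { expect_true(is.na(got[key])); next }
      tp_b <- logical(0)
      for (r in seq_along(m$order)) {
        if (m$tp[r]) {
          if (gt_in[m$matched_gt[r]]) tp_b <- c(tp_b, TRUE)
        } else {
          d <- sc$dets[m$order[r], ]
          if (band_of(as.numeric(d[c("x1", "y1", "x2", "y2")])) == b) {
            tp_b <- c(tp_b, FALSE)
          }
        }
      }
      if (length(tp_b) == 0) { expect_equal(unname(got[key]), 0); next }
      prec <- cumsum(tp_b) / seq_along(tp_b)
      rec <- cumsum(tp_b) / sum(gt_in)
      total <- 0
      for (rr in seq(0, 1, by = 0.01)) {
        best <- 0
        for (i in seq_along(rec)) {
          if (rec[i] >= rr - 1e-12 && prec[i] > best) best <- prec[i]
        }
        total <- total + best
      }
      expect_equal(unname(got[key]), total / 101, tolerance = 1e-9)
    }
  }
})

test_that("composite mAP averages the defined components", {
  expect_equal(map_composite(c(0.8, 0.8, 0.8, 0.8, 0.8)), 0.8)
  expect_equal(map_composite(c(1.0, 0.5, 0.5, 0.5, 0.5)), 0.6)
  expect_warning(v <- map_composite(c(0.8, 0.8, NA, 0.8, 0.8)), "undefined")
  expect_equal(v, 0.8)
  expect_error(map_composite(c(NA_real_, NA_real_)), "undefined")
})

test_that("evaluate_detections assembles a consistent report", {
  sc <- random_scene(42, n_img = 3, max_gt = 4, max_det = 6)
  rep <- evaluate_detections(sc$dets, sc$gts)
  for (f in c("ap50", "ap75")) {
    expect_gte(rep[[f]], 0); expect_lte(rep[[f]], 1)
  }
  expect_gte(rep$accuracy, 0); expect_lte(rep$accuracy, 1)
  comps <- c(rep$ap50, rep$ap75, rep$ap_s, rep$ap_m, rep$ap_l)
  expect_equal(rep$map_composite, mean(comps[!is.na(comps)]))
  expect_output(print(rep), "composite mAP")
})
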