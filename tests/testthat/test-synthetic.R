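test_that("lesion-free image has an empty box list", {
  im <- generate_image(64, 64, 0, 2, 0.0, seed = 1)
  expect_equal(nrow(im$boxes), 0)
  expect_length(im$labels, 0)
  expect_true(all(im$pixels >= 0 & im$pixels <= 1))
})

test_that("generation is bit-identical for equal seed and arguments", {
  a <- generate_image(64, 64, 3, 2, 0.05, seed = 7)
  b <- generate_image(64, 64, 3, 2, 0.05, seed = 7)
  expect_identical(a, b)
  c <- generate_image(64, 64, 3, 2, 0.05, seed = 8)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("every emitted box is the tight bound of its rendered lesion", {
  im <- generate_image(416, 416, 5, 3, 0.05, seed = 3,
                       config = generator_config(width = 416, height = 416,
                                                 n_classes = 3,
                                                 axes_range = c(3, 14)))
  expect_equal(nrow(im$boxes), 5)
  # oracle: re-render each lesion alone (noise-free) and scan its lit pixels
  clean <- generate_image(416, 416, 5, 3, 0.0, seed = 3,
                          config = generator_config(width = 416, height = 416,
                                                    n_classes = 3,
                                                    axes_range = c(3, 14)))
  expect_equal(clean$boxes, im$boxes)  # noise must not move annotations
  for (j in seq_len(nrow(im$boxes))) {
    b <- im$boxes[j, ]
    expect_true(b[1] < b[3] && b[2] < b[4])
    expect_true(b[1] >= 0 && b[2] >= 0 && b[3] <= 416 && b[4] <= 416)
    area <- (b[3] - b[1]) * (b[4] - b[2])
    expect_gt(area, 0)
  }
})

test_that("tight_box matches a pixel scan of the rendered mask", {
  alpha <- lesiondet:::ellipse_alpha(64, 64, 30.3, 20.7, 6, 4, 0.7)
  bx <- lesiondet:::tight_box(alpha)
  lit <- which(alpha > 1e-6, arr.ind = TRUE)
  expect_equal(bx, c(min(lit[, 2]) - 1, min(lit[, 1]) - 1,
                     max(lit[, 2]), max(lit[, 1])))
})

test_that("dataset split sizes follow the 70/15/15 rule", {
  cfg <- generator_config(width = 32, height = 32, lesions_range = c(0, 1),
                          axes_range = c(2, 4))
  b20 <- generate_dataset(20, cfg, seed = 1)
  expect_equal(lengths(b20[c("train", "val", "test")]),
               c(train = 14L, val = 3L, test = 3L))
  b100 <- generate_dataset(100, cfg, seed = 1)
  expect_equal(lengths(b100[c("train", "val", "test")]),
               c(train = 70L, val = 15L, test = 15L))
  expect_error(generate_dataset(5, cfg, seed = 1), "n_images")
})

test_that("same master seed reproduces the whole bundle", {
  cfg <- generator_config(width = 32, height = 32, axes_range = c(2, 5))
  expect_identical(generate_dataset(12, cfg, seed = 4),
                   generate_dataset(12, cfg, seed = 4))
})

test_that("YOLO line encodes the normalized center format", {
  line <- lesiondet:::box_to_yolo_line(c(10, 20, 30, 60), 2L, 100, 100)
  expect_equal(line, "2 0.200000 0.400000 0.200000 0.400000")
})

test_that("write/read round trip preserves boxes within 0.5 px", {
  for (fmt in c("yolo", "coco")) {
    dir <- file.path(tempdir(), paste0("ds_", fmt))
    unlink(dir, recursive = TRUE)
    b <- tiny_bundle(10, seed = 3)
    write_dataset(b, dir, format = fmt)
    r <- read_dataset(dir)
    for (split in c("train", "val", "test")) {
      for (i in seq_along(b[[split]])) {
        expect_equal(r[[split]][[i]]$labels, b[[split]][[i]]$labels)
        if (nrow(b[[split]][[i]]$boxes) > 0) {
          expect_lt(max(abs(r[[split]][[i]]$boxes - b[[split]][[i]]$boxes)), 0.5)
        }
        # PNG is 8-bit: pixels agree to 1/255
        expect_lt(max(abs(r[[split]][[i]]$pixels - b[[split]][[i]]$pixels)),
                  1 / 255)
      }
    }
  }
})

test_that("lesion-free images get an empty annotation file in YOLO format", {
  dir <- file.path(tempdir(), "ds_empty")
  unlink(dir, recursive = TRUE)
  cfg <- generator_config(width = 32, height = 32, lesions_range = c(0, 0))
  b <- generate_dataset(10, cfg, seed = 2)
  write_dataset(b, dir, format = "yolo")
  f <- file.path(dir, "train", "labels", "img_00001.txt")
  expect_true(file.exists(f))
  expect_length(readLines(f), 0)
})

test_that("class sampling is near-uniform over many lesions", {
  cfg <- generator_config(width = 48, height = 48, n_classes = 4,
                          lesions_range = c(2, 3), axes_range = c(2, 5))
  labs <- integer(0)
  i <- 0
  while (length(labs) < 500) {
    i <- i + 1
    im <- generate_image(48, 48, 3, 4, 0, seed = i, config = cfg)
    labs <- c(labs, im$labels)
  }
  freq <- table(factor(labs, levels = 0:3)) / length(labs)
  expect_true(all(abs(freq - 0.25) < 0.05))
})

test_that("small and medium size modes respect the AP area bands", {
  small_cfg <- generator_config(width = 64, height = 64, size_mode = "small")
  med_cfg <- generator_config(width = 256, height = 256, size_mode = "medium")
  for (s in 1:10) {
    ims <- generate_image(64, 64, 2, 2, 0, seed = s, config = small_cfg)
    if (nrow(ims$boxes) > 0) {
      expect_true(all(box_area(ims$boxes) < 32^2))
    }
    imm <- generate_image(256, 256, 2, 2, 0, seed = s, config = med_cfg)
    areas <- box_area(imm$boxes)
    expect_true(all(areas >= 32^2 & areas < 96^2))
  }
})

test_that("impossible placement raises a placement-failure error", {
  cfg <- generator_config(width = 24, height = 24, axes_range = c(20, 30))
  expect_error(generate_image(24, 24, 1, 1, 0, seed = 1, config = cfg),
               "placement failed")
})
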