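# synthetic scenes, label I/O, splitting, augmentation, mosaic

test_that("scene generation is deterministic and boxes are valid", {
  sp <- scene_spec(img_size = 96, seed = 11)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$boxes$x1 >= 0 & a$boxes$x2 <= 96 &
                    a$boxes$y1 >= 0 & a$boxes$y2 <= 96))
  expect_true(all((a$boxes$x2 - a$boxes$x1) * (a$boxes$y2 - a$boxes$y1) > 0))
  expect_true(all(a$boxes$class_id %in% 0:28))
  # zero objects give an empty label set
  sp0 <- scene_spec(img_size = 96, n_objects = c(0, 0), seed = 1)
  expect_equal(nrow(generate_scene(sp0)$boxes), 0L)
  # different seeds give different scenes
  sp2 <- scene_spec(img_size = 96, seed = 12)
  expect_false(identical(generate_scene(sp2)$image, a$image))
})

test_that("per-class weights control the class frequencies", {
  w <- rep(0, 29); w[3] <- 15; w[7] <- 1
  sp <- scene_spec(img_size = 96, n_objects = c(4, 8), class_weights = w,
                   seed = 2, occlusion_prob = 0)
  counts <- c(`2` = 0, `6` = 0)
  for (s in 1:25) {
    sp$seed <- 100 + s
    cls <- generate_scene(sp)$boxes$class_id
    counts["2"] <- counts["2"] + sum(cls == 2)
    counts["6"] <- counts["6"] + sum(cls == 6)
    expect_true(all(cls %in% c(2, 6)))
  }
  expect_gt(counts["2"], 5 * counts["6"])
})

test_that("YOLO label round-trip preserves normalized coordinates", {
  set.seed(3)
  boxes <- data.frame(class_id = c(0L, 12L, 28L),
                      x1 = c(10.25, 50, 3.5), y1 = c(5.75, 40, 60),
                      x2 = c(30.25, 90, 13.5), y2 = c(25.75, 80, 90))
  p <- tempfile(fileext = ".txt")
  write_yolo_labels(boxes, p, 96, 96)
  back <- read_yolo_labels(p, 96, 96)
  expect_equal(back$class_id, boxes$class_id)
  expect_lt(max(abs(back$cx - (boxes$x1 + boxes$x2) / 2 / 96)), 1e-6)
  expect_lt(max(abs(back$cy - (boxes$y1 + boxes$y2) / 2 / 96)), 1e-6)
  expect_lt(max(abs(back$w - (boxes$x2 - boxes$x1) / 96)), 1e-6)
  expect_lt(max(abs(back$h - (boxes$y2 - boxes$y1) / 96)), 1e-6)
  # empty labels round-trip too
  write_yolo_labels(boxes[0, ], p, 96, 96)
  expect_equal(nrow(read_yolo_labels(p, 96, 96)), 0L)
})

test_that("dataset splitting follows the 7:2:1 ratio and is reproducible", {
  man <- tiny_easy_manifest(n = 10, img_size = 64, seed = 5)
  expect_equal(sum(man$split == "train"), 7L)
  expect_equal(sum(man$split == "test"), 2L)
  expect_equal(sum(man$split == "val"), 1L)
  expect_true(all(file.exists(man$image)))
  expect_true(all(file.exists(man$label)))
  man2 <- tiny_easy_manifest(n = 10, img_size = 64, seed = 5,
                             dir = file.path(tempdir(), "pn_rep"))
  expect_identical(man$split, man2$split)
  expect_error(generate_dataset(5, scene_spec(img_size = 64, seed = 1),
                                tempdir()), "at least 10")
})

test_that("geometric augmentations move boxes consistently", {
  set.seed(6)
  sc <- generate_scene(scene_spec(img_size = 96, preset = "easy", seed = 7))
  # horizontal flip: cx -> 1 - cx in normalized coordinates
  set.seed(1)
  fl <- augment_sample(sc$image, sc$boxes, list(hflip = 1))
  cx0 <- (sc$boxes$x1 + sc$boxes$x2) / 2 / 96
  cx1 <- (fl$boxes$x1 + fl$boxes$x2) / 2 / 96
  expect_equal(cx1, 1 - cx0, tolerance = 1e-12)
  expect_equal(fl$boxes$y1, sc$boxes$y1)
  # 90-degree rotation of a square image: (cx,cy,w,h) -> (cy, 1-cx, h, w)
  set.seed(1)
  rt <- augment_sample(sc$image, sc$boxes, list(rot90 = 1))
  cy0 <- (sc$boxes$y1 + sc$boxes$y2) / 2 / 96
  expect_equal((rt$boxes$x1 + rt$boxes$x2) / 2 / 96, cy0, tolerance = 1e-12)
  expect_equal((rt$boxes$y1 + rt$boxes$y2) / 2 / 96, 1 - cx0, tolerance = 1e-12)
  expect_equal(rt$boxes$x2 - rt$boxes$x1, sc$boxes$y2 - sc$boxes$y1)
  # photometric-only policies leave boxes bit-identical
  set.seed(2)
  ph <- augment_sample(sc$image, sc$boxes,
                       list(brightness = 0.3, contrast = 0.3, noise = 0.05,
                            hue = 0.1))
  expect_identical(ph$boxes, sc$boxes)
  expect_false(identical(ph$image, sc$image))
})

test_that("mosaic collages remap and clip boxes deterministically", {
  sps <- lapply(1:4, function(i)
    generate_scene(scene_spec(img_size = 64, preset = "easy", seed = 20 + i)))
  set.seed(8)
  m1 <- mosaic_collage(sps, 64)
  set.seed(8)
  m2 <- mosaic_collage(sps, 64)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$boxes, m2$boxes)
  expect_equal(dim(m1$image), c(64, 64, 3))
  expect_lte(nrow(m1$boxes), sum(vapply(sps, function(s) nrow(s$boxes), 0L)))
  expect_true(all(m1$boxes$x1 >= -1 & m1$boxes$x2 <= 65))
  # four empty-label tiles give an empty label list
  blank <- lapply(sps, function(s) list(image = s$image, boxes = s$boxes[0, ]))
  set.seed(9)
  expect_equal(nrow(mosaic_collage(blank, 64)$boxes), 0L)
  expect_error(mosaic_collage(sps[1:3], 64), "exactly 4")
})
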