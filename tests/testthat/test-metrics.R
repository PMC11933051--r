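# detection metrics: IoU, greedy matching, P/R, AP envelope, mAP grid,
# confusion matrix

det_df <- function(class_id, x1, y1, x2, y2, conf = 1) {
  data.frame(class_id = class_id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             confidence = conf)
}

test_that("box IoU matches hand values and rejects degenerate boxes", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching enforces one-to-one class-aware assignment", {
  gts <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  perfect <- det_df(0L, 0, 0, 10, 10)
  m <- match_detections(perfect, gts, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
  empty <- det_df(integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
                  numeric(0))
  m0 <- match_detections(empty, gts, 0.5)
  expect_equal(c(m0$TP, m0$FN), c(0L, 1L))
  # two detections on one gt: only one true positive
  two <- det_df(c(0L, 0L), c(0, 0.5), c(0, 0.5), c(10, 10.5), c(10, 10.5),
                conf = c(0.9, 0.8))
  m2 <- match_detections(two, gts, 0.5)
  expect_equal(c(m2$TP, m2$FP), c(1L, 1L))
  # class mismatch never matches
  wrong <- det_df(1L, 0, 0, 10, 10)
  expect_equal(match_detections(wrong, gts, 0.5)$TP, 0L)
})

test_that("precision/recall ratios and zero-denominator convention", {
  expect_equal(precision_recall(list(TP = 8, FP = 2, FN = 0))$P, 0.8)
  expect_equal(precision_recall(list(TP = 8, FP = 0, FN = 8))$R, 0.5)
  z <- precision_recall(list(TP = 0, FP = 0, FN = 0))
  expect_equal(z$P, 0)
  expect_true(z$flagged)
})

test_that("average precision matches the brute-force envelope oracle", {
  # 1 gt, two detections: correct at 0.9, wrong at 0.8 -> AP 1
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, FALSE), 1), 1)
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, FALSE), 2), 0)
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    ngt <- sample(1:10, 1)
    conf <- runif(n)
    matched <- rep(FALSE, n)
    pos <- sample(n, min(n, ngt))
    matched[pos[seq_len(sample(0:length(pos), 1))]] <- TRUE
    expect_equal(average_precision(conf, matched, ngt),
                 ap_bruteforce(conf, matched, ngt), tolerance = 1e-12)
  }
  expect_error(average_precision(0.5, TRUE, 0), "ground truth")
})

test_that("adding a duplicate detection of a matched gt never raises AP", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(2:12, 1); ngt <- sample(1:6, 1)
    conf <- runif(n); matched <- runif(n) < 0.5
    ap0 <- average_precision(conf, matched, ngt)
    # a duplicate of an already matched gt is an unmatched (FP) detection
    ap1 <- average_precision(c(conf, runif(1)), c(matched, FALSE), ngt)
    expect_lte(ap1, ap0 + 1e-12)
  }
})

test_that("mAP@0.5:0.95 boundary constructions", {
  gts <- list(data.frame(class_id = c(0L, 1L), x1 = c(0, 20), y1 = c(0, 20),
                         x2 = c(10, 30), y2 = c(10, 30)))
  perfect <- list(det_df(c(0L, 1L), c(0, 20), c(0, 20), c(10, 30), c(10, 30),
                         conf = c(0.9, 0.95)))
  ev <- map_50_95(perfect, gts, nc = 2)
  expect_equal(ev$map50_95, 1)
  expect_equal(ev$P, 1); expect_equal(ev$R, 1)
  # shift every box so IoU is exactly 0.6: AP 1 at thr <= 0.6, else 0
  # 10x10 box shifted by 2.5 in x: inter 7.5*10, union 125 -> IoU 0.6
  shifted <- list(det_df(c(0L, 1L), c(2.5, 22.5), c(0, 20), c(12.5, 32.5),
                         c(10, 30), conf = c(0.9, 0.95)))
  ev2 <- map_50_95(shifted, gts, nc = 2)
  expect_equal(ev2$map50_95, 0.3, tolerance = 1e-12)
  expect_error(map_50_95(list(), list(), 2), "empty ground-truth")
  expect_error(map_50_95(perfect, list(data.frame(class_id = integer(0),
    x1 = numeric(0), y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))), 2),
    "empty ground-truth")
})

test_that("mAP is invariant to detection input order", {
  set.seed(5)
  gts <- list(data.frame(class_id = c(0L, 0L, 1L),
                         x1 = c(0, 30, 60), y1 = c(0, 30, 60),
                         x2 = c(20, 50, 80), y2 = c(20, 50, 80)))
  dets <- det_df(sample(0:1, 8, replace = TRUE),
                 runif(8, 0, 60), runif(8, 0, 60),
                 runif(8, 61, 100), runif(8, 61, 100), conf = runif(8))
  ev1 <- map_50_95(list(dets), gts, 2)
  ev2 <- map_50_95(list(dets[sample(8), ]), gts, 2)
  expect_equal(ev1$map50_95, ev2$map50_95, tolerance = 1e-12)
})

test_that("confusion matrix patterns", {
  gts <- list(data.frame(class_id = 0:2, x1 = c(0, 20, 40), y1 = c(0, 20, 40),
                         x2 = c(10, 30, 50), y2 = c(10, 30, 50)))
  perfect <- list(det_df(0:2, c(0, 20, 40), c(0, 20, 40), c(10, 30, 50),
                         c(10, 30, 50), conf = 0.9))
  M <- det_confusion_matrix(perfect, gts, nc = 3)
  expect_equal(diag(M)[1:3], rep(1, 3), ignore_attr = TRUE)
  expect_equal(sum(M), 3)
  # all detections below the confidence threshold: everything is background
  low <- list(det_df(0:2, c(0, 20, 40), c(0, 20, 40), c(10, 30, 50),
                     c(10, 30, 50), conf = 0.1))
  M0 <- det_confusion_matrix(low, gts, nc = 3, conf_thr = 0.25)
  expect_equal(sum(M0[, 4]), 3)
  expect_equal(sum(M0[, 1:3]), 0)
  # column normalization
  Mn <- det_confusion_matrix(perfect, gts, nc = 3, normalize = TRUE)
  nz <- colSums(Mn) > 0
  expect_true(all(abs(colSums(Mn)[nz] - 1) < 1e-12))
})
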