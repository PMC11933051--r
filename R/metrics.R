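# Detection evaluation: IoU, greedy matching, precision/recall, average
# precision as the area under the monotone precision envelope, mAP over the
# IoU grid 0.50:0.05:0.95, and detection confusion matrices.

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes as `c(x1, y1, x2, y2)` (or data-frame rows)
#' @return IoU in `[0, 1]`
#' @export
box_iou <- function(a, b) {
  pick <- function(v) {
    if (!is.null(names(v)) && all(c("x1", "y1", "x2", "y2") %in% names(v)))
      as.numeric(v[c("x1", "y1", "x2", "y2")])
    else as.numeric(v[1:4])
  }
  a <- pick(unlist(a)); b <- pick(unlist(b))
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("invalid-input: degenerate box")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# IoU matrix between two box matrices (rows are boxes)
iou_matrix <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(0, nrow(A), nrow(B)))
  outer(seq_len(nrow(A)), seq_len(nrow(B)),
        Vectorize(function(i, j) box_iou(A[i, ], B[j, ])))
}

#' Greedy one-to-one detection matching
#'
#' Detections are visited in descending confidence; each matches the
#' highest-IoU unmatched ground-truth box of the same class with IoU at least
#' `iou_thr` (ties broken by ground-truth index).
#'
#' @param dets data frame with `x1, y1, x2, y2, class_id, confidence`
#' @param gts data frame with `x1, y1, x2, y2, class_id`
#' @param iou_thr matching IoU threshold
#' @return list with `TP`, `FP`, `FN`, per-detection `matched` flags (in the
#'   order of `dets` sorted by descending confidence) and the sorted order
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  ord <- order(-dets$confidence)
  matched <- logical(nrow(dets))
  gt_used <- logical(nrow(gts))
  for (i in seq_along(ord)) {
    d <- dets[ord[i], ]
    best <- 0; bestj <- 0L
    for (j in seq_len(nrow(gts))) {
      if (gt_used[j] || gts$class_id[j] != d$class_id) next
      iou <- box_iou(d, gts[j, ])
      if (iou >= iou_thr && iou > best) { best <- iou; bestj <- j }
    }
    if (bestj > 0) { matched[i] <- TRUE; gt_used[bestj] <- TRUE }
  }
  TP <- sum(matched)
  list(TP = TP, FP = nrow(dets) - TP, FN = nrow(gts) - TP,
       matched = matched, order = ord)
}

#' Precision and recall from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; zero denominators yield 0 with
#' a warning flag.
#'
#' @param m list with `TP`, `FP`, `FN`
#' @return list with `P`, `R` and `flagged`
#' @export
precision_recall <- function(m) {
  flagged <- FALSE
  if (m$TP + m$FP > 0) P <- m$TP / (m$TP + m$FP) else { P <- 0; flagged <- TRUE }
  if (m$TP + m$FN > 0) R <- m$TP / (m$TP + m$FN) else { R <- 0; flagged <- TRUE }
  list(P = P, R = R, flagged = flagged)
}

#' Average precision over the precision-recall curve
#'
#' Sweeps the confidence ranking, builds the monotone (running-maximum)
#' precision envelope and integrates it over recall with all-points
#' continuous interpolation.
#'
#' @param confidences detection confidences
#' @param matched logical flags: detection matches a ground truth
#' @param n_gt number of ground-truth boxes (must be >= 1)
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(confidences, matched, n_gt) {
  if (n_gt < 1) stop("invalid-input: average precision needs ground truth")
  if (!length(confidences)) return(0)
  ord <- order(-confidences)
  m <- matched[ord]
  tp <- cumsum(m)
  fp <- cumsum(!m)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Evaluate detections at IoU 0.5:0.95
#'
#' Per-class AP at each IoU threshold in the 0.50 to 0.95 grid (step 0.05),
#' averaged over thresholds and classes; also reports mAP at 0.5 and overall
#' precision/recall at a fixed confidence threshold and IoU 0.5.
#'
#' @param dets per-image list of detection data frames
#' @param gts per-image list of ground-truth data frames
#' @param nc class count
#' @param iou_thrs IoU threshold grid
#' @param conf_thr confidence threshold for the P/R summary
#' @return list with `ap` (class x threshold matrix), `map50`, `map50_95`,
#'   `P`, `R`, `classes` (evaluated class ids)
#' @export
map_50_95 <- function(dets, gts, nc, iou_thrs = seq(0.5, 0.95, by = 0.05),
                      conf_thr = 0.25) {
  stopifnot(length(dets) == length(gts))
  n_gt_total <- sum(vapply(gts, nrow, 0L))
  if (n_gt_total == 0) stop("invalid-input: empty ground-truth set")
  classes <- sort(unique(unlist(lapply(gts, function(g) g$class_id))))
  ap <- matrix(0, length(classes), length(iou_thrs),
               dimnames = list(classes, iou_thrs))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (ti in seq_along(iou_thrs)) {
      confs <- numeric(0); flags <- logical(0); ngt <- 0L
      for (im in seq_along(dets)) {
        dsub <- dets[[im]][dets[[im]]$class_id == cls, , drop = FALSE]
        gsub <- gts[[im]][gts[[im]]$class_id == cls, , drop = FALSE]
        ngt <- ngt + nrow(gsub)
        if (nrow(dsub)) {
          m <- match_detections(dsub, gsub, iou_thrs[ti])
          confs <- c(confs, dsub$confidence[m$order])
          flags <- c(flags, m$matched)
        }
      }
      ap[ci, ti] <- if (ngt > 0) average_precision(confs, flags, ngt) else NA
    }
  }
  TPs <- 0L; FPs <- 0L; FNs <- 0L
  for (im in seq_along(dets)) {
    dsub <- dets[[im]][dets[[im]]$confidence >= conf_thr, , drop = FALSE]
    m <- match_detections(dsub, gts[[im]], 0.5)
    TPs <- TPs + m$TP; FPs <- FPs + m$FP; FNs <- FNs + m$FN
  }
  pr <- precision_recall(list(TP = TPs, FP = FPs, FN = FNs))
  list(ap = ap, classes = classes,
       map50 = mean(ap[, 1], na.rm = TRUE),
       map50_95 = mean(ap, na.rm = TRUE),
       P = pr$P, R = pr$R)
}

#' Detection confusion matrix
#'
#' `(F+1) x (F+1)` counts of ground-truth class (rows) against predicted
#' class (columns), with an extra background row/column collecting false
#' positives and false negatives. Detections below `conf_thr` are dropped;
#' matching is greedy by IoU (class-agnostic) at `iou_thr`.
#'
#' @param dets,gts per-image lists of data frames
#' @param nc class count
#' @param conf_thr confidence threshold
#' @param iou_thr matching IoU threshold
#' @param normalize column-normalize the counts
#' @return a square matrix with `background` as the last row/column
#' @export
det_confusion_matrix <- function(dets, gts, nc, conf_thr = 0.25,
                                 iou_thr = 0.45, normalize = FALSE) {
  M <- matrix(0, nc + 1, nc + 1)
  for (im in seq_along(dets)) {
    d <- dets[[im]][dets[[im]]$confidence >= conf_thr, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    g <- gts[[im]]
    gt_used <- logical(nrow(g))
    det_matched <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      best <- 0; bestj <- 0L
      for (j in seq_len(nrow(g))) {
        if (gt_used[j]) next
        iou <- box_iou(d[i, ], g[j, ])
        if (iou >= iou_thr && iou > best) { best <- iou; bestj <- j }
      }
      if (bestj > 0) {
        gt_used[bestj] <- TRUE
        det_matched[i] <- TRUE
        M[g$class_id[bestj] + 1, d$class_id[i] + 1] <-
          M[g$class_id[bestj] + 1, d$class_id[i] + 1] + 1
      }
    }
    for (i in which(!det_matched))
      M[nc + 1, d$class_id[i] + 1] <- M[nc + 1, d$class_id[i] + 1] + 1
    for (j in which(!gt_used))
      M[g$class_id[j] + 1, nc + 1] <- M[g$class_id[j] + 1, nc + 1] + 1
  }
  dimnames(M) <- list(c(paste0("gt_", 0:(nc - 1)), "background"),
                      c(paste0("pred_", 0:(nc - 1)), "background"))
  if (normalize) {
    cs <- colSums(M)
    nzc <- cs > 0
    M[, nzc] <- sweep(M[, nzc, drop = FALSE], 2, cs[nzc], "/")
  }
  M
}
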