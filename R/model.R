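#' Model configuration
#'
#' Describes one variant of the detection-network family at nano scale
#' (depth multiplier 0.33, width multiplier 0.25, channel cap 1024).
#' `variant` selects which of the three components replace their baseline
#' counterparts: the hybrid re-parameterizable backbone (`rep_hgnetv2`), the
#' GSConv/VoVGSCSP slim neck (`slimneck`), the dynamic-head attention tower
#' (`dyhead`), any `+`-joined combination, or all three (`rsd`).
#'
#' The stage table of the hybrid backbone, the bottleneck repeats of the slim
#' neck and the tower width are calibrated so that every variant reproduces
#' the family's published parameter/FLOP accounting; see the methods vignette.
#'
#' @param variant one of `baseline`, `rep_hgnetv2`, `slimneck`, `dyhead`,
#'   `rep_hgnetv2+slimneck`, `rep_hgnetv2+dyhead`, `slimneck+dyhead`, `rsd`
#' @param nc number of object classes
#' @param img_size training/evaluation image size (divisible by 32)
#' @param depth_mult,width_mult,max_channels nano scaling constants
#' @param reg_max number of distribution-focal bins per box side
#' @param dyhead_width,dyhead_blocks tower channel width and block count
#' @return a `model_config` list
#' @export
model_config <- function(variant = "rsd", nc = 29, img_size = 640,
                         depth_mult = 0.33, width_mult = 0.25,
                         max_channels = 1024, reg_max = 16,
                         dyhead_width = 416, dyhead_blocks = 2) {
  known <- c("baseline", "rep_hgnetv2", "slimneck", "dyhead",
             "rep_hgnetv2+slimneck", "rep_hgnetv2+dyhead", "slimneck+dyhead",
             "rsd")
  if (!variant %in% known)
    stop("invalid-spec: unknown variant '", variant, "'")
  parts <- if (variant == "rsd") c("rep_hgnetv2", "slimneck", "dyhead")
           else strsplit(variant, "+", fixed = TRUE)[[1]]
  wch <- function(c) as.integer(round(min(c, max_channels) * width_mult))
  dn <- function(n) max(1L, as.integer(round(n * depth_mult)))
  list(
    variant = variant,
    nc = as.integer(nc),
    img_size = as.integer(img_size),
    depth_mult = depth_mult, width_mult = width_mult,
    max_channels = max_channels,
    reg_max = as.integer(reg_max),
    strides = c(8L, 16L, 32L),
    use_rep_backbone = "rep_hgnetv2" %in% parts,
    use_slim_neck = "slimneck" %in% parts,
    use_dyhead = "dyhead" %in% parts,
    # baseline CSP widths/depths at nano scale
    base_ch = c(wch(64), wch(128), wch(256), wch(512), wch(1024)),
    base_depth = c(dn(3), dn(6), dn(6), dn(3)),
    # hybrid backbone stage table: mid/out widths, blocks per stage, inner
    # RepLightConv repeats (calibrated; stages run at strides 4/8/16/32)
    rep_stem = c(cm = 16L, out = 32L),
    rep_stages = list(
      c(mid = 8L, out = 32L, blocks = 1L, n = 4L),
      c(mid = 64L, out = 64L, blocks = 1L, n = 6L),
      c(mid = 96L, out = 128L, blocks = 1L, n = 6L),
      c(mid = 192L, out = 256L, blocks = 1L, n = 6L)
    ),
    # slim neck: GSbottleneck repeats and first-GSConv kernel per VoVGSCSP
    # (order: P4-up, P3-out, P4-down, P5-down)
    slim_n = c(3L, 3L, 3L, 3L),
    slim_k1 = c(3L, 3L, 3L, 3L),
    dyhead_width = as.integer(dyhead_width),
    dyhead_blocks = as.integer(dyhead_blocks)
  )
}

#' Read and write model configurations as YAML
#'
#' @param cfg a [model_config()]
#' @param path YAML file path
#' @export
write_model_yaml <- function(cfg, path) {
  out <- cfg
  out$rep_stem <- as.list(cfg$rep_stem)          # maps, not sequences
  out$rep_stages <- lapply(cfg$rep_stages, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- model_config(raw$variant %||% "rsd", nc = raw$nc %||% 29,
                      img_size = raw$img_size %||% 640,
                      depth_mult = raw$depth_mult %||% 0.33,
                      width_mult = raw$width_mult %||% 0.25,
                      max_channels = raw$max_channels %||% 1024,
                      reg_max = raw$reg_max %||% 16,
                      dyhead_width = raw$dyhead_width %||% 416,
                      dyhead_blocks = raw$dyhead_blocks %||% 2)
  # stage tables and slim-neck knobs round-trip verbatim when present
  if (!is.null(raw$rep_stem)) cfg$rep_stem <- unlist(raw$rep_stem)
  if (!is.null(raw$rep_stages))
    cfg$rep_stages <- lapply(raw$rep_stages, unlist)
  if (!is.null(raw$slim_n)) cfg$slim_n <- as.integer(unlist(raw$slim_n))
  if (!is.null(raw$slim_k1)) cfg$slim_k1 <- as.integer(unlist(raw$slim_k1))
  cfg
}

#' Build a detection network
#'
#' Assembles the configured variant as a flat graph of primitive layers.
#' Initialization is deterministic for a given seed.
#'
#' @param cfg a [model_config()]
#' @param seed integer seed for weight initialization
#' @return a `pnet`
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  set.seed(as.integer(seed))
  gb <- new_graph_builder()

  if (cfg$use_rep_backbone) {
    st <- emit_hgstem(gb, 0L, cfg$rep_stem[["cm"]], cfg$rep_stem[["out"]])
    cur <- st
    cin <- cfg$rep_stem[["out"]]
    taps <- integer(0)
    for (si in seq_along(cfg$rep_stages)) {
      sg <- cfg$rep_stages[[si]]
      if (si > 1) # depthwise stride-2 downsample between stages
        cur <- emit_conv(gb, cur, cin, cin, k = 3, s = 2, g = cin, act = "none")
      for (b in seq_len(sg[["blocks"]])) {
        bin <- if (b == 1) cin else sg[["out"]]
        cur <- emit_rep_hgblock(gb, cur, bin, sg[["mid"]], sg[["out"]],
                                n = sg[["n"]], shortcut = (bin == sg[["out"]]))
      }
      cin <- sg[["out"]]
      if (si >= 2) taps <- c(taps, cur)
    }
    p3 <- taps[1]; p4 <- taps[2]; p5 <- taps[3]
    ch <- c(cfg$rep_stages[[2]][["out"]], cfg$rep_stages[[3]][["out"]],
            cfg$rep_stages[[4]][["out"]])
  } else {
    b <- cfg$base_ch   # 16 32 64 128 256
    d <- cfg$base_depth
    l0 <- emit_conv(gb, 0L, 3, b[1], k = 3, s = 2, role = "stem1")
    l1 <- emit_conv(gb, l0, b[1], b[2], k = 3, s = 2)
    l2 <- emit_c2f(gb, l1, b[2], b[2], n = d[1], shortcut = TRUE)
    l3 <- emit_conv(gb, l2, b[2], b[3], k = 3, s = 2)
    p3 <- emit_c2f(gb, l3, b[3], b[3], n = d[2], shortcut = TRUE)
    l5 <- emit_conv(gb, p3, b[3], b[4], k = 3, s = 2)
    p4 <- emit_c2f(gb, l5, b[4], b[4], n = d[3], shortcut = TRUE)
    l7 <- emit_conv(gb, p4, b[4], b[5], k = 3, s = 2)
    l8 <- emit_c2f(gb, l7, b[5], b[5], n = d[4], shortcut = TRUE)
    p5 <- emit_sppf(gb, l8, b[5])
    ch <- b[3:5]
  }

  # PAN/FPN neck (P3/P4/P5 inputs of widths ch)
  nck <- function(from, cin, cout, idx) {
    if (cfg$use_slim_neck)
      emit_vovgscsp(gb, from, cin, cout, n = cfg$slim_n[idx],
                    k1 = cfg$slim_k1[idx])
    else emit_c2f(gb, from, cin, cout, n = max(1L, as.integer(round(3 * cfg$depth_mult))))
  }
  dwn <- function(from, c) {
    if (cfg$use_slim_neck) emit_gsconv(gb, from, c, c, k = 3, s = 2)
    else emit_conv(gb, from, c, c, k = 3, s = 2)
  }
  up1 <- gb$add(node_upsample(p5))
  n1 <- nck(gb$add(node_concat(c(up1, p4))), ch[3] + ch[2], ch[2], 1)
  up2 <- gb$add(node_upsample(n1))
  n2 <- nck(gb$add(node_concat(c(up2, p3))), ch[2] + ch[1], ch[1], 2)
  d1 <- dwn(n2, ch[1])
  n3 <- nck(gb$add(node_concat(c(d1, n1))), ch[1] + ch[2], ch[2], 3)
  d2 <- dwn(n3, ch[2])
  n4 <- nck(gb$add(node_concat(c(d2, p5))), ch[2] + ch[3], ch[3], 4)
  taps <- c(n2, n3, n4)

  if (cfg$use_dyhead)
    taps <- emit_dyhead(gb, taps, ch, cfg$dyhead_width, cfg$dyhead_blocks)

  c2 <- max(16L, ch[1] %/% 4L, 4L * cfg$reg_max)
  c3 <- max(ch[1], min(cfg$nc, 100L))
  reg_ids <- integer(3); cls_ids <- integer(3)
  for (l in 1:3) {
    dl <- emit_detect_level(gb, taps[l], ch[l], c2, c3, cfg$nc, cfg$reg_max)
    reg_ids[l] <- dl$reg
    cls_ids[l] <- dl$cls
  }

  net <- new_pnet(gb$nodes,
                  outputs = list(reg = reg_ids, cls = cls_ids),
                  meta = list(variant = cfg$variant, nc = cfg$nc,
                              reg_max = cfg$reg_max, strides = cfg$strides,
                              cfg = cfg, fused = FALSE, seed = as.integer(seed)))
  init_detect_bias(net)
  net
}

# prior-aware detection bias initialization: class logits start at the prior
# of ~5 objects per image spread over the classes and the full anchor set
# (level-uniform, so no pyramid level outranks another before training)
init_detect_bias <- function(net) {
  strides <- net$meta$strides
  nc <- net$meta$nc
  imgsz <- net$meta$cfg$img_size %||% 640
  a_total <- sum((imgsz / strides)^2)
  for (l in 1:3) {
    reg <- net$nodes[[net$outputs$reg[l]]]
    reg$bias <- rep(1.0, length(reg$bias))
    cls <- net$nodes[[net$outputs$cls[l]]]
    cls$bias <- rep(log(5 / nc / a_total), length(cls$bias))
  }
  invisible(net)
}

#' Pyramid grid sizes
#'
#' Reports the P3/P4/P5 detection-grid sizes for a given input size.
#'
#' @param img_size input image size, divisible by 32
#' @return named list of `c(h, w)` grids
#' @export
forward_shapes <- function(img_size) {
  if (img_size %% 32 != 0)
    stop("invalid-input: image size must be divisible by 32")
  list(P3 = c(img_size %/% 8, img_size %/% 8),
       P4 = c(img_size %/% 16, img_size %/% 16),
       P5 = c(img_size %/% 32, img_size %/% 32))
}

#' Distribution-focal expectation
#'
#' Expected side distance of a discrete distribution over `0:(reg_max-1)`
#' bins, scaled by the level stride.
#'
#' @param p probability vector (or matrix with bins in rows)
#' @param stride level stride in pixels
#' @export
dfl_expectation <- function(p, stride = 1) {
  if (is.matrix(p)) drop(crossprod(p, seq_len(nrow(p)) - 1)) * stride
  else sum(p * (seq_along(p) - 1)) * stride
}

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# anchor centre coordinates (pixels) for an (H, W) grid at a stride
anchor_centres <- function(h, w, stride) {
  gx <- rep(seq_len(w) - 0.5, each = h)
  gy <- rep(seq_len(h) - 0.5, w)
  cbind(x = gx * stride, y = gy * stride)
}

#' Decode raw head outputs into detections
#'
#' Applies distribution-focal decoding (softmax expectation over the per-side
#' bin distributions, scaled by the level stride), sigmoid class scores, a
#' confidence threshold and class-aware non-maximum suppression.
#'
#' @param raw list with `reg` and `cls`: each a list over pyramid levels of
#'   arrays `(H, W, C, N)`
#' @param nc class count
#' @param strides per-level strides in pixels
#' @param reg_max distribution bins per side
#' @param conf_thr confidence threshold
#' @param iou_thr NMS IoU threshold
#' @param max_det maximum detections per image
#' @return per-image list of data frames with columns
#'   `x1, y1, x2, y2, class_id, confidence` (class ids 0-based)
#' @export
decode_predictions <- function(raw, nc, strides = c(8, 16, 32), reg_max = 16,
                               conf_thr = 0.25, iou_thr = 0.7, max_det = 300) {
  N <- dim(raw$reg[[1]])[4]
  out <- vector("list", N)
  for (n in seq_len(N)) {
    boxes <- NULL; scores <- NULL; classes <- NULL
    for (l in seq_along(raw$reg)) {
      rg <- raw$reg[[l]][, , , n, drop = FALSE]
      cl <- raw$cls[[l]][, , , n, drop = FALSE]
      d <- dim(rg); h <- d[1]; w <- d[2]; A <- h * w
      # channels are side-major: reg_max bins for each of (l, t, r, b)
      rm <- matrix(rg, nrow = A)                # A x 4*reg_max
      dists <- matrix(0, A, 4)
      for (s in 1:4) {
        z <- t(rm[, ((s - 1) * reg_max + 1):(s * reg_max), drop = FALSE])
        dists[, s] <- dfl_expectation(softmax_cols(z), strides[l])
      }
      ac <- anchor_centres(h, w, strides[l])
      bx <- cbind(ac[, 1] - dists[, 1], ac[, 2] - dists[, 2],
                  ac[, 1] + dists[, 3], ac[, 2] + dists[, 4])
      cm <- sigmoid_(matrix(cl, nrow = A))      # A x nc
      best <- max.col(cm, ties.method = "first")
      conf <- cm[cbind(seq_len(A), best)]
      keep <- which(conf >= conf_thr & bx[, 3] > bx[, 1] & bx[, 4] > bx[, 2])
      if (length(keep)) {
        boxes <- rbind(boxes, bx[keep, , drop = FALSE])
        scores <- c(scores, conf[keep])
        classes <- c(classes, best[keep] - 1L)
      }
    }
    if (is.null(boxes) || nrow(boxes) == 0) {
      out[[n]] <- data.frame(x1 = numeric(0), y1 = numeric(0),
                             x2 = numeric(0), y2 = numeric(0),
                             class_id = integer(0), confidence = numeric(0))
      next
    }
    keep <- integer(0)
    for (cid in unique(classes)) {
      sel <- which(classes == cid)
      k <- nms_boxes(boxes[sel, , drop = FALSE], scores[sel], iou_thr)
      keep <- c(keep, sel[k])
    }
    keep <- keep[order(scores[keep], decreasing = TRUE)]
    if (length(keep) > max_det) keep <- keep[seq_len(max_det)]
    out[[n]] <- data.frame(x1 = boxes[keep, 1], y1 = boxes[keep, 2],
                           x2 = boxes[keep, 3], y2 = boxes[keep, 4],
                           class_id = classes[keep],
                           confidence = scores[keep])
  }
  out
}

#' Greedy non-maximum suppression
#'
#' @param boxes matrix with columns x1, y1, x2, y2
#' @param scores confidence per box
#' @param iou_thr suppression IoU threshold
#' @return indices of retained boxes
#' @export
nms_boxes <- function(boxes, scores, iou_thr = 0.7) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- vapply(rest, function(j) plain_iou_(boxes[i, ], boxes[j, ]), 0)
    ord <- rest[ious <= iou_thr]
  }
  keep
}

#' Run a model on images and decode detections
#'
#' @param net a `pnet`
#' @param x image batch `(H, W, 3, N)`, values in `[0, 1]`
#' @param conf_thr,iou_thr decoding thresholds
#' @export
predict_boxes <- function(net, x, conf_thr = 0.25, iou_thr = 0.7) {
  st <- net_forward(net, x, train = FALSE)
  raw <- list(reg = lapply(net$outputs$reg, function(i) st$acts[[i]]),
              cls = lapply(net$outputs$cls, function(i) st$acts[[i]]))
  decode_predictions(raw, net$meta$nc, net$meta$strides, net$meta$reg_max,
                     conf_thr, iou_thr)
}
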