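# Training harness: task-aligned assignment, the composite detection loss
# (complete-IoU box term, binary cross-entropy classification term,
# distribution-focal term) with gradients, and a small SGD loop with linear
# warmup/decay and late-stage mosaic disabling.

#' Training configuration
#'
#' Defaults follow the reference training recipe: SGD, learning rate 0.01,
#' momentum 0.937, weight decay 0.005, batch 16, 300 epochs at 640x640, with
#' mosaic augmentation disabled for the final `close_mosaic` epochs.
#'
#' @param epochs,batch,img_size,lr0,momentum,weight_decay,close_mosaic,seed
#'   training hyper-parameters
#' @param warmup_epochs linear warmup span
#' @param lrf final learning-rate fraction of `lr0`
#' @return a `train_config`
#' @export
train_config <- function(epochs = 300, batch = 16, img_size = 640,
                         lr0 = 0.01, momentum = 0.937, weight_decay = 0.005,
                         close_mosaic = 10, warmup_epochs = 3, lrf = 0.01,
                         seed = 0) {
  stopifnot(epochs >= 1, batch >= 1, img_size >= 32, lr0 > 0,
            close_mosaic >= 0, close_mosaic <= epochs)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 img_size = as.integer(img_size), optimizer = "SGD",
                 lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
                 close_mosaic = as.integer(close_mosaic),
                 warmup_epochs = warmup_epochs, lrf = lrf,
                 seed = as.integer(seed)),
            class = "train_config")
}

ciou_ <- function(p, g) {
  iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- iw * ih
  ap <- max(0, p[3] - p[1]) * max(0, p[4] - p[2])
  ag <- max(0, g[3] - g[1]) * max(0, g[4] - g[2])
  union <- ap + ag - inter + 1e-9
  iou <- inter / union
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- ((p[1] + p[3] - g[1] - g[3])^2 + (p[2] + p[4] - g[2] - g[4])^2) / 4
  wp <- max(p[3] - p[1], 1e-9); hp <- max(p[4] - p[2], 1e-9)
  wg <- max(g[3] - g[1], 1e-9); hg <- max(g[4] - g[2], 1e-9)
  v <- (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

plain_iou_ <- function(p, g) {
  iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- iw * ih
  ap <- max(0, p[3] - p[1]) * max(0, p[4] - p[2])
  ag <- max(0, g[3] - g[1]) * max(0, g[4] - g[2])
  inter / (ap + ag - inter + 1e-9)
}

# central-difference gradient of CIoU w.r.t. the predicted box
ciou_grad_ <- function(p, g, h = 1e-3) {
  gr <- numeric(4)
  for (i in 1:4) {
    ph <- p; ph[i] <- ph[i] + h
    pl <- p; pl[i] <- pl[i] - h
    gr[i] <- (ciou_(ph, g) - ciou_(pl, g)) / (2 * h)
  }
  gr
}

# flattened per-image head view: A x (4*reg_max) regression logits,
# A x nc class logits, anchor centres and strides
flatten_head <- function(raw, n, strides) {
  regs <- NULL; clss <- NULL; ax <- NULL; ay <- NULL; st <- NULL
  for (l in seq_along(raw$reg)) {
    rg <- raw$reg[[l]]; cl <- raw$cls[[l]]
    d <- dim(rg)
    A <- d[1] * d[2]
    regs <- rbind(regs, matrix(rg[, , , n], nrow = A))
    clss <- rbind(clss, matrix(cl[, , , n], nrow = A))
    ac <- anchor_centres(d[1], d[2], strides[l])
    ax <- c(ax, ac[, 1]); ay <- c(ay, ac[, 2])
    st <- c(st, rep(strides[l], A))
  }
  list(reg = regs, cls = clss, ax = ax, ay = ay, stride = st)
}

# task-aligned assignment for one image
assign_targets <- function(scores, pboxes, fh, gt, topk = 10,
                           alpha = 0.5, beta = 6) {
  A <- nrow(scores)
  ng <- nrow(gt)
  gt_of <- integer(A)
  tscore <- numeric(A)
  if (ng == 0) return(list(gt_of = gt_of, tscore = tscore))
  meas <- matrix(0, A, ng); ious <- matrix(0, A, ng)
  inside <- matrix(FALSE, A, ng)
  for (g in seq_len(ng)) {
    inside[, g] <- fh$ax > gt$x1[g] & fh$ax < gt$x2[g] &
      fh$ay > gt$y1[g] & fh$ay < gt$y2[g]
    cand <- which(inside[, g])
    if (!length(cand)) next
    gb <- c(gt$x1[g], gt$y1[g], gt$x2[g], gt$y2[g])
    iou <- vapply(cand, function(a) plain_iou_(pboxes[a, ], gb), 0)
    s <- scores[cand, gt$class_id[g] + 1]
    ious[cand, g] <- iou
    meas[cand, g] <- (s^alpha) * (pmax(iou, 0)^beta)
  }
  # top-k candidates per ground truth
  keep <- matrix(FALSE, A, ng)
  for (g in seq_len(ng)) {
    cand <- which(inside[, g] & meas[, g] > 0)
    if (!length(cand)) {
      cand <- which(inside[, g])
      if (!length(cand)) next
      keep[cand[order(-ious[cand, g])[seq_len(min(topk, length(cand)))]], g] <- TRUE
      next
    }
    keep[cand[order(-meas[cand, g])[seq_len(min(topk, length(cand)))]], g] <- TRUE
  }
  # resolve anchors claimed by several ground truths: highest IoU wins
  for (a in which(rowSums(keep) > 0)) {
    gs <- which(keep[a, ])
    g <- gs[which.max(ious[a, gs])]
    gt_of[a] <- g
  }
  # normalized target scores
  for (g in seq_len(ng)) {
    sel <- which(gt_of == g)
    if (!length(sel)) next
    amax <- max(meas[sel, g]); imax <- max(ious[sel, g])
    tscore[sel] <- meas[sel, g] * imax / (amax + 1e-9)
  }
  list(gt_of = gt_of, tscore = tscore)
}

#' Detection loss
#'
#' Composite loss of the anchor-free head under task-aligned assignment:
#' complete-IoU box term, binary cross-entropy classification term and a
#' distribution-focal term over the per-side bin distributions, weighted
#' 7.5 / 0.5 / 1.5.
#'
#' @param raw list with per-level `reg` and `cls` output arrays
#' @param targets per-image list of ground-truth data frames
#'   (`class_id, x1, y1, x2, y2` in pixels)
#' @param nc class count
#' @param strides per-level strides
#' @param reg_max distribution bins per side
#' @param want_grads also return gradients w.r.t. the raw outputs
#' @param hyp loss weights and assigner constants
#' @param assignment optional frozen per-image assignment (as returned in the
#'   `assignment` field); targets and their scores are treated as constants
#'   by the gradients, so a frozen assignment makes the loss differentiable
#'   end to end
#' @return list with `loss`, `components` (box, cls, dfl), the per-image
#'   `assignment`, and optionally `grads` shaped like `raw`
#' @export
compute_loss <- function(raw, targets, nc, strides = c(8, 16, 32),
                         reg_max = 16, want_grads = TRUE,
                         hyp = list(box = 7.5, cls = 0.5, dfl = 1.5,
                                    topk = 10, alpha = 0.5, beta = 6),
                         assignment = NULL) {
  for (l in seq_along(raw$reg))
    if (any(!is.finite(raw$reg[[l]])) || any(!is.finite(raw$cls[[l]])))
      stop("numeric error: non-finite predictions (level ", l, ")")
  N <- dim(raw$reg[[1]])[4]
  per <- vector("list", N)
  tsum <- 0
  for (n in seq_len(N)) {
    fh <- flatten_head(raw, n, strides)
    A <- nrow(fh$reg)
    probs <- vector("list", 4)
    dists <- matrix(0, A, 4)
    for (s in 1:4) {
      z <- t(fh$reg[, ((s - 1) * reg_max + 1):(s * reg_max), drop = FALSE])
      p <- softmax_cols(z)
      probs[[s]] <- p
      dists[, s] <- dfl_expectation(p)   # grid units
    }
    pboxes <- cbind(fh$ax - dists[, 1] * fh$stride,
                    fh$ay - dists[, 2] * fh$stride,
                    fh$ax + dists[, 3] * fh$stride,
                    fh$ay + dists[, 4] * fh$stride)
    scores <- sigmoid_(fh$cls)
    gt <- targets[[n]]
    asg <- if (is.null(assignment)) {
      assign_targets(scores, pboxes, fh, gt, hyp$topk, hyp$alpha, hyp$beta)
    } else assignment[[n]]
    per[[n]] <- list(fh = fh, probs = probs, dists = dists, pboxes = pboxes,
                     scores = scores, asg = asg, gt = gt)
    tsum <- tsum + sum(asg$tscore)
  }
  tsum <- max(tsum, 1)

  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0
  grads <- if (want_grads)
    list(reg = lapply(raw$reg, function(a) array(0, dim(a))),
         cls = lapply(raw$cls, function(a) array(0, dim(a)))) else NULL

  for (n in seq_len(N)) {
    pp <- per[[n]]
    fh <- pp$fh; asg <- pp$asg
    A <- nrow(fh$reg)
    Y <- matrix(0, A, nc)
    pos <- which(asg$gt_of > 0)
    if (length(pos))
      Y[cbind(pos, pp$gt$class_id[asg$gt_of[pos]] + 1)] <- asg$tscore[pos]
    # classification: BCE with logits over all anchors/classes
    z <- fh$cls
    bce <- pmax(z, 0) - z * Y + log1p(exp(-abs(z)))
    loss_cls <- loss_cls + sum(bce) / tsum
    gcls <- if (want_grads) (pp$scores - Y) / tsum * hyp$cls else NULL

    greg <- if (want_grads) matrix(0, A, 4 * reg_max) else NULL
    if (length(pos)) {
      for (a in pos) {
        g <- asg$gt_of[a]
        w <- asg$tscore[a] / tsum
        gb <- c(pp$gt$x1[g], pp$gt$y1[g], pp$gt$x2[g], pp$gt$y2[g])
        ci <- ciou_(pp$pboxes[a, ], gb)
        loss_box <- loss_box + w * (1 - ci)
        # distribution-focal term: cross-entropy against the two adjacent bins
        tl <- pmin(pmax(c((fh$ax[a] - gb[1]), (fh$ay[a] - gb[2]),
                          (gb[3] - fh$ax[a]), (gb[4] - fh$ay[a])) / fh$stride[a],
                        0), reg_max - 1 - 1e-3)
        lo <- floor(tl); hi <- lo + 1
        wl <- hi - tl; wr <- tl - lo
        for (s in 1:4) {
          p <- pp$probs[[s]][, a]
          ce <- -(wl[s] * log(p[lo[s] + 1] + 1e-12) +
                    wr[s] * log(p[min(hi[s], reg_max - 1) + 1] + 1e-12))
          loss_dfl <- loss_dfl + w * ce / 4
        }
        if (want_grads) {
          dbox <- -w * ciou_grad_(pp$pboxes[a, ], gb) * hyp$box
          # chain through box = anchor -/+ stride * E[bins]
          ddist <- c(-dbox[1], -dbox[2], dbox[3], dbox[4]) * fh$stride[a]
          for (s in 1:4) {
            p <- pp$probs[[s]][, a]
            E <- pp$dists[a, s]
            dz_box <- ddist[s] * p * ((0:(reg_max - 1)) - E)
            tgt <- numeric(reg_max)
            tgt[lo[s] + 1] <- wl[s]
            tgt[min(hi[s], reg_max - 1) + 1] <- tgt[min(hi[s], reg_max - 1) + 1] + wr[s]
            dz_dfl <- w * hyp$dfl / 4 * (p - tgt)
            cols <- ((s - 1) * reg_max + 1):(s * reg_max)
            greg[a, cols] <- greg[a, cols] + dz_box + dz_dfl
          }
        }
      }
    }
    if (want_grads) {
      # scatter flattened gradients back into per-level arrays
      at <- 0L
      for (l in seq_along(raw$reg)) {
        d <- dim(raw$reg[[l]])
        A_l <- d[1] * d[2]
        sel <- (at + 1):(at + A_l)
        grads$reg[[l]][, , , n] <- array(greg[sel, ], c(d[1], d[2], d[3]))
        dcl <- dim(raw$cls[[l]])
        grads$cls[[l]][, , , n] <- array(gcls[sel, ], c(dcl[1], dcl[2], dcl[3]))
        at <- at + A_l
      }
    }
  }
  if (want_grads && N > 1) {
    # reference-trainer convention: the optimized objective is the
    # tsum-normalized loss multiplied by the batch size, so per-image
    # gradient scale is batch-independent
    for (part in c("reg", "cls"))
      grads[[part]] <- lapply(grads[[part]], function(a) a * N)
  }
  loss <- hyp$box * loss_box + hyp$cls * loss_cls + hyp$dfl * loss_dfl
  list(loss = loss,
       components = c(box = loss_box, cls = loss_cls, dfl = loss_dfl),
       assignment = lapply(per, function(pp) pp$asg),
       grads = grads)
}

load_split <- function(manifest, split, img_size) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    im <- png::readPNG(rows$image[i])
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    im <- im[, , 1:3, drop = FALSE]
    h0 <- dim(im)[1]
    boxes <- read_yolo_labels(rows$label[i], dim(im)[2], h0)
    if (h0 != img_size) {
      f <- img_size / h0
      im <- cpp_resize_bilinear(array(im, c(dim(im), 1)), img_size, img_size)[, , , 1]
      for (cc in c("x1", "x2", "y1", "y2")) boxes[[cc]] <- boxes[[cc]] * f
    }
    out[[i]] <- list(image = im,
                     boxes = boxes[, c("class_id", "x1", "y1", "x2", "y2")])
  }
  out
}

eval_map50 <- function(net, samples, nc) {
  if (!length(samples)) return(NA_real_)
  dets <- vector("list", length(samples))
  gts <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    x <- array(samples[[i]]$image, c(dim(samples[[i]]$image), 1))
    dets[[i]] <- predict_boxes(net, x, conf_thr = 0.001, iou_thr = 0.7)[[1]]
    gts[[i]] <- samples[[i]]$boxes
  }
  if (sum(vapply(gts, nrow, 0L)) == 0) return(NA_real_)
  map_50_95(dets, gts, nc)$map50
}

#' Train or fine-tune a detector
#'
#' SGD with momentum, linear warmup and linear decay to `lrf * lr0`, mosaic
#' augmentation disabled for the final `close_mosaic` epochs, per-epoch loss
#' and validation mAP\@0.5 logging. Deterministic under a fixed seed.
#'
#' @param net a `pnet` (modified in place and returned)
#' @param manifest a [generate_dataset()] manifest
#' @param cfg a [train_config()]
#' @param verbose print per-epoch progress
#' @return list with `net` and `history` (per-epoch data frame)
#' @export
fit_detector <- function(net, manifest, cfg = train_config(), verbose = FALSE) {
  set.seed(cfg$seed)
  train <- load_split(manifest, "train", cfg$img_size)
  val <- load_split(manifest, "val", cfg$img_size)
  if (!length(train)) stop("invalid-input: empty training split")
  nc <- net$meta$nc
  strides <- net$meta$strides
  reg_ids <- net$outputs$reg; cls_ids <- net$outputs$cls
  nb <- max(1L, length(train) %/% cfg$batch)
  warm_iters <- max(1, round(cfg$warmup_epochs * nb))
  it <- 0
  hist <- data.frame(epoch = integer(0), loss = numeric(0), box = numeric(0),
                     cls = numeric(0), dfl = numeric(0), lr = numeric(0),
                     val_map50 = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample(seq_along(train))
    use_mosaic <- epoch <= cfg$epochs - cfg$close_mosaic
    ep_loss <- c(loss = 0, box = 0, cls = 0, dfl = 0)
    nb_done <- 0
    lr_ep <- cfg$lr0 * (1 - (epoch - 1) / cfg$epochs * (1 - cfg$lrf))
    for (b in seq_len(nb)) {
      sel <- idx[((b - 1) * cfg$batch + 1):min(b * cfg$batch, length(idx))]
      ims <- vector("list", length(sel))
      tgs <- vector("list", length(sel))
      for (j in seq_along(sel)) {
        if (use_mosaic) {
          quad <- c(sel[j], sample(seq_along(train), 3, replace = TRUE))
          sm <- mosaic_collage(train[quad], cfg$img_size)
        } else sm <- train[[sel[j]]]
        sm <- augment_sample(sm$image, sm$boxes,
                             list(hflip = 0.5, brightness = 0.1, noise = 0.01))
        ims[[j]] <- sm$image
        tgs[[j]] <- sm$boxes
      }
      x <- array(0, c(cfg$img_size, cfg$img_size, 3, length(sel)))
      for (j in seq_along(sel)) x[, , , j] <- ims[[j]]
      st <- net_forward(net, x, train = TRUE)
      raw <- list(reg = lapply(reg_ids, function(i) st$acts[[i]]),
                  cls = lapply(cls_ids, function(i) st$acts[[i]]))
      ls <- compute_loss(raw, tgs, nc, strides, net$meta$reg_max)
      gouts <- list()
      for (l in seq_along(reg_ids)) {
        gouts[[as.character(reg_ids[l])]] <- ls$grads$reg[[l]]
        gouts[[as.character(cls_ids[l])]] <- ls$grads$cls[[l]]
      }
      net_backward(net, st, gouts)
      clip_grads(net, max_norm = 10)
      it <- it + 1
      lr <- lr_ep * min(1, it / warm_iters)
      sgd_step(net, lr, cfg$momentum, cfg$weight_decay)
      zero_grads(net)
      ep_loss <- ep_loss + c(ls$loss, ls$components)
      nb_done <- nb_done + 1
    }
    ep_loss <- ep_loss / nb_done
    vmap <- eval_map50(net, val, nc)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss[1],
                                   box = ep_loss[2], cls = ep_loss[3],
                                   dfl = ep_loss[4], lr = lr_ep,
                                   val_map50 = vmap))
    if (verbose)
      message(sprintf("epoch %d/%d loss %.3f (box %.3f cls %.3f dfl %.3f) val mAP50 %s",
                      epoch, cfg$epochs, ep_loss[1], ep_loss[2], ep_loss[3],
                      ep_loss[4], format(round(vmap, 3))))
  }
  rownames(hist) <- NULL
  list(net = net, history = hist)
}
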