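# Synthetic 29-class pest-scene generator with YOLO-format labels,
# 7:2:1 dataset splitting, geometric/photometric augmentation and mosaic.

#' Scene specification
#'
#' Describes the synthetic imaging conditions: procedurally textured
#' backgrounds, class-parameterized insect-like targets (ellipsoidal bodies
#' with heads, legs, wings and stripe/spot textures spanning egg-like dots to
#' elongated larvae), optional partial occluders and clutter. The defaults
#' emulate a dense, cluttered forestry-pest scene; `preset = "easy"` is the
#' smoke-training condition (one to two large unoccluded targets on a plain
#' background, classes drawn from an 8-class subset), `preset = "hard"`
#' stresses density and occlusion.
#'
#' @param img_size square image size in pixels
#' @param n_objects inclusive range of object counts per scene
#' @param class_count number of classes
#' @param occlusion_prob probability that a target is partially occluded
#' @param clutter_level background clutter in `[0, 1]`
#' @param background one of `"foliage"`, `"bark"`, `"soil"`
#' @param object_scale range of target diameters as a fraction of `img_size`
#' @param class_weights sampling weight per class (imbalance control)
#' @param seed base RNG seed
#' @param preset `NULL`, `"easy"` or `"hard"`
#' @return a `scene_spec` list
#' @export
scene_spec <- function(img_size = 640, n_objects = c(3, 8), class_count = 29,
                       occlusion_prob = 0.3, clutter_level = 0.6,
                       background = "foliage", object_scale = c(0.06, 0.22),
                       class_weights = NULL, seed = 0, preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "easy") {
      # large, unoccluded targets on a plain background, drawn from 8
      # hue-spread (visually distinctive) classes
      n_objects <- c(2, 3); occlusion_prob <- 0; clutter_level <- 0.1
      background <- "soil"; object_scale <- c(0.25, 0.45)
      class_weights <- rep(0, class_count)
      class_weights[seq(1, class_count, length.out = min(8, class_count))] <- 1
    } else if (preset == "hard") {
      n_objects <- c(6, 14); occlusion_prob <- 0.5; clutter_level <- 1
      object_scale <- c(0.04, 0.15)
    } else stop("invalid-spec: unknown preset")
  }
  if (is.null(class_weights)) class_weights <- rep(1, class_count)
  stopifnot(class_count >= 1, occlusion_prob >= 0, occlusion_prob <= 1,
            length(class_weights) == class_count, all(class_weights >= 0),
            img_size >= 32)
  structure(list(img_size = as.integer(img_size),
                 n_objects = as.integer(n_objects),
                 class_count = as.integer(class_count),
                 occlusion_prob = occlusion_prob,
                 clutter_level = clutter_level, background = background,
                 object_scale = object_scale, class_weights = class_weights,
                 seed = as.integer(seed), preset = preset),
            class = "scene_spec")
}

# per-class appearance parameters (deterministic in the class id)
class_params <- function(nc = 29) {
  id <- seq_len(nc)
  data.frame(
    class_id = id - 1L,
    hue = ((id - 1) %% nc) / nc,
    sat = 0.65 + 0.3 * ((id * 5) %% 3) / 2,
    val = 0.45 + 0.45 * ((id * 3) %% 4) / 3,
    aspect = 1 + 2.5 * ((id * 7) %% nc) / (nc - 1),
    size_mult = 0.6 + 0.8 * ((id * 11) %% nc) / (nc - 1),
    pattern = id %% 3,            # 0 none, 1 stripes, 2 spots
    legs = id %% 2 == 0,
    wings = id %% 4 == 1
  )
}

bg_base_color <- function(background) {
  switch(background,
         foliage = c(0.22, 0.40, 0.16),
         bark = c(0.36, 0.26, 0.16),
         soil = c(0.52, 0.44, 0.32),
         stop("invalid-spec: unknown background"))
}

# blend a rotated ellipse into img; returns img and the drawn pixel extent
draw_ellipse <- function(img, cx, cy, rx, ry, theta, col, alpha = 1) {
  S <- dim(img)[1]
  rmax <- max(rx, ry)
  xs <- max(1, floor(cx - rmax)):min(S, ceiling(cx + rmax))
  ys <- max(1, floor(cy - rmax)):min(S, ceiling(cy + rmax))
  if (!length(xs) || !length(ys)) return(list(img = img, ext = NULL))
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (gx * ct + gy * st) / rx
  v <- (-gx * st + gy * ct) / ry
  mask <- (u^2 + v^2) <= 1
  if (!any(mask)) return(list(img = img, ext = NULL))
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    img[ys, xs, ch] <- plane * (1 - alpha * mask) + col[ch] * alpha * mask
  }
  mr <- range(ys[rowSums(mask) > 0])
  mc <- range(xs[colSums(mask) > 0])
  list(img = img, ext = c(x1 = mc[1], y1 = mr[1], x2 = mc[2], y2 = mr[2]),
       mask_ix = list(ys = ys, xs = xs, mask = mask, u = u))
}

merge_ext <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  c(x1 = min(a[1], b[1]), y1 = min(a[2], b[2]),
    x2 = max(a[3], b[3]), y2 = max(a[4], b[4]))
}

draw_pest <- function(img, cls, cx, cy, diam, theta) {
  body_col <- as.vector(grDevices::col2rgb(
    grDevices::hsv(cls$hue, cls$sat, cls$val))) / 255
  dark <- body_col * 0.45
  rx <- diam / 2 * sqrt(cls$aspect)
  ry <- diam / 2 / sqrt(cls$aspect)
  ext <- NULL
  # legs: three thin strokes per side
  if (cls$legs) {
    for (k in -1:1) {
      lx <- cx + k * 0.45 * rx * cos(theta)
      ly <- cy + k * 0.45 * rx * sin(theta)
      for (sgn in c(-1, 1)) {
        r <- draw_ellipse(img, lx + sgn * 0.9 * ry * -sin(theta),
                          ly + sgn * 0.9 * ry * cos(theta),
                          ry * 0.7, max(1, ry * 0.08),
                          theta + sgn * 1.2 + k * 0.2, dark)
        img <- r$img; ext <- merge_ext(ext, r$ext)
      }
    }
  }
  r <- draw_ellipse(img, cx, cy, rx, ry, theta, body_col)
  img <- r$img; ext <- merge_ext(ext, r$ext)
  body <- r
  # head at the front end
  hx <- cx + rx * 0.95 * cos(theta)
  hy <- cy + rx * 0.95 * sin(theta)
  r <- draw_ellipse(img, hx, hy, ry * 0.55, ry * 0.55, 0, dark)
  img <- r$img; ext <- merge_ext(ext, r$ext)
  if (cls$wings) {
    wcol <- pmin(1, body_col * 1.6 + 0.15)
    for (sgn in c(-1, 1)) {
      r <- draw_ellipse(img, cx - 0.2 * rx * cos(theta) + sgn * 0.5 * ry * -sin(theta),
                        cy - 0.2 * rx * sin(theta) + sgn * 0.5 * ry * cos(theta),
                        rx * 0.6, ry * 0.45, theta + sgn * 0.35, wcol, alpha = 0.8)
      img <- r$img; ext <- merge_ext(ext, r$ext)
    }
  }
  if (cls$pattern == 1 && !is.null(body$mask_ix)) {
    mi <- body$mask_ix
    stripes <- mi$mask & (sin(mi$u * pi * 3) > 0.2)
    for (ch in 1:3) {
      plane <- img[mi$ys, mi$xs, ch]
      img[mi$ys, mi$xs, ch] <- plane * (1 - 0.8 * stripes) + dark[ch] * 0.8 * stripes
    }
  } else if (cls$pattern == 2) {
    for (k in 1:4) {
      ang <- k * pi / 2 + theta
      r <- draw_ellipse(img, cx + 0.5 * rx * cos(ang), cy + 0.5 * ry * sin(ang),
                        max(1.2, ry * 0.2), max(1.2, ry * 0.2), 0, dark)
      img <- r$img
    }
  }
  list(img = img, ext = ext)
}

#' Generate one synthetic pest scene
#'
#' Deterministic in the spec (including its seed): identical specs give
#' identical images and labels.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (array `(S, S, 3)` in `[0, 1]`) and `boxes`
#'   (data frame `class_id, x1, y1, x2, y2` in pixels, tight around the
#'   drawn extents)
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  S <- spec$img_size
  base <- bg_base_color(spec$background)
  img <- array(rep(base, each = S * S), c(S, S, 3))
  # clutter: low-frequency blobs in background tones
  nblob <- round(2 + 18 * spec$clutter_level)
  for (b in seq_len(nblob)) {
    shade <- stats::runif(1, 0.6, 1.5)
    r <- draw_ellipse(img, stats::runif(1, 1, S), stats::runif(1, 1, S),
                      stats::runif(1, S / 20, S / 4), stats::runif(1, S / 20, S / 4),
                      stats::runif(1, 0, pi), pmin(1, base * shade),
                      alpha = stats::runif(1, 0.3, 0.8))
    img <- r$img
  }
  img <- img + array(stats::rnorm(S * S * 3, 0, 0.015 + 0.03 * spec$clutter_level),
                     c(S, S, 3))
  img <- pmin(pmax(img, 0), 1)

  cp <- class_params(spec$class_count)
  n_obj <- if (spec$n_objects[1] >= spec$n_objects[2]) spec$n_objects[1]
           else sample(spec$n_objects[1]:spec$n_objects[2], 1)
  boxes <- data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  placed <- list()
  for (o in seq_len(n_obj)) {
    cid <- sample.int(spec$class_count, 1, prob = spec$class_weights)
    cls <- cp[cid, ]
    diam <- stats::runif(1, spec$object_scale[1], spec$object_scale[2]) *
      S * cls$size_mult
    diam <- min(max(diam, 6), 0.45 * S)
    ok <- FALSE
    for (try in 1:30) {
      cx <- stats::runif(1, diam / 2, S - diam / 2)
      cy <- stats::runif(1, diam / 2, S - diam / 2)
      clash <- FALSE
      for (p in placed)
        if (sqrt((p[1] - cx)^2 + (p[2] - cy)^2) < 0.5 * (p[3] + diam) / 2) {
          clash <- TRUE; break
        }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      if (o == 1) stop("placement failed: objects cannot be placed")
      next
    }
    theta <- stats::runif(1, 0, pi)
    r <- draw_pest(img, cls, cx, cy, diam, theta)
    img <- r$img
    if (!is.null(r$ext)) {
      boxes <- rbind(boxes, data.frame(class_id = cid - 1L,
                                       x1 = r$ext[1], y1 = r$ext[2],
                                       x2 = r$ext[3], y2 = r$ext[4]))
      placed <- c(placed, list(c(cx, cy, diam)))
      if (stats::runif(1) < spec$occlusion_prob) {
        occ <- draw_ellipse(img, cx + stats::runif(1, -diam / 3, diam / 3),
                            cy + stats::runif(1, -diam / 3, diam / 3),
                            diam * 0.35, diam * 0.25, stats::runif(1, 0, pi),
                            bg_base_color("foliage") * stats::runif(1, 0.8, 1.2))
        img <- occ$img
      }
    }
  }
  img <- pmin(pmax(img, 0), 1)
  rownames(boxes) <- NULL
  list(image = img, boxes = boxes, spec = spec)
}

#' Read and write YOLO-format labels
#'
#' One object per line: `class cx cy w h` with centre-based coordinates
#' normalized to `[0, 1]`.
#'
#' @param boxes data frame with `class_id, x1, y1, x2, y2` (pixels)
#' @param path label file path
#' @param img_w,img_h image size in pixels
#' @export
write_yolo_labels <- function(boxes, path, img_w, img_h) {
  if (nrow(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cx <- (boxes$x1 + boxes$x2) / 2 / img_w
  cy <- (boxes$y1 + boxes$y2) / 2 / img_h
  w <- (boxes$x2 - boxes$x1) / img_w
  h <- (boxes$y2 - boxes$y1) / img_h
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, cx, cy, w, h),
             path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @return `read_yolo_labels`: data frame with `class_id`, normalized
#'   `cx, cy, w, h`, and pixel corners `x1, y1, x2, y2`
#' @export
read_yolo_labels <- function(path, img_w, img_h) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5],
             x1 = (m[, 2] - m[, 4] / 2) * img_w,
             y1 = (m[, 3] - m[, 5] / 2) * img_h,
             x2 = (m[, 2] + m[, 4] / 2) * img_w,
             y2 = (m[, 3] + m[, 5] / 2) * img_h)
}

#' Generate a dataset with a 7:2:1 train/test/val split
#'
#' Writes `n` scenes (PNG images plus YOLO label files), splits them 7:2:1 by
#' a seeded shuffle, and writes a dataset YAML with paths and class names.
#'
#' @param n number of scenes (>= 10)
#' @param spec a [scene_spec()]; scene `i` uses seed `spec$seed + i`
#' @param out_dir output directory
#' @return a `dataset_manifest`: data frame of image/label paths and split
#'   assignment, with the dataset YAML path as an attribute
#' @export
generate_dataset <- function(n, spec, out_dir) {
  if (n < 10) stop("invalid-input: need at least 10 scenes")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create output directory")
  imgs <- character(n); labs <- character(n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i
    sc <- generate_scene(sp)
    imgs[i] <- file.path(out_dir, "images", sprintf("scene_%04d.png", i))
    labs[i] <- file.path(out_dir, "labels", sprintf("scene_%04d.txt", i))
    png::writePNG(sc$image, imgs[i])
    write_yolo_labels(sc$boxes, labs[i], sp$img_size, sp$img_size)
  }
  set.seed(spec$seed)
  ord <- sample.int(n)
  ntr <- round(0.7 * n); nte <- round(0.2 * n)
  split <- character(n)
  split[ord[seq_len(ntr)]] <- "train"
  split[ord[(ntr + 1):(ntr + nte)]] <- "test"
  split[ord[(ntr + nte + 1):n]] <- "val"
  manifest <- data.frame(image = imgs, label = labs, split = split,
                         stringsAsFactors = FALSE)
  ypath <- file.path(out_dir, "dataset.yaml")
  yaml::write_yaml(list(path = normalizePath(out_dir),
                        nc = spec$class_count,
                        names = sprintf("pest_%02d", seq_len(spec$class_count) - 1),
                        img_size = spec$img_size), ypath)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "yaml") <- ypath
  attr(manifest, "img_size") <- spec$img_size
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

clip_boxes <- function(boxes, W, H, min_visible = 0.1) {
  if (!nrow(boxes)) return(boxes)
  area0 <- pmax(0, boxes$x2 - boxes$x1) * pmax(0, boxes$y2 - boxes$y1)
  boxes$x1 <- pmax(0, pmin(W, boxes$x1)); boxes$x2 <- pmax(0, pmin(W, boxes$x2))
  boxes$y1 <- pmax(0, pmin(H, boxes$y1)); boxes$y2 <- pmax(0, pmin(H, boxes$y2))
  area <- pmax(0, boxes$x2 - boxes$x1) * pmax(0, boxes$y2 - boxes$y1)
  keep <- area > 0 & area >= min_visible * area0
  boxes[keep, , drop = FALSE]
}

#' Augment an image/label pair
#'
#' Geometric transforms (horizontal/vertical flip, 90-degree rotation,
#' translation, scaling) update the boxes consistently; photometric
#' transforms (noise, brightness, contrast, colour jitter) leave them
#' untouched. Boxes are clipped to the image and dropped when less than 10%
#' of their area stays visible.
#'
#' @param image array `(H, W, 3)`
#' @param boxes data frame `class_id, x1, y1, x2, y2` in pixels
#' @param policy list of enabled transforms with magnitudes: `hflip`,
#'   `vflip`, `rot90` (probabilities), `translate`, `scale` (fractions),
#'   `noise`, `brightness`, `contrast`, `hue` (magnitudes)
#' @return list with `image` and `boxes`
#' @export
augment_sample <- function(image, boxes, policy = list()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  p <- function(nm, default = 0) policy[[nm]] %||% default
  if (stats::runif(1) < p("hflip")) {
    image <- image[, W:1, , drop = FALSE]
    if (nrow(boxes)) {
      x1 <- W - boxes$x2; boxes$x2 <- W - boxes$x1; boxes$x1 <- x1
    }
  }
  if (stats::runif(1) < p("vflip")) {
    image <- image[H:1, , , drop = FALSE]
    if (nrow(boxes)) {
      y1 <- H - boxes$y2; boxes$y2 <- H - boxes$y1; boxes$y1 <- y1
    }
  }
  if (H == W && stats::runif(1) < p("rot90")) {
    # (cx, cy) -> (cy, S - cx); new[r, c] = old[c, S + 1 - r]
    image <- aperm(image, c(2, 1, 3))[W:1, , , drop = FALSE]
    if (nrow(boxes)) {
      nx1 <- boxes$y1; nx2 <- boxes$y2
      ny1 <- W - boxes$x2; ny2 <- W - boxes$x1
      boxes$x1 <- nx1; boxes$x2 <- nx2; boxes$y1 <- ny1; boxes$y2 <- ny2
    }
  }
  tr <- p("translate")
  if (tr > 0) {
    dx <- round(stats::runif(1, -tr, tr) * W)
    dy <- round(stats::runif(1, -tr, tr) * H)
    fill <- mean(image)
    out <- array(fill, dim(image))
    sx <- max(1, 1 + dx):min(W, W + dx); ox <- sx - dx
    sy <- max(1, 1 + dy):min(H, H + dy); oy <- sy - dy
    out[sy, sx, ] <- image[oy, ox, ]
    image <- out
    if (nrow(boxes)) {
      boxes$x1 <- boxes$x1 + dx; boxes$x2 <- boxes$x2 + dx
      boxes$y1 <- boxes$y1 + dy; boxes$y2 <- boxes$y2 + dy
    }
    boxes <- clip_boxes(boxes, W, H)
  }
  sc <- p("scale")
  if (sc > 0) {
    f <- exp(stats::runif(1, -sc, sc))
    x4 <- array(image, c(H, W, 3, 1))
    nh <- max(8, round(H * f)); nw <- max(8, round(W * f))
    resized <- cpp_resize_bilinear(x4, nh, nw)
    fill <- mean(image)
    out <- array(fill, dim(image))
    if (f >= 1) {
      oy <- (nh - H) %/% 2; ox <- (nw - W) %/% 2
      out <- resized[(oy + 1):(oy + H), (ox + 1):(ox + W), , 1]
      shift_x <- -ox; shift_y <- -oy
    } else {
      oy <- (H - nh) %/% 2; ox <- (W - nw) %/% 2
      out[(oy + 1):(oy + nh), (ox + 1):(ox + nw), ] <- resized[, , , 1]
      shift_x <- ox; shift_y <- oy
    }
    image <- out
    if (nrow(boxes)) {
      fx <- nw / W; fy <- nh / H
      boxes$x1 <- boxes$x1 * fx + shift_x; boxes$x2 <- boxes$x2 * fx + shift_x
      boxes$y1 <- boxes$y1 * fy + shift_y; boxes$y2 <- boxes$y2 * fy + shift_y
    }
    boxes <- clip_boxes(boxes, W, H)
  }
  nz <- p("noise")
  if (nz > 0) image <- image + array(stats::rnorm(length(image), 0, nz), dim(image))
  br <- p("brightness")
  if (br > 0) image <- image + stats::runif(1, -br, br)
  ct <- p("contrast")
  if (ct > 0) image <- (image - 0.5) * exp(stats::runif(1, -ct, ct)) + 0.5
  hu <- p("hue")
  if (hu > 0)
    for (ch in 1:3) image[, , ch] <- image[, , ch] * (1 + stats::runif(1, -hu, hu))
  image <- pmin(pmax(image, 0), 1)
  list(image = image, boxes = boxes)
}

#' Mosaic collage of four samples
#'
#' Places four image/label pairs in a 2x2 collage around a random centre on a
#' double-size canvas, remaps and clips their boxes, and resizes the canvas
#' back to `img_size`.
#'
#' @param samples list of exactly four `list(image, boxes)` pairs
#' @param img_size output image size
#' @return list with `image` and `boxes`
#' @export
mosaic_collage <- function(samples, img_size) {
  if (length(samples) != 4) stop("invalid-spec: mosaic needs exactly 4 samples")
  s <- img_size
  canvas <- array(mean(samples[[1]]$image), c(2 * s, 2 * s, 3))
  cx <- round(stats::runif(1, 0.5 * s, 1.5 * s))
  cy <- round(stats::runif(1, 0.5 * s, 1.5 * s))
  all_boxes <- NULL
  for (i in 1:4) {
    im <- samples[[i]]$image
    h <- dim(im)[1]; w <- dim(im)[2]
    # anchor each tile at the centre point
    if (i == 1) { x2 <- cx; x1 <- max(1, cx - w + 1); y2 <- cy; y1 <- max(1, cy - h + 1) }
    if (i == 2) { x1 <- cx + 1; x2 <- min(2 * s, cx + w); y2 <- cy; y1 <- max(1, cy - h + 1) }
    if (i == 3) { x2 <- cx; x1 <- max(1, cx - w + 1); y1 <- cy + 1; y2 <- min(2 * s, cy + h) }
    if (i == 4) { x1 <- cx + 1; x2 <- min(2 * s, cx + w); y1 <- cy + 1; y2 <- min(2 * s, cy + h) }
    tw <- x2 - x1 + 1; th <- y2 - y1 + 1
    # crop from the tile's near corner
    if (i %in% c(1, 3)) { sx <- (w - tw + 1):w } else { sx <- 1:tw }
    if (i %in% c(1, 2)) { sy <- (h - th + 1):h } else { sy <- 1:th }
    canvas[y1:y2, x1:x2, ] <- im[sy, sx, , drop = FALSE]
    b <- samples[[i]]$boxes
    if (nrow(b)) {
      ox <- x1 - min(sx); oy <- y1 - min(sy)
      b$x1 <- b$x1 + ox; b$x2 <- b$x2 + ox
      b$y1 <- b$y1 + oy; b$y2 <- b$y2 + oy
      b <- b[b$x2 > x1 & b$x1 < x2 & b$y2 > y1 & b$y1 < y2, , drop = FALSE]
      if (nrow(b)) {
        a0 <- (b$x2 - b$x1) * (b$y2 - b$y1)
        b$x1 <- pmax(b$x1, x1 - 1); b$x2 <- pmin(b$x2, x2)
        b$y1 <- pmax(b$y1, y1 - 1); b$y2 <- pmin(b$y2, y2)
        a1 <- pmax(0, b$x2 - b$x1) * pmax(0, b$y2 - b$y1)
        b <- b[a1 >= 0.1 * a0, , drop = FALSE]
        all_boxes <- rbind(all_boxes, b)
      }
    }
  }
  out <- cpp_resize_bilinear(array(canvas, c(2 * s, 2 * s, 3, 1)), s, s)
  boxes <- if (is.null(all_boxes))
    data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0))
  else {
    all_boxes$x1 <- all_boxes$x1 / 2; all_boxes$x2 <- all_boxes$x2 / 2
    all_boxes$y1 <- all_boxes$y1 / 2; all_boxes$y2 <- all_boxes$y2 / 2
    all_boxes
  }
  rownames(boxes) <- NULL
  list(image = out[, , , 1], boxes = boxes)
}
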