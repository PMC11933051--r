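# shared fixtures: tiny graphs, random feature maps, brute-force oracles

rand_fmap <- function(h, w, c, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * n), c(h, w, c, n))
}

# reference convolution by direct summation (oracle for the im2col kernel)
conv2d_ref <- function(x, w, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); kd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- kd[1]; kw <- kd[2]; ing <- kd[3]; cout <- kd[4]
  outg <- cout / groups
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout, N))
  for (n in seq_len(N)) for (co in seq_len(cout)) {
    g <- (co - 1) %/% outg
    for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(ing)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
        hi <- (oh - 1) * stride - pad + i
        wi <- (ow - 1) * stride - pad + j
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, g * ing + ci, n] * w[i, j, ci, co]
      }
      y[oh, ow, co, n] <- acc
    }
  }
  y
}

# brute-force average precision: integrate the precision envelope directly
# over every distinct confidence threshold
ap_bruteforce <- function(confidences, matched, n_gt) {
  if (!length(confidences)) return(0)
  ord <- order(-confidences)
  m <- matched[ord]
  pts <- cbind(rec = cumsum(m) / n_gt,
               prec = cumsum(m) / seq_along(m))
  env <- function(r) {
    sel <- pts[, "rec"] >= r - 1e-12
    if (!any(sel)) 0 else max(pts[sel, "prec"])
  }
  recs <- sort(unique(pts[, "rec"]))
  ap <- 0; prev <- 0
  for (r in recs) {
    ap <- ap + (r - prev) * env(r)
    prev <- r
  }
  ap
}

# brute-force LAMP score of one index (direct evaluation of the definition)
lamp_ref <- function(w) {
  n <- length(w)
  ord <- order(abs(w))
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  vapply(seq_len(n), function(u) {
    ru <- rank_of[u]
    denom <- sum(w[ord[ru:n]]^2)
    if (w[u] == 0) 0 else w[u]^2 / denom
  }, 0)
}

tiny_easy_manifest <- function(n = 12, img_size = 96, seed = 0, dir = NULL) {
  if (is.null(dir)) dir <- file.path(tempdir(), paste0("pn_ds_", seed, "_", n))
  unlink(dir, recursive = TRUE)
  generate_dataset(n, scene_spec(img_size = img_size, preset = "easy",
                                 seed = seed), dir)
}
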