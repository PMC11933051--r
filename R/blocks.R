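# Composite block emitters.  Each emits primitive nodes into a graph builder
# and returns the id of the block output.

emit_conv <- function(gb, from, cin, cout, k = 1, s = 1, g = 1, act = "silu",
                      bn = TRUE, bias = !bn, p = NULL, role = "")
  gb$add(node_conv(from, cin, cout, k, s, p = p, g = g, act = act, bn = bn,
                   bias = bias, role = role))

# residual bottleneck used inside C2f (two 3x3 convs)
emit_bottleneck <- function(gb, from, c, shortcut = TRUE) {
  a <- emit_conv(gb, from, c, c, k = 3)
  b <- emit_conv(gb, a, c, c, k = 3)
  if (shortcut) gb$add(node_add(c(from, b))) else b
}

# cross-stage-partial block with dense bottleneck aggregation
emit_c2f <- function(gb, from, cin, cout, n = 1, shortcut = FALSE) {
  c <- cout %/% 2
  cv1 <- emit_conv(gb, from, cin, 2 * c, k = 1)
  s1 <- gb$add(node_slice(cv1, 1:c))
  s2 <- gb$add(node_slice(cv1, (c + 1):(2 * c)))
  parts <- c(s1, s2)
  cur <- s2
  for (i in seq_len(n)) {
    cur <- emit_bottleneck(gb, cur, c, shortcut)
    parts <- c(parts, cur)
  }
  cat_id <- gb$add(node_concat(parts))
  emit_conv(gb, cat_id, (2 + n) * c, cout, k = 1)
}

emit_sppf <- function(gb, from, c, k = 5) {
  ch <- c %/% 2
  cv1 <- emit_conv(gb, from, c, ch, k = 1)
  p1 <- gb$add(node_maxpool(cv1, k, 1, k %/% 2))
  p2 <- gb$add(node_maxpool(p1, k, 1, k %/% 2))
  p3 <- gb$add(node_maxpool(p2, k, 1, k %/% 2))
  cat_id <- gb$add(node_concat(c(cv1, p1, p2, p3)))
  emit_conv(gb, cat_id, 4 * ch, c, k = 1)
}

# stem of the hybrid backbone: five convolutions and one max pooling
emit_hgstem <- function(gb, from, cm, cout, first = TRUE) {
  s1 <- emit_conv(gb, from, 3, cm, k = 3, s = 2,
                  role = if (first) "stem1" else "")
  pad1 <- gb$add(node_padrb(s1))
  s2a <- emit_conv(gb, pad1, cm, cm %/% 2, k = 2, s = 1, p = 0)
  pad2 <- gb$add(node_padrb(s2a))
  s2b <- emit_conv(gb, pad2, cm %/% 2, cm, k = 2, s = 1, p = 0)
  pool <- gb$add(node_maxpool(pad1, 2, 1, 0, ceil = TRUE))
  cat_id <- gb$add(node_concat(c(pool, s2b)))
  s3 <- emit_conv(gb, cat_id, 2 * cm, cm, k = 3, s = 2)
  emit_conv(gb, s3, cm, cout, k = 1)
}

# pointwise conv (linear) followed by a depthwise re-parameterizable conv
emit_replightconv <- function(gb, from, cin, cout) {
  pw <- emit_conv(gb, from, cin, cout, k = 1, act = "none")
  gb$add(node_repconv(pw, cout, cout, s = 1, g = cout, act = "silu"))
}

# dense-aggregation block: n RepLightConvs concatenated with the input, then
# 1x1 squeeze and excitation convs; optional residual shortcut
emit_rep_hgblock <- function(gb, from, cin, cm, cout, n = 6, shortcut = TRUE) {
  if (shortcut && cin != cout)
    stop("invalid-spec: shortcut requires matching in/out channels")
  parts <- from
  cur <- from
  cprev <- cin
  for (i in seq_len(n)) {
    cur <- emit_replightconv(gb, cur, cprev, cm)
    cprev <- cm
    parts <- c(parts, cur)
  }
  cat_id <- gb$add(node_concat(parts))
  sc <- emit_conv(gb, cat_id, cin + n * cm, cout %/% 2, k = 1)
  ec <- emit_conv(gb, sc, cout %/% 2, cout, k = 1)
  if (shortcut) gb$add(node_add(c(from, ec))) else ec
}

# half standard / half depthwise convolution with a channel shuffle
emit_gsconv <- function(gb, from, cin, cout, k = 1, s = 1, act = "silu") {
  if (cout %% 2 != 0) stop("invalid-spec: GSConv needs an even output width")
  ch <- cout %/% 2
  sc <- emit_conv(gb, from, cin, ch, k = k, s = s, act = act)
  dw <- emit_conv(gb, sc, ch, ch, k = 3, s = 1, g = ch, act = act)
  cat_id <- gb$add(node_concat(c(sc, dw)))
  gb$add(node_shuffle(cat_id, 2))
}

# two GSConvs (first halving the width) with an identity skip
emit_gsbottleneck <- function(gb, from, c, k1 = 3) {
  g1 <- emit_gsconv(gb, from, c, c %/% 2, k = k1, s = 1)
  g2 <- emit_gsconv(gb, g1, c %/% 2, c, k = 3, s = 1)
  gb$add(node_add(c(from, g2)))
}

# cross-stage-partial block over GSbottlenecks
emit_vovgscsp <- function(gb, from, cin, cout, n = 1, k1 = 3) {
  if (cout %% 2 != 0) stop("invalid-spec: VoVGSCSP needs an even output width")
  ch <- cout %/% 2
  cv1 <- emit_conv(gb, from, cin, ch, k = 1)
  cur <- cv1
  for (i in seq_len(n)) cur <- emit_gsbottleneck(gb, cur, ch, k1 = k1)
  cv2 <- emit_conv(gb, from, cin, ch, k = 1)
  cat_id <- gb$add(node_concat(c(cur, cv2)))
  emit_conv(gb, cat_id, 2 * ch, cout, k = 1)
}

# decoupled anchor-free detect layers for one pyramid level
emit_detect_level <- function(gb, from, cin, c2, c3, nc, reg_max = 16) {
  r1 <- emit_conv(gb, from, cin, c2, k = 3)
  r2 <- emit_conv(gb, r1, c2, c2, k = 3)
  reg <- emit_conv(gb, r2, c2, 4 * reg_max, k = 1, act = "none", bn = FALSE,
                   bias = TRUE, role = "detect_final")
  c1 <- emit_conv(gb, from, cin, c3, k = 3)
  c2b <- emit_conv(gb, c1, c3, c3, k = 3)
  cls <- emit_conv(gb, c2b, c3, nc, k = 1, act = "none", bn = FALSE,
                   bias = TRUE, role = "detect_final")
  list(reg = reg, cls = cls)
}

# dynamic-head tower: project each level to a common width, resize to the
# median level's grid, stack, run scale/spatial/task attention blocks, then
# map back to the original per-level widths
emit_dyhead <- function(gb, taps, chs, hidc, blocks) {
  L <- length(taps)
  proj <- integer(L)
  for (l in seq_len(L))
    proj[l] <- emit_conv(gb, taps[l], chs[l], hidc, k = 1, act = "none",
                         role = "dyhead_proj")
  med <- (L + 1) %/% 2
  unified <- integer(L)
  for (l in seq_len(L))
    unified[l] <- if (l == med) proj[l]
      else gb$add(node_resize_like(proj[l], proj[med]))
  cur <- gb$add(node_stack(unified))
  for (b in seq_len(blocks)) {
    cur <- gb$add(node_scale_att(cur, hidc))
    cur <- gb$add(node_spatial_att(cur, L = L))
    cur <- gb$add(node_task_att(cur, hidc, L = L))
  }
  outs <- integer(L)
  for (l in seq_len(L)) {
    u <- gb$add(node_unstack(cur, level = l, L = L))
    rb <- if (l == med) u else gb$add(node_resize_like(u, proj[l]))
    outs[l] <- emit_conv(gb, rb, hidc, chs[l], k = 1, act = "none",
                         role = "dyhead_proj_back")
  }
  outs
}
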