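# Primitive graph nodes.
#
# A network is a flat DAG of primitive nodes (environments), each with a
# `type`, the ids of its inputs (`from`; 0 denotes the network input), and its
# parameters.  Composite blocks (C2f, Rep-HGBlock, GSConv, ...) are emitted as
# subgraphs of primitives, which keeps forward/backward passes, parameter and
# FLOP accounting, re-parameterization and channel-dependency tracing uniform.

new_node <- function(type, from, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$from <- as.integer(from)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "pn_node"
  e
}

# torch-style kaiming-uniform draw for a conv weight (kh, kw, in/g, out)
init_conv_weight <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(kh * kw * cin_g * cout, -bound, bound),
        dim = c(kh, kw, cin_g, cout))
}

bn_fields <- function(node, c, prefix = "bn") {
  assign(paste0(prefix, "_g"), rep(1, c), envir = node)
  assign(paste0(prefix, "_b"), rep(0, c), envir = node)
  assign(paste0(prefix, "_rm"), rep(0, c), envir = node)
  assign(paste0(prefix, "_rv"), rep(1, c), envir = node)
  invisible(node)
}

# conv + (optional) BN + activation. BN-free convs carry a bias.
node_conv <- function(from, cin, cout, k = 1, s = 1, p = NULL, g = 1,
                      act = "silu", bn = TRUE, bias = !bn, role = "") {
  if (cin %% g != 0 || cout %% g != 0)
    stop("invalid-spec: channels not divisible by groups")
  k <- rep(k, length.out = 2)
  if (is.null(p)) p <- k[1] %/% 2
  if (p < 0) stop("invalid-spec: negative padding")
  n <- new_node("conv", from,
                w = init_conv_weight(k[1], k[2], cin %/% g, cout),
                stride = as.integer(s), pad = as.integer(p),
                groups = as.integer(g), act = act, has_bn = bn,
                cin = as.integer(cin), cout = as.integer(cout),
                eps = 1e-3, mom = 0.03, role = role)
  if (bn) bn_fields(n, cout)
  if (bias) n$bias <- rep(0, cout) else n$bias <- NULL
  n
}

# multi-branch re-parameterizable conv: BN(3x3) + BN(1x1) (+ identity BN when
# cin == cout and stride == 1), summed, then activated
node_repconv <- function(from, cin, cout, s = 1, g = 1, act = "silu",
                         identity = (cin == cout && s == 1), role = "") {
  if (cin %% g != 0 || cout %% g != 0)
    stop("invalid-spec: channels not divisible by groups")
  if (identity && (cin != cout || s != 1))
    stop("invalid-spec: identity branch requires cin == cout and stride 1")
  n <- new_node("repconv", from,
                w3 = init_conv_weight(3, 3, cin %/% g, cout),
                w1 = init_conv_weight(1, 1, cin %/% g, cout),
                stride = as.integer(s), groups = as.integer(g), act = act,
                has_id = identity, cin = as.integer(cin),
                cout = as.integer(cout), eps = 1e-3, mom = 0.03, role = role)
  bn_fields(n, cout, "bn3")
  bn_fields(n, cout, "bn1")
  if (identity) bn_fields(n, cout, "bnid")
  n
}

# zero-pad one row/column at the bottom/right (2x2 stem convs)
node_padrb <- function(from) new_node("padrb", from)

node_maxpool <- function(from, k, s, p = 0, ceil = FALSE)
  new_node("maxpool", from, k = as.integer(k), stride = as.integer(s),
           pad = as.integer(p), ceil = ceil)

node_upsample <- function(from) new_node("upsample", from)
node_concat <- function(from) new_node("concat", from)
node_add <- function(from) new_node("add", from)
node_slice <- function(from, channels)
  new_node("slice", from, channels = as.integer(channels))
node_shuffle <- function(from, groups)
  new_node("shuffle", from, groups = as.integer(groups))
# resize first input bilinearly to the spatial size of the second
node_resize_like <- function(from_src, from_ref)
  new_node("resize_like", c(from_src, from_ref))
node_stack <- function(from) new_node("stack", from, L = length(from))
node_unstack <- function(from, level, L)
  new_node("unstack", from, level = as.integer(level), L = as.integer(L))

node_scale_att <- function(from, c) {
  # f is a per-channel linear readout of the spatial mean; initialised to the
  # plain S,C-mean so the initial gate is sigma(mean(F))
  new_node("scale_att", from, w = rep(1 / c, c), b = 0, cchan = as.integer(c))
}

node_spatial_att <- function(from, L, K = 9L) {
  side <- sqrt(K)
  if (side != floor(side)) stop("invalid-spec: K must be a square grid count")
  g <- seq_len(side) - (side + 1) / 2
  base <- as.matrix(expand.grid(dy = g, dx = g))
  new_node("spatial_att", from, base = base,
           off = matrix(0, K, 2), dm = rep(1 / K, K),
           wlk = matrix(1, L, K), L = as.integer(L), K = as.integer(K))
}

node_task_att <- function(from, c, L, reduction = 16L) {
  cr <- max(4L, c %/% reduction)
  b2 <- rep(0, 4 * c)
  # shifted sigmoid: zero logits give alpha = beta = 0; bias the alpha1 logits
  # so the block starts close to the identity map (alpha1 ~ 1)
  b2[seq_len(c)] <- 4
  new_node("task_att", from,
           fc1 = matrix(stats::runif(c * cr, -1, 1) / sqrt(c), c, cr),
           fc1_b = rep(0, cr),
           fc2 = matrix(stats::runif(cr * 4 * c, -1, 1) / sqrt(cr) * 0.01, cr, 4 * c),
           fc2_b = b2, cchan = as.integer(c), cr = cr, L = as.integer(L))
}

# ---- batch norm ---------------------------------------------------------

bn_forward <- function(node, z, train, prefix = "bn") {
  d <- dim(z)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  g <- get(paste0(prefix, "_g"), envir = node)
  b <- get(paste0(prefix, "_b"), envir = node)
  if (train) {
    m <- matrix(z, nrow = HW)
    cm <- colSums(m) / HW
    cm2 <- colSums(m * m) / HW
    mu <- rowMeans(matrix(cm, C, N))
    ex2 <- rowMeans(matrix(cm2, C, N))
    v <- pmax(ex2 - mu^2, 0)
    ntot <- HW * N
    mom <- node$mom
    vu <- if (ntot > 1) v * ntot / (ntot - 1) else v
    assign(paste0(prefix, "_rm"),
           (1 - mom) * get(paste0(prefix, "_rm"), envir = node) + mom * mu,
           envir = node)
    assign(paste0(prefix, "_rv"),
           (1 - mom) * get(paste0(prefix, "_rv"), envir = node) + mom * vu,
           envir = node)
  } else {
    mu <- get(paste0(prefix, "_rm"), envir = node)
    v <- get(paste0(prefix, "_rv"), envir = node)
  }
  if (any(v + node$eps <= 0)) stop("numeric error: non-positive BN variance")
  invstd <- 1 / sqrt(v + node$eps)
  scale <- g * invstd
  shift <- b - mu * scale
  y <- z * rep(rep(scale, N), each = HW) + rep(rep(shift, N), each = HW)
  list(y = y, mu = mu, invstd = invstd)
}

chan_sum <- function(a) {
  d <- dim(a)
  HW <- d[1] * d[2]
  rowSums(matrix(colSums(matrix(a, nrow = HW)), d[3], d[4]))
}

bc_chan <- function(v, d) rep(rep(v, d[4]), each = d[1] * d[2])

bn_backward <- function(node, z, mu, invstd, gy, prefix = "bn") {
  d <- dim(z)
  M <- d[1] * d[2] * d[4]
  g <- get(paste0(prefix, "_g"), envir = node)
  xhat <- (z - bc_chan(mu, d)) * bc_chan(invstd, d)
  dbeta <- chan_sum(gy)
  dgamma <- chan_sum(gy * xhat)
  acc_grad(node, paste0("g_", prefix, "_g"), dgamma)
  acc_grad(node, paste0("g_", prefix, "_b"), dbeta)
  coef <- g * invstd / M
  gz <- bc_chan(coef, d) * (M * gy - bc_chan(dbeta, d) - xhat * bc_chan(dgamma, d))
  dim(gz) <- d
  gz
}

acc_grad <- function(node, name, val) {
  cur <- if (exists(name, envir = node, inherits = FALSE)) get(name, envir = node) else NULL
  if (is.null(cur)) assign(name, val, envir = node)
  else assign(name, cur + val, envir = node)
  invisible(NULL)
}

# ---- forward ------------------------------------------------------------

convbn_branch_fwd <- function(node, x, w, prefix, stride, pad, train) {
  z <- cpp_conv2d(x, w, stride, pad, node$groups)
  r <- bn_forward(node, z, train, prefix)
  list(a = r$y, z = z, mu = r$mu, invstd = r$invstd)
}

node_forward <- function(node, ins, train = FALSE) {
  switch(node$type,
    conv = {
      x <- ins[[1]]
      z <- cpp_conv2d(x, node$w, node$stride, node$pad, node$groups)
      if (!is.null(node$bias)) z <- z + bc_chan(node$bias, dim(z))
      if (node$has_bn) {
        r <- bn_forward(node, z, train)
        a <- r$y
        cache <- list(z = z, mu = r$mu, invstd = r$invstd, a = a)
      } else {
        a <- z
        cache <- list(a = a)
      }
      list(y = act_fwd(a, node$act), cache = cache)
    },
    repconv = {
      x <- ins[[1]]
      b3 <- convbn_branch_fwd(node, x, node$w3, "bn3", node$stride, 1L, train)
      b1 <- convbn_branch_fwd(node, x, node$w1, "bn1", node$stride, 0L, train)
      a <- b3$a + b1$a
      cache <- list(b3 = b3, b1 = b1)
      if (node$has_id) {
        rid <- bn_forward(node, x, train, "bnid")
        a <- a + rid$y
        cache$id <- rid
      }
      cache$a <- a
      list(y = act_fwd(a, node$act), cache = cache)
    },
    padrb = {
      d <- dim(ins[[1]])
      y <- array(0, c(d[1] + 1L, d[2] + 1L, d[3], d[4]))
      y[seq_len(d[1]), seq_len(d[2]), , ] <- ins[[1]]
      list(y = y, cache = list(xdim = d))
    },
    maxpool = {
      r <- cpp_maxpool(ins[[1]], node$k, node$stride, node$pad, node$ceil)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(ins[[1]])))
    },
    upsample = list(y = cpp_upsample2(ins[[1]]), cache = NULL),
    concat = {
      d1 <- dim(ins[[1]])
      cs <- vapply(ins, function(a) dim(a)[3], 0)
      y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
      at <- 0L
      for (i in seq_along(ins)) {
        y[, , (at + 1):(at + cs[i]), ] <- ins[[i]]
        at <- at + cs[i]
      }
      list(y = y, cache = list(cs = cs))
    },
    add = list(y = ins[[1]] + ins[[2]], cache = NULL),
    slice = list(y = ins[[1]][, , node$channels, , drop = FALSE],
                 cache = list(xdim = dim(ins[[1]]))),
    shuffle = {
      ord <- shuffle_order(dim(ins[[1]])[3], node$groups)
      list(y = ins[[1]][, , ord, , drop = FALSE], cache = list(ord = ord))
    },
    resize_like = {
      dref <- dim(ins[[2]])
      x <- ins[[1]]
      if (all(dim(x)[1:2] == dref[1:2])) list(y = x, cache = list(noop = TRUE))
      else list(y = cpp_resize_bilinear(x, dref[1], dref[2]),
                cache = list(xdim = dim(x), noop = FALSE))
    },
    stack = {
      d <- dim(ins[[1]])
      L <- length(ins)
      y <- array(0, c(d[1], d[2], d[3], d[4] * L))
      for (l in seq_len(L)) y[, , , ((l - 1) * d[4] + 1):(l * d[4])] <- ins[[l]]
      list(y = y, cache = list(N = d[4]))
    },
    unstack = {
      d <- dim(ins[[1]])
      N <- d[4] %/% node$L
      sel <- ((node$level - 1) * N + 1):(node$level * N)
      list(y = ins[[1]][, , , sel, drop = FALSE], cache = list(xdim = d))
    },
    scale_att = {
      x <- ins[[1]]
      d <- dim(x)
      HW <- d[1] * d[2]
      m <- matrix(colSums(matrix(x, nrow = HW)) / HW, d[3], d[4]) # C x B
      s <- drop(crossprod(m, node$w)) + node$b                    # per entry
      gate <- hardsigmoid_(s)
      y <- x * rep(gate, each = HW * d[3])
      list(y = y, cache = list(m = m, s = s, gate = gate))
    },
    spatial_att = {
      x <- ins[[1]]
      d <- dim(x)
      L <- node$L
      N <- d[4] %/% L
      y <- array(0, d)
      for (n in seq_len(N)) {
        sel <- n + (0:(L - 1)) * N
        Fl <- x[, , , sel, drop = FALSE]
        o <- cpp_spatial_att(Fl, node$base, node$off, node$dm, node$wlk)
        for (l in sel) y[, , , l] <- o
      }
      list(y = y, cache = list(N = N))
    },
    task_att = {
      x <- ins[[1]]
      d <- dim(x)
      L <- node$L
      N <- d[4] %/% L
      HW <- d[1] * d[2]
      C <- d[3]
      mcols <- matrix(colSums(matrix(x, nrow = HW)) / HW, C, d[4])
      y <- array(0, d)
      cache <- vector("list", N)
      for (n in seq_len(N)) {
        sel <- n + (0:(L - 1)) * N
        m <- rowMeans(mcols[, sel, drop = FALSE])
        hpre <- drop(crossprod(node$fc1, m)) + node$fc1_b
        h <- pmax(hpre, 0)
        tpre <- drop(crossprod(node$fc2, h)) + node$fc2_b
        tt <- 2 * sigmoid_(tpre) - 1
        a1 <- tt[1:C]; a2 <- tt[(C + 1):(2 * C)]
        be1 <- tt[(2 * C + 1):(3 * C)]; be2 <- tt[(3 * C + 1):(4 * C)]
        for (l in sel) {
          xl <- x[, , , l]
          br1 <- xl * rep(a1, each = HW) + rep(be1, each = HW)
          br2 <- xl * rep(a2, each = HW) + rep(be2, each = HW)
          y[, , , l] <- pmax(br1, br2)
        }
        cache[[n]] <- list(m = m, hpre = hpre, h = h, tpre = tpre, tt = tt)
      }
      list(y = y, cache = list(per = cache, N = N))
    },
    stop("unknown node type: ", node$type)
  )
}

# ---- backward -----------------------------------------------------------

convbn_branch_bwd <- function(node, x, w, wname, prefix, cache, ga, stride, pad) {
  gz <- bn_backward(node, cache$z, cache$mu, cache$invstd, ga, prefix)
  acc_grad(node, paste0("g_", wname),
           cpp_conv2d_bwd_w(gz, x, dim(w), stride, pad, node$groups))
  cpp_conv2d_bwd_x(gz, w, dim(x), stride, pad, node$groups)
}

node_backward <- function(node, ins, cache, y, gy) {
  switch(node$type,
    conv = {
      x <- ins[[1]]
      ga <- act_bwd(gy, cache$a, node$act)
      if (node$has_bn) {
        gz <- bn_backward(node, cache$z, cache$mu, cache$invstd, ga)
      } else gz <- ga
      if (!is.null(node$bias)) acc_grad(node, "g_bias", chan_sum(gz))
      acc_grad(node, "g_w",
               cpp_conv2d_bwd_w(gz, x, dim(node$w), node$stride, node$pad, node$groups))
      list(cpp_conv2d_bwd_x(gz, node$w, dim(x), node$stride, node$pad, node$groups))
    },
    repconv = {
      x <- ins[[1]]
      ga <- act_bwd(gy, cache$a, node$act)
      gx <- convbn_branch_bwd(node, x, node$w3, "w3", "bn3", cache$b3, ga, node$stride, 1L)
      gx <- gx + convbn_branch_bwd(node, x, node$w1, "w1", "bn1", cache$b1, ga, node$stride, 0L)
      if (node$has_id)
        gx <- gx + bn_backward(node, x, cache$id$mu, cache$id$invstd, ga, "bnid")
      list(gx)
    },
    padrb = {
      d <- cache$xdim
      list(gy[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE])
    },
    maxpool = list(cpp_maxpool_bwd(gy, cache$idx, cache$xdim)),
    upsample = list(cpp_upsample2_bwd(gy)),
    concat = {
      out <- vector("list", length(cache$cs))
      at <- 0L
      for (i in seq_along(cache$cs)) {
        out[[i]] <- gy[, , (at + 1):(at + cache$cs[i]), , drop = FALSE]
        at <- at + cache$cs[i]
      }
      out
    },
    add = list(gy, gy),
    slice = {
      gx <- array(0, cache$xdim)
      gx[, , node$channels, ] <- gy
      list(gx)
    },
    shuffle = {
      inv <- order(cache$ord)
      list(gy[, , inv, , drop = FALSE])
    },
    resize_like = {
      if (isTRUE(cache$noop)) list(gy, NULL)
      else list(cpp_resize_bilinear_bwd(gy, cache$xdim), NULL)
    },
    stack = {
      L <- length(node$from)
      N <- cache$N
      lapply(seq_len(L), function(l) gy[, , , ((l - 1) * N + 1):(l * N), drop = FALSE])
    },
    unstack = {
      gx <- array(0, cache$xdim)
      N <- cache$xdim[4] %/% node$L
      sel <- ((node$level - 1) * N + 1):(node$level * N)
      gx[, , , sel] <- gy
      list(gx)
    },
    scale_att = {
      x <- ins[[1]]
      d <- dim(x)
      HW <- d[1] * d[2]
      gate <- cache$gate
      dgate <- colSums(matrix(gy * x, nrow = HW * d[3]))
      ds <- dgate * 0.5 * (abs(cache$s) < 1)
      acc_grad(node, "g_w", drop(cache$m %*% ds))
      acc_grad(node, "g_b", sum(ds))
      gx <- gy * rep(gate, each = HW * d[3]) +
        x * rep(drop(ds), each = HW * d[3]) *
          rep(rep(node$w / HW, d[4]), each = HW)
      dim(gx) <- d
      list(gx)
    },
    spatial_att = {
      x <- ins[[1]]
      d <- dim(x)
      L <- node$L
      N <- d[4] %/% L
      gx <- array(0, d)
      for (n in seq_len(N)) {
        sel <- n + (0:(L - 1)) * N
        gsum <- array(0, d[1:3])
        for (l in sel) gsum <- gsum + gy[, , , l]
        Fl <- x[, , , sel, drop = FALSE]
        r <- cpp_spatial_att_bwd(Fl, node$base, node$off, node$dm, node$wlk, gsum)
        gx[, , , sel] <- r$gF
        acc_grad(node, "g_off", r$goff)
        acc_grad(node, "g_dm", r$gdm)
        acc_grad(node, "g_wlk", r$gwlk)
      }
      list(gx)
    },
    task_att = {
      x <- ins[[1]]
      d <- dim(x)
      L <- node$L
      N <- d[4] %/% L
      HW <- d[1] * d[2]
      C <- d[3]
      gx <- array(0, d)
      for (n in seq_len(N)) {
        pc <- cache$per[[n]]
        sel <- n + (0:(L - 1)) * N
        tt <- pc$tt
        a1 <- tt[1:C]; a2 <- tt[(C + 1):(2 * C)]
        be1 <- tt[(2 * C + 1):(3 * C)]; be2 <- tt[(3 * C + 1):(4 * C)]
        dt <- numeric(4 * C)
        dm <- numeric(C)
        for (l in sel) {
          xl <- x[, , , l]
          gl <- gy[, , , l]
          br1 <- xl * rep(a1, each = HW) + rep(be1, each = HW)
          br2 <- xl * rep(a2, each = HW) + rep(be2, each = HW)
          take1 <- br1 >= br2
          g1 <- gl * take1
          g2 <- gl * !take1
          gxl <- g1 * rep(a1, each = HW) + g2 * rep(a2, each = HW)
          gx[, , , l] <- gxl
          dt[1:C] <- dt[1:C] + colSums(matrix(g1 * xl, nrow = HW))
          dt[(C + 1):(2 * C)] <- dt[(C + 1):(2 * C)] + colSums(matrix(g2 * xl, nrow = HW))
          dt[(2 * C + 1):(3 * C)] <- dt[(2 * C + 1):(3 * C)] + colSums(matrix(g1, nrow = HW))
          dt[(3 * C + 1):(4 * C)] <- dt[(3 * C + 1):(4 * C)] + colSums(matrix(g2, nrow = HW))
        }
        sg <- sigmoid_(pc$tpre)
        dpre <- dt * 2 * sg * (1 - sg)
        acc_grad(node, "g_fc2", outer(pc$h, dpre))
        acc_grad(node, "g_fc2_b", dpre)
        dh <- drop(node$fc2 %*% dpre) * (pc$hpre > 0)
        acc_grad(node, "g_fc1", outer(pc$m, dh))
        acc_grad(node, "g_fc1_b", dh)
        dm <- drop(node$fc1 %*% dh)
        gx[, , , sel] <- gx[, , , sel] + rep(dm / (HW * L), each = HW)
      }
      list(gx)
    },
    stop("unknown node type: ", node$type)
  )
}

# trainable parameter field names per node type
node_param_names <- function(node) {
  switch(node$type,
    conv = c("w", if (!is.null(node$bias)) "bias",
             if (node$has_bn) c("bn_g", "bn_b")),
    repconv = c("w3", "bn3_g", "bn3_b", "w1", "bn1_g", "bn1_b",
                if (node$has_id) c("bnid_g", "bnid_b")),
    scale_att = c("w", "b"),
    spatial_att = c("off", "dm", "wlk"),
    task_att = c("fc1", "fc1_b", "fc2", "fc2_b"),
    character(0))
}

# ---- shape inference ----------------------------------------------------

conv_out_hw <- function(hw, k, s, p, ceil = FALSE) {
  if (ceil) {
    o <- (hw + 2 * p - k + s - 1) %/% s + 1
    o - ((o - 1) * s >= hw + p)
  } else (hw + 2 * p - k) %/% s + 1
}

node_shape <- function(node, in_shapes) {
  s1 <- in_shapes[[1]]
  switch(node$type,
    conv = {
      kd <- dim(node$w)
      c(conv_out_hw(s1[1], kd[1], node$stride, node$pad),
        conv_out_hw(s1[2], kd[2], node$stride, node$pad), kd[4], s1[4])
    },
    repconv = c(conv_out_hw(s1[1], 3, node$stride, 1),
                conv_out_hw(s1[2], 3, node$stride, 1), dim(node$w3)[4], s1[4]),
    padrb = c(s1[1] + 1L, s1[2] + 1L, s1[3], s1[4]),
    maxpool = c(conv_out_hw(s1[1], node$k, node$stride, node$pad, node$ceil),
                conv_out_hw(s1[2], node$k, node$stride, node$pad, node$ceil),
                s1[3], s1[4]),
    upsample = c(2 * s1[1], 2 * s1[2], s1[3], s1[4]),
    concat = c(s1[1], s1[2], sum(vapply(in_shapes, function(s) s[3], 0)), s1[4]),
    add = s1,
    slice = c(s1[1], s1[2], length(node$channels), s1[4]),
    shuffle = s1,
    resize_like = c(in_shapes[[2]][1], in_shapes[[2]][2], s1[3], s1[4]),
    stack = c(s1[1], s1[2], s1[3], s1[4] * length(in_shapes)),
    unstack = c(s1[1], s1[2], s1[3], s1[4] %/% node$L),
    scale_att = s1,
    spatial_att = s1,
    task_att = s1,
    stop("unknown node type: ", node$type)
  )
}

# multiply-accumulate count of a node given its input and output shapes
# (convolution/linear work only; batch taken as the per-level batch)
node_macs <- function(node, in_shapes, out_shape) {
  switch(node$type,
    conv = {
      kd <- dim(node$w)
      kd[1] * kd[2] * kd[3] * kd[4] * out_shape[1] * out_shape[2]
    },
    repconv = {
      kd <- dim(node$w3)
      (9 + 1) * kd[3] * kd[4] * out_shape[1] * out_shape[2]
    },
    scale_att = node$cchan,                     # per-level linear readout
    task_att = {
      C <- node$cchan
      C * node$cr + node$cr * 4 * C             # one theta pass per stack
    },
    0)
}
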