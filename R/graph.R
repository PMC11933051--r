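# Network container and forward/backward engine.

new_graph_builder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$add <- function(node) {
    force(node)  # nested adds must land before this node takes its id
    id <- length(gb$nodes) + 1L
    node$id <- id
    gb$nodes[[id]] <- node
    id
  }
  gb
}

new_pnet <- function(nodes, outputs, meta = list()) {
  structure(list(nodes = nodes, outputs = outputs, meta = meta),
            class = "pnet")
}

#' @export
print.pnet <- function(x, ...) {
  cat(sprintf("<pnet> %s: %d nodes, nc=%d%s\n",
              x$meta$variant %||% "custom", length(x$nodes),
              x$meta$nc %||% NA_integer_,
              if (isTRUE(x$meta$fused)) " (fused)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a network forward
#'
#' @param net a `pnet`
#' @param x input feature map `(H, W, C, N)`
#' @param train logical; batch statistics (and activation caches for a
#'   subsequent backward pass) when `TRUE`, running statistics when `FALSE`
#' @param keep node ids whose activations must be retained in eval mode
#' @return an environment with `acts` (list over node ids), `caches` (train
#'   only) and the input `x`
#' @export
net_forward <- function(net, x, train = FALSE, keep = integer(0)) {
  if (!all(is.finite(x))) stop("invalid-input: non-finite network input")
  nn <- length(net$nodes)
  refs <- integer(nn)
  for (nd in net$nodes)
    for (f in nd$from) if (f > 0) refs[f] <- refs[f] + 1L
  need <- unique(c(unlist(net$outputs, use.names = FALSE), keep))
  st <- new.env(parent = emptyenv())
  st$x <- x
  st$acts <- vector("list", nn)
  st$caches <- if (train) vector("list", nn) else NULL
  for (i in seq_len(nn)) {
    nd <- net$nodes[[i]]
    ins <- lapply(nd$from, function(f) if (f == 0) x else st$acts[[f]])
    r <- node_forward(nd, ins, train)
    st$acts[[i]] <- r$y
    if (train) st$caches[[i]] <- r$cache
    if (!train) {
      for (f in nd$from) {
        if (f > 0) {
          refs[f] <- refs[f] - 1L
          if (refs[f] == 0L && !(f %in% need)) st$acts[f] <- list(NULL)
        }
      }
    }
  }
  st
}

# Backward pass: gouts is a list mapping node id -> gradient array.
# Accumulates parameter gradients (g_<name>) into the node environments and
# returns the gradient with respect to the network input.
net_backward <- function(net, st, gouts) {
  nn <- length(net$nodes)
  gacc <- vector("list", nn)
  gx_in <- NULL
  for (nm in names(gouts)) {
    id <- as.integer(nm)
    gacc[[id]] <- if (is.null(gacc[[id]])) gouts[[nm]] else gacc[[id]] + gouts[[nm]]
  }
  for (i in rev(seq_len(nn))) {
    g <- gacc[[i]]
    if (is.null(g)) next
    nd <- net$nodes[[i]]
    ins <- lapply(nd$from, function(f) if (f == 0) st$x else st$acts[[f]])
    gins <- node_backward(nd, ins, st$caches[[i]], st$acts[[i]], g)
    for (j in seq_along(nd$from)) {
      f <- nd$from[j]
      gj <- gins[[j]]
      if (is.null(gj)) next
      if (f == 0) gx_in <- if (is.null(gx_in)) gj else gx_in + gj
      else gacc[[f]] <- if (is.null(gacc[[f]])) gj else gacc[[f]] + gj
    }
    gacc[i] <- list(NULL)
  }
  gx_in
}

zero_grads <- function(net) {
  for (nd in net$nodes) {
    gn <- grep("^g_", ls(nd), value = TRUE)
    if (length(gn)) rm(list = gn, envir = nd)
  }
  invisible(net)
}

# global gradient-norm clipping (reference-trainer stabilizer)
clip_grads <- function(net, max_norm = 10) {
  ss <- 0
  for (nd in net$nodes)
    for (p in node_param_names(nd)) {
      gname <- paste0("g_", p)
      if (exists(gname, envir = nd, inherits = FALSE))
        ss <- ss + sum(get(gname, envir = nd)^2)
    }
  gn <- sqrt(ss)
  if (is.finite(gn) && gn > max_norm) {
    sc <- max_norm / gn
    for (nd in net$nodes)
      for (p in node_param_names(nd)) {
        gname <- paste0("g_", p)
        if (exists(gname, envir = nd, inherits = FALSE))
          assign(gname, get(gname, envir = nd) * sc, envir = nd)
      }
  }
  invisible(gn)
}

# SGD with momentum; weight decay applied to conv/linear weights only
sgd_step <- function(net, lr, momentum = 0.937, weight_decay = 0) {
  decayed <- c("w", "w3", "w1", "fc1", "fc2")
  for (nd in net$nodes) {
    for (p in node_param_names(nd)) {
      gname <- paste0("g_", p)
      if (!exists(gname, envir = nd, inherits = FALSE)) next
      g <- get(gname, envir = nd)
      th <- get(p, envir = nd)
      if (p %in% decayed && weight_decay > 0) g <- g + weight_decay * th
      vname <- paste0("v_", p)
      v <- if (exists(vname, envir = nd, inherits = FALSE))
        get(vname, envir = nd) else 0 * g
      v <- momentum * v + g
      assign(vname, v, envir = nd)
      assign(p, th - lr * v, envir = nd)
    }
  }
  invisible(net)
}

# drop optimizer state and accumulated gradients (their shapes are tied to
# the parameter shapes at the time they were created)
strip_opt_state <- function(net) {
  for (nd in net$nodes) {
    drop <- grep("^(g_|v_)", ls(nd, all.names = TRUE), value = TRUE)
    if (length(drop)) rm(list = drop, envir = nd)
  }
  invisible(net)
}

clone_net <- function(net) {
  nodes <- lapply(net$nodes, function(nd) {
    e <- new.env(parent = emptyenv())
    for (nm in ls(nd, all.names = TRUE)) assign(nm, get(nm, envir = nd), envir = e)
    class(e) <- "pn_node"
    e
  })
  new_pnet(nodes, net$outputs, net$meta)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the full node parameter set, the model configuration and
#' the fused flag.
#'
#' @param net a `pnet`
#' @param path file path
#' @export
save_checkpoint <- function(net, path) {
  nodes <- lapply(net$nodes, function(nd) {
    keep <- setdiff(ls(nd, all.names = TRUE), grep("^(g_|v_)", ls(nd), value = TRUE))
    mget(keep, envir = nd)
  })
  saveRDS(list(nodes = nodes, outputs = net$outputs, meta = net$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  nodes <- lapply(obj$nodes, function(fl) {
    e <- new.env(parent = emptyenv())
    for (nm in names(fl)) assign(nm, fl[[nm]], envir = e)
    class(e) <- "pn_node"
    e
  })
  new_pnet(nodes, obj$outputs, obj$meta)
}

# shapes of every node for a given input shape (H, W, C, N)
infer_shapes <- function(net, in_shape) {
  shapes <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    ins <- lapply(nd$from, function(f) if (f == 0) in_shape else shapes[[f]])
    shapes[[i]] <- node_shape(nd, ins)
  }
  shapes
}
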