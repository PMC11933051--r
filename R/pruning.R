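# Layer-adaptive magnitude pruning (LAMP) with channel-level aggregation,
# global greedy plan search to a FLOPs speed-up target, and physical channel
# removal with dependency-graph tracing across concat/add/shuffle/depthwise
# junctions.

#' LAMP scores
#'
#' For a layer's flattened weight vector, sorted ascending by magnitude,
#' `score(u) = w[u]^2 / sum_{v >= u} w[v]^2` (suffix sum over the sorted
#' order); scores are returned in the original index order. The
#' largest-magnitude weight of a layer always scores exactly 1, and scores
#' are invariant to positive rescaling of the layer.
#'
#' @param weights numeric vector with at least one non-zero entry
#' @return score vector in `(0, 1]` (zero weights score 0)
#' @export
lamp_scores <- function(weights) {
  w <- as.numeric(weights)
  if (all(w == 0)) stop("degenerate-layer: all weights are zero")
  ord <- order(abs(w))
  w2 <- w[ord]^2
  suffix <- rev(cumsum(rev(w2)))
  s <- numeric(length(w))
  s[ord] <- ifelse(w2 > 0, w2 / suffix, 0)
  s
}

#' Channel importance from LAMP scores
#'
#' LAMP scores are computed over the whole layer; the importance of an output
#' channel is the sum of the scores of all weights in that channel.
#'
#' @param weights a matrix with channels in rows, or a conv kernel array
#'   `(kh, kw, in/groups, out)` with channels on the last axis
#' @return numeric importance per channel
#' @export
channel_importance <- function(weights) {
  if (is.matrix(weights)) m <- weights
  else {
    d <- dim(weights)
    m <- t(matrix(weights, ncol = d[length(d)]))
  }
  s <- lamp_scores(as.vector(t(m)))   # row-major: channel-contiguous
  rowSums(matrix(s, nrow(m), byrow = TRUE))
}

# per-out-channel weight matrix of a conv/repconv node (channels in rows)
node_weight_matrix <- function(nd) {
  if (nd$type == "conv") {
    t(matrix(nd$w, ncol = dim(nd$w)[4]))
  } else {
    cbind(t(matrix(nd$w3, ncol = dim(nd$w3)[4])),
          t(matrix(nd$w1, ncol = dim(nd$w1)[4])))
  }
}

# ---- channel-variable tracing -------------------------------------------

new_uf <- function() new.env(parent = emptyenv())

uf_find <- function(uf, x) {
  key <- as.character(x)
  p <- uf[[key]]
  if (is.null(p) || p == x) return(x)
  r <- uf_find(uf, p)
  uf[[key]] <- r
  r
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[as.character(max(ra, rb))]] <- min(ra, rb)
  invisible(NULL)
}

is_dw <- function(nd) {
  co <- if (nd$type == "conv") dim(nd$w)[4] else dim(nd$w3)[4]
  nd$groups > 1 && nd$groups == co
}

# Trace channel variables through the graph. Returns per-node output variable
# vectors, each conv's input variable vector, and the union-find structure.
trace_channels <- function(net) {
  uf <- new_uf()
  nvar <- 0L
  fresh <- function(n) {
    v <- (nvar + 1L):(nvar + n)
    nvar <<- nvar + n
    v
  }
  in_vars <- fresh(3L)   # image channels (never pruned)
  outv <- vector("list", length(net$nodes))
  conv_in <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    iv <- lapply(nd$from, function(f) if (f == 0) in_vars else outv[[f]])
    outv[[i]] <- switch(nd$type,
      conv = ,
      repconv = {
        conv_in[[i]] <- iv[[1]]
        co <- if (nd$type == "conv") dim(nd$w)[4] else dim(nd$w3)[4]
        if (is_dw(nd)) iv[[1]] else fresh(co)
      },
      concat = unlist(iv),
      add = {
        for (k in seq_along(iv[[1]])) uf_union(uf, iv[[1]][k], iv[[2]][k])
        iv[[1]]
      },
      slice = iv[[1]][nd$channels],
      shuffle = iv[[1]][shuffle_order(length(iv[[1]]), nd$groups)],
      stack = {
        for (l in seq_along(iv)[-1])
          for (k in seq_along(iv[[1]])) uf_union(uf, iv[[1]][k], iv[[l]][k])
        iv[[1]]
      },
      iv[[1]]  # pass-through: pool, pad, upsample, resize, unstack, attention
    )
  }
  roots <- function(v) vapply(v, function(x) as.integer(uf_find(uf, x)), 0L)
  list(out = lapply(outv, roots),
       conv_in = lapply(conv_in, function(v) if (is.null(v)) NULL else roots(v)),
       image_vars = roots(in_vars), uf = uf)
}

protected_roles <- c("stem1", "detect_final", "dyhead_proj")

#' Plan LAMP channel pruning to a FLOPs speed-up target
#'
#' Computes LAMP channel importances for every conv layer, aggregates them
#' over coupled channel groups (dependency-graph tracing through concats,
#' residual adds, shuffles and depthwise convolutions), and greedily removes
#' the globally least important groups until
#' `FLOPs_before / FLOPs_after >= speed_up`. The first stem convolution, the
#' detect output convolutions and the attention-tower projections are
#' protected.
#'
#' @param net a `pnet`
#' @param speed_up target FLOPs ratio (> 1)
#' @param img_size input size for the FLOPs model
#' @return a `prune_plan`: per-conv keep masks, protected layers, FLOPs
#'   before/after and the achieved speed-up
#' @export
plan_pruning <- function(net, speed_up = 1.5, img_size = 640) {
  if (speed_up <= 1) stop("invalid-spec: speed_up must exceed 1")
  tr <- trace_channels(net)
  shapes <- infer_shapes(net, c(img_size, img_size, 3, 1))

  conv_ids <- which(vapply(net$nodes, function(nd)
    nd$type %in% c("conv", "repconv"), TRUE))
  # per-conv bookkeeping for the FLOPs model
  coef <- numeric(length(net$nodes))     # MACs per (in x out) unit, or per
                                         # channel for depthwise layers
  dw <- logical(length(net$nodes))
  for (i in conv_ids) {
    nd <- net$nodes[[i]]
    hw <- shapes[[i]][1] * shapes[[i]][2]
    kk <- if (nd$type == "conv") prod(dim(nd$w)[1:2]) else 10 # 3x3 + 1x1
    dw[i] <- is_dw(nd)
    coef[i] <- kk * hw
  }

  nconv <- length(conv_ids)
  conv_pos <- integer(length(net$nodes))
  conv_pos[conv_ids] <- seq_len(nconv)

  # importance per coupled channel group, and group -> conv adjacency
  imp_by_conv <- lapply(conv_ids, function(i)
    channel_importance(node_weight_matrix(net$nodes[[i]])))
  all_roots <- sort(unique(c(unlist(tr$out[conv_ids]),
                             unlist(tr$conv_in[conv_ids]), tr$image_vars)))
  nroot <- length(all_roots)
  rix <- function(v) match(v, all_roots)

  var_imp <- numeric(nroot)
  var_prot <- logical(nroot)
  var_prot[rix(tr$image_vars)] <- TRUE
  # adjacency: for each root, affected convs and channel multiplicities
  aff_out <- vector("list", nroot)
  aff_in <- vector("list", nroot)
  add_aff <- function(lst, root_ix, conv, mult) {
    lst[[root_ix]] <- rbind(lst[[root_ix]], c(conv, mult))
    lst
  }
  for (ci in seq_len(nconv)) {
    i <- conv_ids[ci]
    nd <- net$nodes[[i]]
    ov <- rix(tr$out[[i]])
    imp <- imp_by_conv[[ci]]
    for (p in seq_along(ov)) var_imp[ov[p]] <- var_imp[ov[p]] + imp[p]
    if ((nd$role %||% "") %in% protected_roles) var_prot[ov] <- TRUE
    to <- table(ov)
    for (q in seq_along(to))
      aff_out <- add_aff(aff_out, as.integer(names(to)[q]), ci, as.integer(to[q]))
    if (!dw[i]) {
      ti <- table(rix(tr$conv_in[[i]]))
      for (q in seq_along(ti))
        aff_in <- add_aff(aff_in, as.integer(names(ti)[q]), ci, as.integer(ti[q]))
    }
  }

  out_kept <- vapply(conv_ids, function(i) length(tr$out[[i]]), 0)
  in_kept <- vapply(conv_ids, function(i)
    if (dw[i]) length(tr$out[[i]]) else length(tr$conv_in[[i]]), 0)
  dwc <- dw[conv_ids]
  coefc <- coef[conv_ids]
  conv_macs <- function(ci)
    if (dwc[ci]) coefc[ci] * out_kept[ci] else coefc[ci] * in_kept[ci] * out_kept[ci]
  fixed_macs <- sum(vapply(net$nodes, function(nd)
    if (nd$type %in% c("scale_att", "task_att")) node_macs(nd, NULL, NULL) else 0, 0))
  cur <- sum(vapply(seq_len(nconv), conv_macs, 0)) + fixed_macs
  flops_before <- cur
  target <- flops_before / speed_up

  cand <- order(var_imp)
  cand <- cand[!var_prot[cand]]

  removed <- integer(0)
  try_remove <- function(k) {
    ao <- aff_out[[k]]; ai <- aff_in[[k]]
    if (!is.null(ao))
      for (r in seq_len(nrow(ao)))
        if (out_kept[ao[r, 1]] - ao[r, 2] < 2) return(FALSE)
    if (!is.null(ai))
      for (r in seq_len(nrow(ai))) {
        ci <- ai[r, 1]
        if (!dwc[ci] && in_kept[ci] - ai[r, 2] < 2) return(FALSE)
      }
    touched <- unique(c(if (!is.null(ao)) ao[, 1], if (!is.null(ai)) ai[, 1]))
    dmacs <- -sum(vapply(touched, conv_macs, 0))
    if (!is.null(ao))
      for (r in seq_len(nrow(ao)))
        out_kept[ao[r, 1]] <<- out_kept[ao[r, 1]] - ao[r, 2]
    if (!is.null(ai))
      for (r in seq_len(nrow(ai)))
        in_kept[ai[r, 1]] <<- in_kept[ai[r, 1]] - ai[r, 2]
    dmacs <- dmacs + sum(vapply(touched, conv_macs, 0))
    cur <<- cur + dmacs
    removed <<- c(removed, k)
    TRUE
  }

  for (k in cand) {
    if (cur <= target) break
    try_remove(k)
  }
  if (cur > target)
    stop("infeasible-plan: speed-up target unreachable under protections")

  # round channel counts to multiples of 2 where possible
  rest <- setdiff(cand, removed)
  repeat {
    odd <- which(out_kept %% 2 == 1)
    if (!length(odd) || !length(rest)) break
    fixed <- FALSE
    for (k in rest) {
      ao <- aff_out[[k]]
      if (!is.null(ao) && any(ao[, 1] %in% odd) && try_remove(k)) {
        rest <- setdiff(rest, k)
        fixed <- TRUE
        break
      }
    }
    if (!fixed) break
  }
  flops_after <- cur

  removed_set <- all_roots[removed]
  keep_out <- lapply(seq_along(net$nodes), function(i)
    if (i %in% conv_ids) !(tr$out[[i]] %in% removed_set) else NULL)
  keep_in <- lapply(seq_along(net$nodes), function(i) {
    if (!(i %in% conv_ids)) return(NULL)
    if (dw[i]) keep_out_i <- !(tr$out[[i]] %in% removed_set)
    else keep_out_i <- !(tr$conv_in[[i]] %in% removed_set)
    keep_out_i
  })
  structure(list(
    removed_groups = removed_set,
    keep_out = keep_out, keep_in = keep_in,
    trace = tr,
    protected = conv_ids[vapply(conv_ids, function(i)
      (net$nodes[[i]]$role %||% "") %in% protected_roles, TRUE)],
    flops_before = 2 * flops_before / 1e9,
    flops_after = 2 * flops_after / 1e9,
    speed_up_target = speed_up,
    speed_up_achieved = flops_before / flops_after,
    img_size = img_size,
    channels = data.frame(
      layer = conv_ids,
      type = vapply(conv_ids, function(i) net$nodes[[i]]$type, ""),
      channels_before = vapply(conv_ids, function(i) length(tr$out[[i]]), 0),
      channels_after = out_kept
    )
  ), class = "prune_plan")
}

#' @export
print.prune_plan <- function(x, ...) {
  cat(sprintf(
    "<prune_plan> %d channel groups removed; GFLOPs %.2f -> %.2f (x%.2f, target x%.2f)\n",
    length(x$removed_groups), x$flops_before, x$flops_after,
    x$speed_up_achieved, x$speed_up_target))
  invisible(x)
}

slice_arr4 <- function(a, in_keep = NULL, out_keep = NULL) {
  if (!is.null(in_keep)) a <- a[, , in_keep, , drop = FALSE]
  if (!is.null(out_keep)) a <- a[, , , out_keep, drop = FALSE]
  a
}

#' Apply a pruning plan
#'
#' Physically removes the planned channels: kernel rows/columns, batch-norm
#' vectors and biases are sliced, downstream input channels are sliced to
#' match, and channel-indexed nodes (slices) are re-indexed. The returned
#' network is a modified copy.
#'
#' @param net the `pnet` the plan was computed for
#' @param plan a [plan_pruning()] result
#' @return pruned `pnet`
#' @export
apply_pruning <- function(net, plan) {
  if (length(plan$keep_out) != length(net$nodes))
    stop("invalid-plan: plan does not match the network")
  pruned <- strip_opt_state(clone_net(net))
  tr <- plan$trace
  removed <- plan$removed_groups
  keep_of <- function(vars) !(vars %in% removed)
  for (i in seq_along(pruned$nodes)) {
    nd <- pruned$nodes[[i]]
    if (nd$type %in% c("conv", "repconv")) {
      ok <- plan$keep_out[[i]]
      dwl <- is_dw(nd)
      ik <- if (dwl) NULL else plan$keep_in[[i]]
      if (nd$type == "conv") {
        nd$w <- slice_arr4(nd$w, ik, ok)
        if (!is.null(nd$bias)) nd$bias <- nd$bias[ok]
        if (nd$has_bn)
          for (f in c("bn_g", "bn_b", "bn_rm", "bn_rv"))
            assign(f, get(f, envir = nd)[ok], envir = nd)
      } else {
        nd$w3 <- slice_arr4(nd$w3, ik, ok)
        nd$w1 <- slice_arr4(nd$w1, ik, ok)
        pref <- c("bn3", "bn1", if (nd$has_id) "bnid")
        for (p in pref)
          for (sf in c("_g", "_b", "_rm", "_rv")) {
            f <- paste0(p, sf)
            assign(f, get(f, envir = nd)[ok], envir = nd)
          }
      }
      nd$cout <- sum(ok)
      nd$cin <- if (dwl) sum(ok) else sum(ik)
      if (dwl) nd$groups <- as.integer(sum(ok))
    } else if (nd$type == "slice") {
      src <- nd$from[1]
      src_vars <- tr$out[[src]]
      src_keep <- keep_of(src_vars)
      newpos <- cumsum(src_keep)
      sel <- nd$channels[src_keep[nd$channels]]
      nd$channels <- as.integer(newpos[sel])
    }
  }
  pruned$meta$pruned <- TRUE
  pruned$meta$prune_plan <- list(speed_up_target = plan$speed_up_target,
                                 speed_up_achieved = plan$speed_up_achieved)
  pruned
}
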