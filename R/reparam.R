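# Structural re-parameterization: fold batch norm into convolutions, lift
# 1x1 and identity branches to 3x3 kernels, and merge multi-branch blocks
# into single fused convolutions that produce identical outputs.

#' Batch-norm parameter set
#'
#' @param gamma,beta scale and shift
#' @param mean,var running statistics
#' @param eps numerical stabilizer
#' @return a `bn_params` list
#' @export
bn_params <- function(gamma, beta, mean, var, eps = 1e-3) {
  n <- length(gamma)
  stopifnot(length(beta) == n, length(mean) == n, length(var) == n)
  if (any(var + eps <= 0)) stop("numeric error: non-positive BN variance")
  list(gamma = as.double(gamma), beta = as.double(beta),
       mean = as.double(mean), var = as.double(var), eps = eps)
}

# eval-mode BN applied to a feature map
bn_apply <- function(z, bn) {
  d <- dim(z)
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  shift <- bn$beta - bn$mean * scale
  z * bc_chan(scale, d) + bc_chan(shift, d)
}

#' Fold batch norm into a convolution
#'
#' Produces the kernel/bias pair `w' = w * gamma / sqrt(var + eps)` (per
#' output channel) and `b' = beta - mean * gamma / sqrt(var + eps)` whose
#' plain convolution equals conv followed by eval-mode batch norm.
#'
#' @param kernel conv kernel array `(kh, kw, in/groups, out)`
#' @param bn a [bn_params()]
#' @return list with `kernel` and `bias`
#' @export
fuse_conv_bn <- function(kernel, bn) {
  d <- dim(kernel)
  if (length(bn$gamma) != d[4])
    stop("invalid-spec: BN width does not match conv output channels")
  if (any(bn$var + bn$eps <= 0)) stop("numeric error: non-positive BN variance")
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  k <- kernel * rep(scale, each = d[1] * d[2] * d[3])
  list(kernel = k, bias = bn$beta - bn$mean * scale)
}

#' Lift a 1x1 kernel to an equivalent 3x3 kernel
#'
#' Places each 1x1 tap at the spatial centre of a zero 3x3 kernel; with
#' padding 1 the lifted convolution equals the original 1x1 convolution.
#'
#' @param kernel1 array `(1, 1, in/groups, out)`
#' @return array `(3, 3, in/groups, out)`
#' @export
lift_1x1_to_3x3 <- function(kernel1) {
  d <- dim(kernel1)
  if (d[1] != 1 || d[2] != 1) stop("invalid-spec: kernel is not 1x1")
  k <- array(0, c(3, 3, d[3], d[4]))
  k[2, 2, , ] <- kernel1[1, 1, , ]
  k
}

#' Identity map as a 3x3 kernel
#'
#' Group-aware Dirac kernel: output channel `o` has a centre tap of 1 on its
#' own input slot within its group.
#'
#' @param channels channel count
#' @param groups conv groups; must divide `channels`
#' @return array `(3, 3, channels/groups, channels)`
#' @export
identity_to_3x3 <- function(channels, groups = 1) {
  if (channels %% groups != 0)
    stop("invalid-spec: channels not divisible by groups")
  ing <- channels %/% groups
  k <- array(0, c(3, 3, ing, channels))
  for (o in seq_len(channels)) k[2, 2, ((o - 1) %% ing) + 1, o] <- 1
  k
}

#' Random multi-branch parameters for a re-parameterizable conv
#'
#' Convenience generator for tests and examples: random kernels and random
#' (well-conditioned) batch-norm statistics.
#'
#' @param cin,cout channel counts
#' @param groups conv groups
#' @param identity include the identity-BN branch (requires `cin == cout`)
#' @param stride conv stride (identity branch requires 1)
#' @return a `repconv_params` list
#' @export
make_repconv_params <- function(cin, cout, groups = 1,
                                identity = (cin == cout), stride = 1) {
  if (identity && (cin != cout || stride != 1))
    stop("invalid-spec: identity branch requires cin == cout and stride 1")
  rbn <- function(c) bn_params(stats::runif(c, 0.5, 1.5),
                               stats::rnorm(c, 0, 0.2),
                               stats::rnorm(c, 0, 0.5),
                               stats::runif(c, 0.5, 2))
  list(w3 = init_conv_weight(3, 3, cin %/% groups, cout), bn3 = rbn(cout),
       w1 = init_conv_weight(1, 1, cin %/% groups, cout), bn1 = rbn(cout),
       bnid = if (identity) rbn(cout) else NULL,
       groups = as.integer(groups), stride = as.integer(stride))
}

#' Multi-branch (training form) forward of a re-parameterizable conv
#'
#' `BN(conv3x3(x)) + BN(conv1x1(x)) + BN(x)` (identity term only when
#' present), then the activation.
#'
#' @param x feature map
#' @param p a `repconv_params` list (see [make_repconv_params()])
#' @param act activation name
#' @export
repconv_forward_train <- function(x, p, act = "silu") {
  if (dim(x)[3] != dim(p$w3)[3] * p$groups)
    stop("invalid-spec: input channels do not match branch shapes")
  y <- bn_apply(cpp_conv2d(x, p$w3, p$stride, 1L, p$groups), p$bn3) +
    bn_apply(cpp_conv2d(x, p$w1, p$stride, 0L, p$groups), p$bn1)
  if (!is.null(p$bnid)) y <- y + bn_apply(x, p$bnid)
  act_fwd(y, act)
}

#' Fuse a multi-branch block into one 3x3 kernel and bias
#'
#' Folds each branch's batch norm, lifts the 1x1 and identity branches to
#' 3x3, and sums kernels and biases.
#'
#' @param p a `repconv_params` list
#' @return list with `kernel` `(3,3,in/groups,out)` and `bias`
#' @export
fuse_repconv <- function(p) {
  f3 <- fuse_conv_bn(p$w3, p$bn3)
  f1 <- fuse_conv_bn(p$w1, p$bn1)
  k <- f3$kernel + lift_1x1_to_3x3(f1$kernel)
  b <- f3$bias + f1$bias
  if (!is.null(p$bnid)) {
    cout <- dim(p$w3)[4]
    fid <- fuse_conv_bn(identity_to_3x3(cout, p$groups), p$bnid)
    k <- k + fid$kernel
    b <- b + fid$bias
  }
  list(kernel = k, bias = b)
}

#' Fused (inference form) forward
#'
#' @param x feature map
#' @param fk fused kernel list from [fuse_repconv()]
#' @param stride,groups conv geometry
#' @param act activation name
#' @export
repconv_forward_fused <- function(x, fk, stride = 1, groups = 1, act = "silu") {
  z <- cpp_conv2d(x, fk$kernel, stride, 1L, groups)
  act_fwd(z + bc_chan(fk$bias, dim(z)), act)
}

node_bn_params <- function(node, prefix) {
  bn_params(get(paste0(prefix, "_g"), envir = node),
            get(paste0(prefix, "_b"), envir = node),
            get(paste0(prefix, "_rm"), envir = node),
            get(paste0(prefix, "_rv"), envir = node), node$eps)
}

repconv_node_params <- function(node) {
  list(w3 = node$w3, bn3 = node_bn_params(node, "bn3"),
       w1 = node$w1, bn1 = node_bn_params(node, "bn1"),
       bnid = if (node$has_id) node_bn_params(node, "bnid") else NULL,
       groups = node$groups, stride = node$stride)
}

#' Re-parameterize a whole network
#'
#' Replaces every multi-branch block by its fused single convolution and
#' optionally verifies input-output equivalence on random probes.
#'
#' @param net a `pnet` (the returned network is a modified copy)
#' @param verify run random-probe equivalence checks
#' @param n_probes number of probe inputs
#' @param img_size probe input size
#' @param tol max-abs tolerance for the equivalence report
#' @param seed probe RNG seed
#' @return list with `net` (fused) and `report` (an equivalence report with
#'   `max_abs_diff`, `mean_abs_diff`, `n_probes`, `tolerance`, `passed`)
#' @export
reparameterize_model <- function(net, verify = TRUE, n_probes = 3,
                                 img_size = 64, tol = 1e-4, seed = 0) {
  fused <- strip_opt_state(clone_net(net))
  for (nd in fused$nodes) {
    if (nd$type != "repconv") next
    fk <- fuse_repconv(repconv_node_params(nd))
    keep <- list(id = nd$id, from = nd$from, type = "conv", w = fk$kernel,
                 bias = fk$bias, stride = nd$stride, pad = 1L,
                 groups = nd$groups, act = nd$act, has_bn = FALSE,
                 cin = nd$cin, cout = nd$cout, eps = nd$eps, mom = nd$mom,
                 role = nd$role %||% "")
    rm(list = ls(nd, all.names = TRUE), envir = nd)
    for (nm in names(keep)) assign(nm, keep[[nm]], envir = nd)
  }
  fused$meta$fused <- TRUE
  report <- NULL
  if (verify) {
    set.seed(seed)
    mx <- 0; mn <- 0; cnt <- 0
    for (i in seq_len(n_probes)) {
      x <- array(stats::rnorm(img_size * img_size * 3), c(img_size, img_size, 3, 1))
      so <- net_forward(net, x)
      sf <- net_forward(fused, x)
      for (oid in unlist(net$outputs)) {
        dd <- abs(so$acts[[oid]] - sf$acts[[oid]])
        mx <- max(mx, max(dd))
        mn <- mn + sum(dd); cnt <- cnt + length(dd)
      }
    }
    report <- list(max_abs_diff = mx, mean_abs_diff = mn / cnt,
                   n_probes = n_probes, tolerance = tol, passed = mx <= tol)
  }
  list(net = fused, report = report)
}
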