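# Model accounting: parameters, FLOPs, weight size, analytic complexity.

#' Analytic convolution complexity
#'
#' Operation counts (up to a constant) of a standard convolution, a depthwise
#' separable convolution, and a GSConv unit producing a `W x H x C2` output
#' from `C1` input channels with a `K1 x K2` kernel:
#' standard `W*H*K1*K2*C1*C2`, depthwise-separable `W*H*K1*K2*1*C2`,
#' GSConv `W*H*K1*K2*(C2/2)*(C1+1)`.
#'
#' @param W,H output feature-map width and height
#' @param K1,K2 kernel dimensions
#' @param C1,C2 input and output channel counts
#' @return operation count
#' @export
sc_complexity <- function(W, H, K1, K2, C1, C2) {
  stopifnot(W >= 1, H >= 1, K1 >= 1, K2 >= 1, C1 >= 1, C2 >= 1)
  W * H * K1 * K2 * C1 * C2
}

#' @rdname sc_complexity
#' @export
dsc_complexity <- function(W, H, K1, K2, C1, C2) {
  stopifnot(W >= 1, H >= 1, K1 >= 1, K2 >= 1, C1 >= 1, C2 >= 1)
  W * H * K1 * K2 * 1 * C2
}

#' @rdname sc_complexity
#' @export
gsconv_complexity <- function(W, H, K1, K2, C1, C2) {
  stopifnot(W >= 1, H >= 1, K1 >= 1, K2 >= 1, C1 >= 1, C2 >= 1)
  W * H * K1 * K2 * (C2 / 2) * (C1 + 1)
}

#' Count trainable parameters
#'
#' Counts every trainable scalar (conv kernels, biases, batch-norm scale and
#' shift, attention parameters). Multi-branch re-parameterizable blocks are
#' counted in their training-time form unless `fused = TRUE`, in which case the
#' network is re-parameterized (on a copy) first.
#'
#' @param net a `pnet`
#' @param fused count the single-branch inference form instead
#' @return integer parameter count
#' @export
count_params <- function(net, fused = FALSE) {
  if (fused && !isTRUE(net$meta$fused))
    net <- reparameterize_model(clone_net(net), verify = FALSE)$net
  tot <- 0
  for (nd in net$nodes)
    for (p in node_param_names(nd))
      tot <- tot + length(get(p, envir = nd))
  tot
}

#' Count FLOPs
#'
#' Total floating-point operations of one forward pass at a square input,
#' using the 2-x-multiply-accumulate convention over convolution and linear
#' layers (normalization, activations and pooling excluded), in GFLOPs.
#' Multi-branch blocks are counted in their training-time (unfused) form.
#'
#' @param net a `pnet`
#' @param img_size input size, divisible by 32
#' @return GFLOPs
#' @export
count_flops <- function(net, img_size = 640) {
  if (img_size %% 32 != 0)
    stop("invalid-input: image size must be divisible by 32")
  in_shape <- c(img_size, img_size, 3, 1)
  shapes <- infer_shapes(net, in_shape)
  tot <- 0
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    ins <- lapply(nd$from, function(f) if (f == 0) in_shape else shapes[[f]])
    tot <- tot + node_macs(nd, ins, shapes[[i]])
  }
  2 * tot / 1e9
}

#' Estimate serialized weight size
#'
#' `params * bytes-per-scalar / 2^20` plus a fixed serialization overhead.
#'
#' @param net a `pnet`
#' @param precision `"fp16"` or `"fp32"`
#' @param overhead_mb fixed container overhead in MB
#' @return size in MB
#' @export
weight_size_estimate <- function(net, precision = c("fp16", "fp32"),
                                 overhead_mb = 0.25) {
  precision <- match.arg(precision)
  bytes <- if (precision == "fp16") 2 else 4
  count_params(net) * bytes / 2^20 + overhead_mb
}

#' Model summary
#'
#' @param net a `pnet`
#' @param img_size input size for the FLOP count
#' @return list with train/fused parameter counts, GFLOPs, weight-size
#'   estimate and a per-node table
#' @export
model_summary <- function(net, img_size = 640) {
  shapes <- infer_shapes(net, c(img_size, img_size, 3, 1))
  rows <- lapply(seq_along(net$nodes), function(i) {
    nd <- net$nodes[[i]]
    np <- sum(vapply(node_param_names(nd),
                     function(p) length(get(p, envir = nd)), 0))
    data.frame(id = i, type = nd$type,
               out_h = shapes[[i]][1], out_w = shapes[[i]][2],
               out_c = shapes[[i]][3], params = np)
  })
  list(variant = net$meta$variant,
       params_train = count_params(net),
       params_fused = count_params(net, fused = TRUE),
       gflops = count_flops(net, img_size),
       weight_mb = weight_size_estimate(net),
       layers = do.call(rbind, rows))
}
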