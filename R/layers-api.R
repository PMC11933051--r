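# Functional single-block forwards.  Each builds the block as a small graph
# with seed-deterministic weights and runs it in inference mode; they are the
# unit-testable surface of the building blocks.

run_block <- function(x, emit, seed = 0L) {
  set.seed(as.integer(seed))
  gb <- new_graph_builder()
  out <- emit(gb)
  net <- new_pnet(gb$nodes, outputs = list(out = out))
  st <- net_forward(net, x, train = FALSE)
  structure(st$acts[[out]], net = net)
}

#' GSConv forward
#'
#' Standard convolution producing half the output channels, a depthwise
#' convolution producing the other half, concatenated and channel-shuffled
#' with two groups.
#'
#' @param x feature map `(H, W, C, N)`
#' @param out_ch output channels (even)
#' @param k,s kernel and stride of the standard half
#' @param seed weight seed
#' @return feature map
#' @export
gsconv_forward <- function(x, out_ch, k = 1, s = 1, seed = 0L) {
  if (out_ch %% 2 != 0) stop("invalid-spec: GSConv needs an even output width")
  cin <- dim(x)[3]
  run_block(x, function(gb) emit_gsconv(gb, 0L, cin, out_ch, k = k, s = s), seed)
}

#' HGStem forward
#'
#' Stem of the hybrid backbone: five convolutions and one max pooling with a
#' total spatial downsampling of 4.
#'
#' @param x 3-channel image map
#' @param cm stem mid width
#' @param out_ch stem output width
#' @param seed weight seed
#' @export
hgstem_forward <- function(x, cm, out_ch, seed = 0L) {
  d <- dim(x)
  if (d[1] < 8 || d[2] < 8) stop("invalid-input: stem needs at least 8x8 input")
  run_block(x, function(gb) emit_hgstem(gb, 0L, cm, out_ch), seed)
}

#' RepLightConv forward
#'
#' Pointwise 1x1 convolution (linear) followed by an activated depthwise
#' re-parameterizable 3x3 convolution.
#'
#' @param x feature map
#' @param out_ch output channels
#' @param seed weight seed
#' @export
replightconv_forward <- function(x, out_ch, seed = 0L) {
  cin <- dim(x)[3]
  run_block(x, function(gb) emit_replightconv(gb, 0L, cin, out_ch), seed)
}

#' Rep-HGBlock forward
#'
#' `n` chained RepLightConvs densely concatenated with the block input, then
#' 1x1 squeeze and excitation convolutions; optional residual shortcut.
#'
#' @param x feature map
#' @param mid RepLightConv width
#' @param out_ch block output width
#' @param n RepLightConv repeats
#' @param shortcut add the input (requires matching widths)
#' @param seed weight seed
#' @export
rep_hgblock_forward <- function(x, mid, out_ch, n = 6,
                                shortcut = (dim(x)[3] == out_ch), seed = 0L) {
  cin <- dim(x)[3]
  run_block(x, function(gb)
    emit_rep_hgblock(gb, 0L, cin, mid, out_ch, n = n, shortcut = shortcut), seed)
}

#' VoVGSCSP forward
#'
#' Cross-stage-partial block over GSbottlenecks: a 1x1-conv branch through
#' stacked GSbottlenecks and a parallel 1x1-conv branch, concatenated and
#' projected to `out_ch`.
#'
#' @param x feature map
#' @param out_ch output channels (even)
#' @param n GSbottleneck repeats
#' @param k1 kernel of the first GSConv in each bottleneck
#' @param seed weight seed
#' @export
vovgscsp_forward <- function(x, out_ch, n = 1, k1 = 3, seed = 0L) {
  if (out_ch %% 2 != 0) stop("invalid-spec: VoVGSCSP needs an even output width")
  cin <- dim(x)[3]
  run_block(x, function(gb)
    emit_vovgscsp(gb, 0L, cin, out_ch, n = n, k1 = k1), seed)
}
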