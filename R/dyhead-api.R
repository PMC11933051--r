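# Functional dynamic-head attention over a level-stacked pyramid.
#
# A pyramid stack holds L pyramid levels after unification to a common
# spatial size S = h*w and channel width C, as an array (L, S, C).

#' Pyramid stack
#'
#' @param values array or vector of length `L*S*C`
#' @param L,h,w,C levels, unified grid height/width, channels
#' @return a `pyramid_stack`: array `(L, S, C)` with grid attributes
#' @export
pyramid_stack <- function(values, L, h, w, C) {
  stopifnot(L >= 1, h >= 1, w >= 1, C >= 1)
  F <- array(as.double(values), dim = c(L, h * w, C))
  if (!all(is.finite(F))) stop("invalid-input: non-finite pyramid values")
  attr(F, "hw") <- c(h, w)
  class(F) <- c("pyramid_stack", class(F))
  F
}

stack_hw <- function(F) {
  hw <- attr(F, "hw")
  if (is.null(hw)) stop("invalid-input: pyramid stack lacks grid attributes")
  hw
}

# (L, S, C) -> (H, W, C, L) feature-map layout
stack_to_map <- function(F) {
  hw <- stack_hw(F)
  d <- dim(F)
  aperm(array(F, c(d[1], hw[1], hw[2], d[3])), c(2, 3, 4, 1))
}

map_to_stack <- function(m, like) {
  hw <- stack_hw(like)
  d <- dim(like)
  F <- array(aperm(m, c(4, 1, 2, 3)), dim = d)
  attr(F, "hw") <- hw
  class(F) <- class(like)
  F
}

#' Scale-aware attention
#'
#' Gates each pyramid level by `sigma(f(mean_{S,C} F))` where `f` is a linear
#' readout of the per-channel spatial means and `sigma` is the hard sigmoid
#' `max(0, min(1, (x+1)/2))`; the gate lies in `[0, 1]`.
#'
#' @param F a [pyramid_stack()]
#' @param w per-channel readout weights (default `1/C`, i.e. the plain
#'   S,C-mean)
#' @param b readout bias
#' @return gated pyramid stack
#' @export
scale_attention <- function(F, w = NULL, b = 0) {
  d <- dim(F)
  if (is.null(w)) w <- rep(1 / d[3], d[3])
  m <- apply(F, c(1, 3), mean)            # L x C spatial means
  gate <- hardsigmoid_(drop(m %*% w) + b) # per level
  out <- F * as.vector(gate)              # recycles over S, C
  attributes(out) <- attributes(F)
  out
}

#' Spatial-aware attention
#'
#' Importance-weighted deformable sampling aggregated over levels:
#' `out(s, c) = (1/L) sum_l sum_k w[l,k] * F(l; p_s + p_k + dp_k; c) * dm_k`,
#' broadcast back to every level. Sampling is bilinear with coordinates
#' clamped to the feature bounds.
#'
#' @param F a [pyramid_stack()]
#' @param offsets `K x 2` learned offsets (dy, dx), added to the base grid
#' @param dm length-`K` importance weights
#' @param wlk `L x K` aggregation weights
#' @param base `K x 2` base sampling grid; defaults to the centred
#'   `sqrt(K) x sqrt(K)` grid
#' @return pyramid stack
#' @export
spatial_attention <- function(F, offsets, dm, wlk, base = NULL) {
  d <- dim(F)
  K <- length(dm)
  if (is.null(base)) {
    side <- sqrt(K)
    if (side != floor(side)) stop("invalid-spec: K must be a square grid count")
    g <- seq_len(side) - (side + 1) / 2
    base <- as.matrix(expand.grid(dy = g, dx = g))
  }
  if (!all(is.finite(offsets))) stop("invalid-input: non-finite offsets")
  m <- stack_to_map(F)
  o <- cpp_spatial_att(m, base, as.matrix(offsets), as.double(dm),
                       matrix(wlk, d[1], K))
  out <- array(0, dim(m))
  for (l in seq_len(d[1])) out[, , , l] <- o
  map_to_stack(out, F)
}

#' Task-aware attention
#'
#' Per-channel piecewise-linear activation
#' `max(alpha1 * F_c + beta1, alpha2 * F_c + beta2)` with coefficients in
#' `[-1, 1]`.
#'
#' @param F a [pyramid_stack()]
#' @param alpha1,alpha2,beta1,beta2 per-channel coefficients (scalars recycle)
#' @return pyramid stack
#' @export
task_attention <- function(F, alpha1, alpha2, beta1, beta2) {
  d <- dim(F)
  C <- d[3]
  co <- function(v) rep(v, length.out = C)
  if (any(abs(c(co(alpha1), co(alpha2), co(beta1), co(beta2))) > 1 + 1e-12))
    stop("invalid-spec: task-attention coefficients must lie in [-1, 1]")
  a1 <- array(rep(co(alpha1), each = d[1] * d[2]), d)
  a2 <- array(rep(co(alpha2), each = d[1] * d[2]), d)
  b1 <- array(rep(co(beta1), each = d[1] * d[2]), d)
  b2 <- array(rep(co(beta2), each = d[1] * d[2]), d)
  out <- pmax(a1 * F + b1, a2 * F + b2)
  attributes(out) <- attributes(F)
  out
}

#' Dynamic-head tower
#'
#' Applies `blocks` repetitions of scale-, spatial- and task-aware attention
#' in sequence. `block_params` supplies the per-block parameter lists
#' (recycled); the default parameters make each block the identity map, which
#' is the reference point for composition tests.
#'
#' @param F a [pyramid_stack()]
#' @param blocks number of attention blocks (>= 1)
#' @param block_params list with elements `scale` (`w`, `b`), `spatial`
#'   (`offsets`, `dm`, `wlk`, `base`) and `task`
#'   (`alpha1`, `alpha2`, `beta1`, `beta2`)
#' @return pyramid stack
#' @export
dyhead_tower <- function(F, blocks = 1, block_params = NULL) {
  if (blocks < 1) stop("invalid-spec: tower needs at least one block")
  d <- dim(F)
  if (is.null(block_params))
    block_params <- list(
      scale = list(w = rep(0, d[3]), b = 1),   # saturated gate = 1
      spatial = list(offsets = matrix(0, 1, 2), dm = 1,
                     wlk = matrix(1, d[1], 1), base = matrix(0, 1, 2)),
      task = list(alpha1 = 1, alpha2 = 1, beta1 = 0, beta2 = 0))
  for (b in seq_len(blocks)) {
    F <- scale_attention(F, block_params$scale$w, block_params$scale$b)
    F <- spatial_attention(F, block_params$spatial$offsets,
                           block_params$spatial$dm, block_params$spatial$wlk,
                           block_params$spatial$base)
    F <- task_attention(F, block_params$task$alpha1, block_params$task$alpha2,
                        block_params$task$beta1, block_params$task$beta2)
  }
  F
}
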