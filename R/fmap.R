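#' Feature maps
#'
#' Activations flowing through a network are plain 4-d arrays with
#' `dim = c(H, W, C, N)` (height, width, channels, batch). `fmap()` builds one
#' from a vector or array and validates the invariants: all dimensions at
#' least 1 and all values finite.
#'
#' @param values numeric vector or array of length `h*w*c*n`
#' @param h,w,c,n dimensions
#' @return a 4-d array
#' @export
fmap <- function(values, h, w, c, n = 1L) {
  stopifnot(h >= 1, w >= 1, c >= 1, n >= 1)
  x <- array(as.double(values), dim = c(h, w, c, n))
  if (!all(is.finite(x))) stop("invalid-input: feature map contains non-finite values")
  x
}

#' @rdname fmap
#' @param x a feature map
#' @export
fmap_dim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  c(h = d[1], w = d[2], c = d[3], n = d[4])
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

silu_ <- function(x) x / (1 + exp(-x))

silu_grad_ <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

hardsigmoid_ <- function(x) pmax(0, pmin(1, (x + 1) / 2))

relu_ <- function(x) pmax(x, 0)

act_fwd <- function(x, act) {
  switch(act, silu = silu_(x), relu = relu_(x), none = x,
         stop("unknown activation: ", act))
}

act_bwd <- function(g, x, act) {
  switch(act,
         silu = g * silu_grad_(x),
         relu = g * (x > 0),
         none = g,
         stop("unknown activation: ", act))
}

#' Channel shuffle
#'
#' Permutes the channel axis so that channel `c` (0-based) moves to position
#' `(c mod g) * (C/g) + floor(c/g)`; values are untouched. Used inside GSConv
#' to mix the standard-convolution half with the depthwise half.
#'
#' @param x feature map (H, W, C, N)
#' @param groups number of shuffle groups; must divide C
#' @return feature map with permuted channels
#' @export
channel_shuffle <- function(x, groups) {
  d <- dim(x)
  C <- d[3]
  if (C %% groups != 0) stop("invalid-spec: channels not divisible by groups")
  x[, , shuffle_order(C, groups), , drop = FALSE]
}

# old channel index (1-based) feeding each new position
shuffle_order <- function(C, groups) {
  cc <- 0:(C - 1)
  newpos <- (cc %% groups) * (C %/% groups) + cc %/% groups
  order(newpos)
}
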