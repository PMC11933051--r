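# dynamic-head attention: scale gates, deformable spatial sampling,
# task-aware activation, tower composition, offset gradients

test_that("scale attention gates with the hard sigmoid", {
  set.seed(1)
  F <- pyramid_stack(rnorm(3 * 16 * 4), 3, 4, 4, 4)
  # f == 0 -> gate 0.5
  expect_equal(unclass(scale_attention(F, w = rep(0, 4), b = 0)),
               unclass(F) * 0.5, ignore_attr = TRUE)
  # f >= 1 saturates at 1; f <= -1 at 0
  expect_equal(unclass(scale_attention(F, w = rep(0, 4), b = 5)),
               unclass(F), ignore_attr = TRUE)
  expect_equal(max(abs(scale_attention(F, w = rep(0, 4), b = -5))), 0)
  # gates always within [0, 1]: output never exceeds input in magnitude
  for (rep in 1:5) {
    w <- rnorm(4); b <- rnorm(1)
    out <- scale_attention(F, w, b)
    expect_true(all(abs(out) <= abs(unclass(F)) + 1e-12))
  }
})

test_that("spatial attention reference points", {
  set.seed(2)
  F1 <- pyramid_stack(rnorm(1 * 25 * 3), 1, 5, 5, 3)
  # L=1, K=1, zero offset, unit weights: identity
  out <- spatial_attention(F1, offsets = matrix(0, 1, 2), dm = 1,
                           wlk = matrix(1, 1, 1), base = matrix(0, 1, 2))
  expect_equal(unclass(out), unclass(F1), ignore_attr = TRUE)
  # zero importance: zero output
  out0 <- spatial_attention(F1, offsets = matrix(0, 1, 2), dm = 0,
                            wlk = matrix(1, 1, 1), base = matrix(0, 1, 2))
  expect_equal(max(abs(out0)), 0)
  # two identical levels average to either level
  v <- rnorm(25 * 3)
  F2 <- pyramid_stack(c(rbind(v, v)), 2, 5, 5, 3)
  out2 <- spatial_attention(F2, offsets = matrix(0, 1, 2), dm = 1,
                            wlk = matrix(1, 2, 1), base = matrix(0, 1, 2))
  expect_equal(out2[1, , ], F2[1, , ], tolerance = 1e-12)
  expect_equal(out2[2, , ], F2[1, , ], tolerance = 1e-12)
})

test_that("spatial attention offset gradients match finite differences", {
  set.seed(3)
  H <- 6; W <- 6; C <- 2; L <- 2; K <- 4
  Fm <- array(rnorm(H * W * C * L), c(H, W, C, L))
  base <- matrix(0, K, 2)
  off <- matrix(runif(K * 2, -0.8, 0.8), K, 2)
  dm <- runif(K); wlk <- matrix(runif(L * K), L, K)
  g <- array(rnorm(H * W * C), c(H, W, C))
  bwd <- pestnet:::cpp_spatial_att_bwd(Fm, base, off, dm, wlk, g)
  lossf <- function(offx) sum(pestnet:::cpp_spatial_att(Fm, base, offx, dm, wlk) * g)
  eps <- 1e-6
  for (k in 1:K) for (j in 1:2) {
    op <- off; op[k, j] <- op[k, j] + eps
    om <- off; om[k, j] <- om[k, j] - eps
    num <- (lossf(op) - lossf(om)) / (2 * eps)
    expect_equal(bwd$goff[k, j], num, tolerance = 1e-5)
  }
  # importance and aggregation weight gradients too
  lossm <- function(dmx) sum(pestnet:::cpp_spatial_att(Fm, base, off, dmx, wlk) * g)
  for (k in 1:K) {
    dp <- dm; dp[k] <- dp[k] + eps
    dmn <- dm; dmn[k] <- dmn[k] - eps
    expect_equal(bwd$gdm[k], (lossm(dp) - lossm(dmn)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("task attention reference activations and bounds", {
  set.seed(4)
  F <- pyramid_stack(rnorm(2 * 9 * 5), 2, 3, 3, 5)
  relu <- task_attention(F, 1, 0, 0, 0)
  expect_equal(unclass(relu), pmax(unclass(F), 0), ignore_attr = TRUE)
  ident <- task_attention(F, 1, 1, 0, 0)
  expect_equal(unclass(ident), unclass(F), ignore_attr = TRUE)
  absv <- task_attention(F, 1, -1, 0, 0)
  expect_equal(unclass(absv), abs(unclass(F)), ignore_attr = TRUE)
  expect_error(task_attention(F, 2, 0, 0, 0), "\\[-1, 1\\]")
  # output dominates each single affine branch
  a1 <- runif(5, -1, 1); a2 <- runif(5, -1, 1)
  b1 <- runif(5, -1, 1); b2 <- runif(5, -1, 1)
  out <- task_attention(F, a1, a2, b1, b2)
  br1 <- unclass(F) * rep(a1, each = 2 * 9) + rep(b1, each = 2 * 9)
  expect_true(all(out >= br1 - 1e-12))
})

test_that("tower composition: identity settings give the identity map", {
  set.seed(5)
  F <- pyramid_stack(rnorm(1 * 16 * 3), 1, 4, 4, 3)
  for (blocks in c(1, 3)) {
    out <- dyhead_tower(F, blocks = blocks)
    expect_equal(unclass(out), unclass(F), ignore_attr = TRUE)
    expect_equal(dim(out), dim(F))
  }
  expect_error(dyhead_tower(F, blocks = 0), "at least one block")
  # shape preservation under arbitrary parameters
  F3 <- pyramid_stack(rnorm(3 * 16 * 4), 3, 4, 4, 4)
  bp <- list(scale = list(w = rnorm(4), b = 0.2),
             spatial = list(offsets = matrix(rnorm(18, 0, 0.3), 9, 2),
                            dm = runif(9), wlk = matrix(runif(27), 3, 9),
                            base = NULL),
             task = list(alpha1 = runif(4, -1, 1), alpha2 = runif(4, -1, 1),
                         beta1 = runif(4, -1, 1), beta2 = runif(4, -1, 1)))
  out3 <- dyhead_tower(F3, blocks = 2, block_params = bp)
  expect_equal(dim(out3), dim(F3))
  expect_true(all(is.finite(out3)))
})
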