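# structural re-parameterization: BN folding, branch lifting, fusion
# equivalence at block and whole-model level

test_that("BN folding matches hand-computed values and a numeric oracle", {
  # identity BN leaves the kernel untouched
  w <- array(1:8, c(1, 1, 2, 4))
  f <- fuse_conv_bn(w, bn_params(rep(1, 4), rep(0, 4), rep(0, 4), rep(1, 4),
                                 eps = 0))
  expect_equal(f$kernel, w)
  expect_equal(f$bias, rep(0, 4))
  # w=2, gamma=2, var=3, eps=1, mu=1, beta=0.5 -> w'=2, b'=-0.5
  w1 <- array(2, c(1, 1, 1, 1))
  f1 <- fuse_conv_bn(w1, bn_params(2, 0.5, 1, 3, eps = 1))
  expect_equal(as.numeric(f1$kernel), 2)
  expect_equal(f1$bias, -0.5)
  # fused layer equals conv + eval BN on random probes
  set.seed(1)
  w3 <- array(rnorm(3 * 3 * 4 * 6), c(3, 3, 4, 6))
  bn <- bn_params(runif(6, 0.5, 2), rnorm(6), rnorm(6), runif(6, 0.5, 2))
  fz <- fuse_conv_bn(w3, bn)
  mx <- 0
  for (p in 1:100) {
    x <- rand_fmap(6, 6, 4, 1)
    a <- pestnet:::bn_apply(pestnet:::cpp_conv2d(x, w3, 1L, 1L, 1L), bn)
    z <- pestnet:::cpp_conv2d(x, fz$kernel, 1L, 1L, 1L)
    b <- z + pestnet:::bc_chan(fz$bias, dim(z))
    mx <- max(mx, max(abs(a - b)))
  }
  expect_lt(mx, 1e-10)
})

test_that("1x1 lifting and identity kernels are exact", {
  k1 <- array(5, c(1, 1, 1, 1))
  k3 <- lift_1x1_to_3x3(k1)
  expect_equal(k3[2, 2, 1, 1], 5)
  expect_equal(sum(k3 != 0), 1L)
  expect_error(lift_1x1_to_3x3(array(0, c(3, 3, 1, 1))), "1x1")
  expect_equal(lift_1x1_to_3x3(array(0, c(1, 1, 2, 3))),
               array(0, c(3, 3, 2, 3)))
  # lifted conv (pad 1) equals the original 1x1 conv on random input
  set.seed(2)
  kk <- array(rnorm(8 * 5), c(1, 1, 8, 5))
  x <- rand_fmap(7, 7, 8, 2)
  expect_equal(pestnet:::cpp_conv2d(x, lift_1x1_to_3x3(kk), 1L, 1L, 1L),
               pestnet:::cpp_conv2d(x, kk, 1L, 0L, 1L), tolerance = 1e-12)
  # Dirac kernels reproduce the identity map
  idk <- identity_to_3x3(2, 1)
  expect_equal(idk[2, 2, 1, 1], 1); expect_equal(idk[2, 2, 2, 2], 1)
  expect_equal(sum(idk), 2)
  x2 <- rand_fmap(5, 5, 6, 2)
  expect_equal(pestnet:::cpp_conv2d(x2, identity_to_3x3(6, 1), 1L, 1L, 1L), x2,
               tolerance = 1e-14)
  dw <- identity_to_3x3(4, 4)   # depthwise: centre 1 on each 1-channel kernel
  expect_equal(dim(dw), c(3, 3, 1, 4))
  expect_true(all(dw[2, 2, 1, ] == 1))
  expect_error(identity_to_3x3(5, 2), "divisible")
})

test_that("multi-branch and fused forwards agree on random probes", {
  set.seed(3)
  cases <- list(list(cin = 8, cout = 8, g = 1, id = TRUE),
                list(cin = 8, cout = 8, g = 8, id = TRUE),
                list(cin = 6, cout = 10, g = 2, id = FALSE))
  for (cs in cases) {
    p <- make_repconv_params(cs$cin, cs$cout, cs$g, identity = cs$id)
    fk <- fuse_repconv(p)
    expect_equal(length(fk$kernel) + length(fk$bias),
                 cs$cout * (cs$cin / cs$g) * 9 + cs$cout)
    mx <- 0
    for (pr in 1:100) {
      x <- rand_fmap(8, 8, cs$cin, 1)
      a <- repconv_forward_train(x, p, act = "silu")
      b <- repconv_forward_fused(x, fk, groups = cs$g, act = "silu")
      mx <- max(mx, max(abs(a - b)))
    }
    expect_lt(mx, 1e-5)   # well inside the single-precision band
    expect_lt(mx, 1e-10)  # and the double-precision band
  }
  # zero 1x1 branch and no identity: fused kernel equals the folded 3x3 alone
  p <- make_repconv_params(4, 6, identity = FALSE)
  p$w1[] <- 0; p$bn1 <- bn_params(rep(1, 6), rep(0, 6), rep(0, 6), rep(1, 6),
                                  eps = 0)
  expect_equal(fuse_repconv(p)$kernel, fuse_conv_bn(p$w3, p$bn3)$kernel)
  # zero input with zero shifts gives zero pre-activation output
  p0 <- make_repconv_params(4, 4)
  p0$bn3$beta[] <- 0; p0$bn1$beta[] <- 0; p0$bnid$beta[] <- 0
  p0$bn3$mean[] <- 0; p0$bn1$mean[] <- 0; p0$bnid$mean[] <- 0
  y0 <- repconv_forward_train(array(0, c(4, 4, 4, 1)), p0, act = "none")
  expect_equal(max(abs(y0)), 0)
})

test_that("whole-model re-parameterization is equivalent and idempotent", {
  net <- build_model(model_config("rep_hgnetv2", nc = 5, img_size = 64), seed = 1)
  # give the BN layers non-trivial running statistics first
  invisible(net_forward(net, rand_fmap(64, 64, 3, 2, seed = 4), train = TRUE))
  r <- reparameterize_model(net, verify = TRUE, n_probes = 3, img_size = 64,
                            tol = 1e-10)
  expect_true(r$report$passed)
  expect_lt(r$report$max_abs_diff, 1e-10)
  expect_lt(count_params(r$net), count_params(net))
  expect_lt(count_flops(r$net, 64), count_flops(net, 64))
  # idempotent: no multi-branch blocks remain
  r2 <- reparameterize_model(r$net, verify = TRUE, n_probes = 1, img_size = 64)
  expect_equal(count_params(r2$net), count_params(r$net))
  expect_equal(r2$report$max_abs_diff, 0)
})
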