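# building-block layers: shuffle permutation, GSConv, HGStem, RepLightConv,
# Rep-HGBlock, VoVGSCSP

test_that("conv kernel matches a direct-summation oracle", {
  set.seed(7)
  for (case in list(list(k = 3, s = 1, p = 1, g = 1, cin = 5, cout = 4),
                    list(k = 1, s = 1, p = 0, g = 1, cin = 4, cout = 6),
                    list(k = 3, s = 2, p = 1, g = 4, cin = 4, cout = 4),
                    list(k = 2, s = 1, p = 0, g = 1, cin = 3, cout = 2))) {
    x <- rand_fmap(7, 6, case$cin, 2)
    w <- array(rnorm(case$k^2 * (case$cin / case$g) * case$cout),
               c(case$k, case$k, case$cin / case$g, case$cout))
    expect_equal(pestnet:::cpp_conv2d(x, w, case$s, case$p, case$g),
                 conv2d_ref(x, w, case$s, case$p, case$g), tolerance = 1e-12)
  }
})

test_that("channel shuffle applies the stated permutation and is value-preserving", {
  x <- fmap(1:(2 * 2 * 4), 2, 2, 4)
  y <- channel_shuffle(x, 2)
  # channel c -> (c mod g)*(C/g) + floor(c/g): order [0,1,2,3] -> [0,2,1,3]
  expect_equal(y[1, 1, , 1], x[1, 1, c(1, 3, 2, 4), 1])
  expect_equal(channel_shuffle(x, 1), x)                    # identity at g=1
  expect_equal(channel_shuffle(y, 2), x)                    # self-inverse here
  expect_error(channel_shuffle(x, 3), "divisible")
  # permutation property: per-location multisets unchanged
  x2 <- rand_fmap(3, 3, 12, 2, seed = 1)
  y2 <- channel_shuffle(x2, 3)
  expect_equal(apply(y2, c(1, 2, 4), sort), apply(x2, c(1, 2, 4), sort))
})

test_that("GSConv shape contract and parameter advantage", {
  x <- rand_fmap(20, 20, 64, 1, seed = 2)
  expect_equal(dim(gsconv_forward(x, 64, k = 1, s = 1)), c(20, 20, 64, 1))
  x2 <- rand_fmap(40, 40, 32, 1, seed = 3)
  y2 <- gsconv_forward(x2, 64, k = 3, s = 2)
  expect_equal(dim(y2), c(20, 20, 64, 1))
  expect_true(all(is.finite(y2)))
  expect_error(gsconv_forward(x2, 63), "even")
  # weight count of both halves is below the full standard conv
  gs_weights <- 3 * 3 * 64 * 32 + 3 * 3 * 1 * 32
  expect_lt(gs_weights, 3 * 3 * 64 * 64)
  # spatial preservation with out = 2*in, k = 1, s = 1
  x3 <- rand_fmap(9, 13, 8, 2, seed = 4)
  expect_equal(dim(gsconv_forward(x3, 16))[1:2], c(9, 13))
})

test_that("HGStem downsamples by 4 with five convs and one pool", {
  x <- rand_fmap(64, 64, 3, 1, seed = 5)
  y <- hgstem_forward(x, 16, 24)
  expect_equal(dim(y), c(16, 16, 24, 1))
  net <- attr(y, "net")
  types <- vapply(net$nodes, function(nd) nd$type, "")
  expect_equal(sum(types == "conv"), 5L)
  expect_equal(sum(types == "maxpool"), 1L)
  expect_error(hgstem_forward(rand_fmap(4, 4, 3, 1), 16, 24), "8x8")
  y640 <- hgstem_forward(rand_fmap(160, 160, 3, 1, seed = 6), 16, 24)
  expect_equal(dim(y640)[1:2], c(40, 40))
})

test_that("RepLightConv shape and parameter accounting", {
  x <- rand_fmap(16, 16, 32, 1, seed = 7)
  y <- replightconv_forward(x, 64)
  expect_equal(dim(y), c(16, 16, 64, 1))
  net <- attr(y, "net")
  # multi-branch weight count (kernels only): pointwise + depthwise 3x3 + 1x1
  nw <- 0
  for (nd in net$nodes)
    nw <- nw + if (nd$type == "conv") length(nd$w)
      else length(nd$w3) + length(nd$w1)
  expect_equal(nw, 1 * 1 * 32 * 64 + 3 * 3 * 64 + 1 * 1 * 64)
  # after fusing, the depthwise block is one 3x3 kernel plus bias
  fused <- reparameterize_model(net, verify = FALSE)$net
  expect_equal(sum(vapply(fused$nodes, function(nd)
    length(nd$w) + if (!is.null(nd$bias)) length(nd$bias) else 0L, 0)),
    1 * 1 * 32 * 64 + 3 * 3 * 64 + 64)
})

test_that("Rep-HGBlock dense aggregation, residual identity and shapes", {
  # concat width before squeeze: in + n*mid
  x <- rand_fmap(8, 8, 64, 1, seed = 8)
  y <- rep_hgblock_forward(x, mid = 32, out_ch = 64, n = 6, shortcut = TRUE)
  expect_equal(dim(y), c(8, 8, 64, 1))
  net <- attr(y, "net")
  cats <- Filter(function(nd) nd$type == "concat", net$nodes)
  sq <- net$nodes[[max(vapply(cats, function(nd) nd$id, 0L)) + 1L]]
  expect_equal(dim(sq$w)[3], 64 + 6 * 32)
  # zero-initialized convs + shortcut: output equals input
  for (nd in net$nodes) {
    if (nd$type == "conv") nd$w[] <- 0
    if (nd$type == "repconv") { nd$w3[] <- 0; nd$w1[] <- 0
      if (nd$has_id) { nd$bnid_g[] <- 0 } }
  }
  st <- net_forward(net, x)
  expect_equal(st$acts[[net$outputs$out]], x)
  expect_error(rep_hgblock_forward(x, 16, 32, shortcut = TRUE), "matching")
})

test_that("VoVGSCSP shape contract, skip path and parameter advantage", {
  x <- rand_fmap(10, 10, 128, 1, seed = 9)
  y <- vovgscsp_forward(x, 128, n = 1)
  expect_equal(dim(y), c(10, 10, 128, 1))
  expect_true(all(is.finite(y)))
  expect_error(vovgscsp_forward(x, 127), "even")
  # GSbottleneck skip: zero-weight GSConvs leave the shortcut value
  gb <- pestnet:::new_graph_builder()
  set.seed(10)
  out <- pestnet:::emit_gsbottleneck(gb, 0L, 16)
  net <- pestnet:::new_pnet(gb$nodes, outputs = list(out = out))
  for (nd in net$nodes) if (nd$type == "conv") { nd$w[] <- 0; nd$bn_b[] <- 0 }
  x16 <- rand_fmap(6, 6, 16, 1, seed = 11)
  st <- net_forward(net, x16)
  expect_equal(st$acts[[out]], x16)
  # fewer parameters than a C2f block of equal width
  gb1 <- pestnet:::new_graph_builder()
  set.seed(0)
  o1 <- pestnet:::emit_vovgscsp(gb1, 0L, 128, 128, n = 1)
  n1 <- pestnet:::new_pnet(gb1$nodes, outputs = list(out = o1))
  gb2 <- pestnet:::new_graph_builder()
  set.seed(0)
  o2 <- pestnet:::emit_c2f(gb2, 0L, 128, 128, n = 1, shortcut = FALSE)
  n2 <- pestnet:::new_pnet(gb2$nodes, outputs = list(out = o2))
  expect_lt(count_params(n1), count_params(n2))
})

test_that("layer outputs stay finite for finite inputs", {
  x <- rand_fmap(12, 12, 8, 2, seed = 12) * 10
  for (y in list(gsconv_forward(x, 16, k = 3, s = 1),
                 replightconv_forward(x, 12),
                 vovgscsp_forward(x, 8, n = 2)))
    expect_true(all(is.finite(y)))
})
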