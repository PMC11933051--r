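# LAMP scoring, channel aggregation, plan search and physical pruning

test_that("LAMP scores match the definition on hand examples", {
  s <- lamp_scores(c(1, 2, 3))
  expect_equal(s, c(1 / 14, 4 / 13, 1), tolerance = 1e-15)
  expect_equal(lamp_scores(5), 1)
  expect_error(lamp_scores(c(0, 0)), "degenerate-layer")
  # max-magnitude weight always scores exactly 1
  set.seed(1)
  for (rep in 1:10) {
    w <- rnorm(sample(2:64, 1))
    s <- lamp_scores(w)
    expect_equal(s[which.max(abs(w))], 1)
    expect_true(all(s > 0 & s <= 1))
  }
})

test_that("LAMP oracle equivalence and scale invariance", {
  set.seed(2)
  for (rep in 1:25) {
    w <- rnorm(sample(2:64, 1)) * 10^runif(1, -2, 2)
    expect_equal(lamp_scores(w), lamp_ref(w), tolerance = 1e-12)
    expect_equal(lamp_scores(w * runif(1, 0.01, 100)), lamp_scores(w),
                 tolerance = 1e-12)
  }
})

test_that("channel importance aggregates layer-wide scores", {
  W <- rbind(c(1, 2), c(3, 4))
  # global sort 1,2,3,4; suffix sums 30,29,25,16
  expect_equal(channel_importance(W),
               c(1 / 30 + 4 / 29, 9 / 25 + 16 / 16), tolerance = 1e-12)
  # tied magnitudes occupy distinct suffix positions (equal-magnitude weights
  # carry different scores); ties resolve stably by index, so the
  # earlier-indexed copy sees the larger denominators
  W2 <- rbind(c(1, -2, 0.5), c(1, -2, 0.5))
  imp <- channel_importance(W2)
  expect_lt(imp[1], imp[2])
  expect_equal(sum(imp), sum(lamp_scores(as.vector(W2))), tolerance = 1e-12)
  # a channel holding the largest weights dominates
  W3 <- rbind(c(10, 10, 10), c(0.1, 0.2, 0.1))
  expect_gt(channel_importance(W3)[1], channel_importance(W3)[2])
})

test_that("plan search hits the speed-up target and is monotone", {
  net <- build_model(model_config("rsd", nc = 5, img_size = 64), seed = 0)
  p15 <- plan_pruning(net, speed_up = 1.5, img_size = 64)
  expect_gte(p15$speed_up_achieved, 1.5)
  expect_lte(p15$flops_after, p15$flops_before / 1.5 * 1.0001)
  p20 <- plan_pruning(net, speed_up = 2.0, img_size = 64)
  expect_lte(p20$flops_after, p15$flops_after)           # monotonicity
  # boundary: barely-above-1 target keeps nearly everything
  p1 <- plan_pruning(net, speed_up = 1.0001, img_size = 64)
  expect_gte(p1$speed_up_achieved, 1.0001)
  expect_lt(length(p1$removed_groups), length(p15$removed_groups))
  expect_error(plan_pruning(net, speed_up = 1), "exceed 1")
})

test_that("a fully protected toy network is infeasible to prune", {
  gb <- pestnet:::new_graph_builder()
  set.seed(3)
  a <- pestnet:::emit_conv(gb, 0L, 3, 8, k = 3, s = 2, role = "stem1")
  b <- pestnet:::emit_conv(gb, a, 8, 8, k = 3, role = "detect_final")
  d <- pestnet:::emit_conv(gb, b, 8, 4, k = 1, role = "detect_final")
  net <- pestnet:::new_pnet(gb$nodes, outputs = list(out = d))
  expect_error(plan_pruning(net, speed_up = 10, img_size = 64),
               "infeasible-plan")
})

test_that("applying a plan slices channels physically and keeps the forward valid", {
  net <- build_model(model_config("rsd", nc = 5, img_size = 64), seed = 0)
  plan <- plan_pruning(net, speed_up = 1.5, img_size = 64)
  pruned <- apply_pruning(net, plan)
  expect_lt(count_params(pruned), count_params(net))
  expect_lt(count_flops(pruned, 64), count_flops(net, 64))
  expect_equal(count_flops(pruned, 64), plan$flops_after, tolerance = 1e-8)
  # per-layer channel counts match the plan exactly
  got <- vapply(plan$channels$layer, function(i) {
    nd <- pruned$nodes[[i]]
    if (nd$type == "conv") dim(nd$w)[4] else dim(nd$w3)[4]
  }, 0)
  expect_equal(got, plan$channels$channels_after, ignore_attr = TRUE)
  # pruned forward produces decodable detections without shape errors
  x <- rand_fmap(64, 64, 3, 1, seed = 4)
  dets <- predict_boxes(pruned, x, conf_thr = 0.001)
  expect_true(is.data.frame(dets[[1]]))
  # protected layers keep full width
  for (i in plan$protected) {
    nd <- pruned$nodes[[i]]
    co <- if (nd$type == "conv") dim(nd$w)[4] else dim(nd$w3)[4]
    co0 <- if (net$nodes[[i]]$type == "conv") dim(net$nodes[[i]]$w)[4]
           else dim(net$nodes[[i]]$w3)[4]
    expect_equal(co, co0)
  }
})

test_that("a keep-all plan leaves outputs byte-identical", {
  net <- build_model(model_config("slimneck", nc = 4, img_size = 64), seed = 1)
  plan <- plan_pruning(net, speed_up = 1.0001, img_size = 64)
  # force an actually empty removal set for the identity check
  plan$removed_groups <- numeric(0)
  plan$keep_out <- lapply(plan$keep_out, function(k)
    if (is.null(k)) NULL else rep(TRUE, length(k)))
  plan$keep_in <- lapply(plan$keep_in, function(k)
    if (is.null(k)) NULL else rep(TRUE, length(k)))
  pruned <- apply_pruning(net, plan)
  x <- rand_fmap(64, 64, 3, 1, seed = 5)
  a <- net_forward(net, x)$acts[[net$outputs$cls[1]]]
  b <- net_forward(pruned, x)$acts[[pruned$outputs$cls[1]]]
  expect_identical(a, b)
  expect_error(apply_pruning(build_model(model_config("baseline", nc = 4,
                                                      img_size = 64), 0),
                             plan), "invalid-plan")
})
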