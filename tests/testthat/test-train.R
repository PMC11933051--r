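# loss components, gradients, assigner behaviour, short descent runs

mk_raw <- function(net, x) {
  st <- net_forward(net, x, train = TRUE)
  list(st = st,
       raw = list(reg = lapply(net$outputs$reg, function(i) st$acts[[i]]),
                  cls = lapply(net$outputs$cls, function(i) st$acts[[i]])))
}

test_that("training configuration validates its invariants", {
  cfg <- train_config()
  expect_equal(cfg$optimizer, "SGD")
  expect_equal(cfg$lr0, 0.01)
  expect_equal(cfg$momentum, 0.937)
  expect_equal(cfg$weight_decay, 0.005)
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$close_mosaic, 10L)
  expect_error(train_config(epochs = 5, close_mosaic = 10), "close_mosaic")
})

test_that("loss components are finite, non-negative and behave at the edges", {
  set.seed(1)
  net <- build_model(model_config("baseline", nc = 4, img_size = 64), seed = 1)
  x <- rand_fmap(64, 64, 3, 1, seed = 2) * 0.5 + 0.5
  r <- mk_raw(net, x)
  tg <- list(data.frame(class_id = 1L, x1 = 8, y1 = 8, x2 = 40, y2 = 40))
  ls <- compute_loss(r$raw, tg, nc = 4)
  expect_true(all(is.finite(c(ls$loss, ls$components))))
  expect_true(all(ls$components >= 0))
  # no objects: box and dfl terms vanish, cls persists from negatives
  ls0 <- compute_loss(r$raw, list(tg[[1]][0, ]), nc = 4)
  expect_equal(unname(ls0$components["box"]), 0)
  expect_equal(unname(ls0$components["dfl"]), 0)
  expect_gt(unname(ls0$components["cls"]), 0)
  # NaN predictions are rejected with a numeric error
  bad <- r$raw
  bad$cls[[1]][1] <- NaN
  expect_error(compute_loss(bad, tg, nc = 4), "numeric error")
})

test_that("loss gradients match finite differences through the raw outputs", {
  set.seed(3)
  net <- build_model(model_config("baseline", nc = 3, img_size = 64), seed = 3)
  x <- rand_fmap(64, 64, 3, 1, seed = 4) * 0.5 + 0.5
  r <- mk_raw(net, x)
  tg <- list(data.frame(class_id = c(0L, 2L), x1 = c(4, 30), y1 = c(4, 30),
                        x2 = c(28, 60), y2 = c(28, 60)))
  ls <- compute_loss(r$raw, tg, nc = 3)
  eps <- 1e-5
  # targets (assignment + scores) are constants w.r.t. the gradients, so the
  # numeric oracle evaluates the loss under the same frozen assignment
  lossat <- function(raw) compute_loss(raw, tg, nc = 3, want_grads = FALSE,
                                       assignment = ls$assignment)$loss
  for (part in c("reg", "cls")) for (lvl in c(1, 3)) {
    g <- ls$grads[[part]][[lvl]]
    hot <- order(-abs(g))[1:4]
    for (k in hot) {
      rp <- r$raw; rp[[part]][[lvl]][k] <- rp[[part]][[lvl]][k] + eps
      rm <- r$raw; rm[[part]][[lvl]][k] <- rm[[part]][[lvl]][k] - eps
      num <- (lossat(rp) - lossat(rm)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 5e-3)
    }
  }
})

test_that("gradient steps on a fixed tiny batch decrease the loss", {
  set.seed(5)
  net <- build_model(model_config("rsd", nc = 8, img_size = 64), seed = 5)
  sc <- generate_scene(scene_spec(img_size = 64, class_count = 8,
                                  preset = "easy", seed = 31))
  x <- array(sc$image, c(64, 64, 3, 1))
  tg <- list(sc$boxes)
  losses <- numeric(3)
  asg <- NULL   # freeze the assignment after the first step: descent is a
                # property of the loss with detached targets
  for (it in 1:3) {
    st <- net_forward(net, x, train = TRUE)
    raw <- list(reg = lapply(net$outputs$reg, function(i) st$acts[[i]]),
                cls = lapply(net$outputs$cls, function(i) st$acts[[i]]))
    ls <- compute_loss(raw, tg, nc = 8, assignment = asg)
    if (is.null(asg)) asg <- ls$assignment
    losses[it] <- ls$loss
    gouts <- list()
    for (l in 1:3) {
      gouts[[as.character(net$outputs$reg[l])]] <- ls$grads$reg[[l]]
      gouts[[as.character(net$outputs$cls[l])]] <- ls$grads$cls[[l]]
    }
    pestnet:::net_backward(net, st, gouts)
    pestnet:::sgd_step(net, lr = 2e-4, momentum = 0, weight_decay = 0)
    pestnet:::zero_grads(net)
  }
  expect_lt(losses[3], losses[1])
})

test_that("short fits are deterministic and log full histories", {
  man <- tiny_easy_manifest(n = 10, img_size = 64, seed = 6,
                            dir = file.path(tempdir(), "pn_fit"))
  cfg <- train_config(epochs = 2, batch = 4, img_size = 64, close_mosaic = 1,
                      warmup_epochs = 1, seed = 7)
  n1 <- build_model(model_config("slimneck", nc = 29, img_size = 64), seed = 7)
  r1 <- fit_detector(n1, man, cfg)
  expect_equal(nrow(r1$history), 2L)
  expect_true(all(c("loss", "box", "cls", "dfl", "val_map50") %in%
                    names(r1$history)))
  n2 <- build_model(model_config("slimneck", nc = 29, img_size = 64), seed = 7)
  r2 <- fit_detector(n2, man, cfg)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_error(fit_detector(n1, man[man$split == "val", ], cfg),
               "empty training split")
})
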