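test_that("the merged feature dimension is backbone dim + handcrafted count", {
  for (case in list(list("tiny-test", 16L), list("resnet18", 512L))) {
    for (p in c(9L, 11L)) {
      cfg <- fusion_config(backbone = case[[1]], n_handcrafted = p, seed = 2)
      net <- build_fusion_net(cfg)
      expect_equal(net$merged_dim, case[[2]] + p)
      expect_equal(ncol(net$head$W), case[[2]] + p)
    }
  }
  cfg <- fusion_config(seed = 1)
  cfg$backbone <- "alexnet"
  expect_error(build_fusion_net(cfg), "unknown backbone")
})

test_that("every backbone's forward pass yields scores in [0, 1]", {
  set.seed(77)
  fb <- matrix(runif(18), 9, 2)
  for (bb in c("tiny-test", "vgg16", "vgg19", "resnet18", "resnet34")) {
    cfg <- fusion_config(backbone = bb, input_mode = "rgb",
                         n_handcrafted = 9, seed = 3)
    net <- build_fusion_net(cfg)
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    fw <- ecgfusion:::.fusion_forward(net, x, fb, cfg)
    expect_length(fw$scores, 2)
    expect_true(all(fw$scores >= 0 & fw$scores <= 1))
  }
  # grayscale mode adapts the first convolution to one channel
  cfg <- fusion_config(backbone = "tiny-test", input_mode = "gray",
                       n_handcrafted = 11, seed = 3)
  net <- build_fusion_net(cfg)
  xg <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  fw <- ecgfusion:::.fusion_forward(net, xg, matrix(runif(33), 11, 3), cfg)
  expect_true(all(fw$scores >= 0 & fw$scores <= 1))
})

test_that("constant handcrafted features do not break the merged pass", {
  cfg <- fusion_config(backbone = "tiny-test", n_handcrafted = 9, seed = 4)
  net <- build_fusion_net(cfg)
  x <- array(runif(16 * 16 * 1 * 4), c(16, 16, 1, 4))
  fb <- matrix(0.5, 9, 4)
  expect_no_error(ecgfusion:::.fusion_forward(net, x, fb, cfg))
})

test_that("the score threshold sends the 0.5 boundary to normal", {
  expect_equal(classify_score(0.5), 0L)
  expect_equal(classify_score(0.51), 1L)
  expect_equal(classify_score(0), 0L)
  expect_equal(classify_score(1), 1L)
  expect_error(classify_score(1.2), "\\[0, 1\\]")
})

test_that("lead fusion follows y1 + y2 - 0.5 with >= 0.5 abnormal", {
  expect_equal(fuse_leads(0.9, 0.8)$y, 1.2)
  expect_equal(fuse_leads(0.9, 0.8)$label, 1L)
  expect_equal(fuse_leads(0.2, 0.3)$y, 0)
  expect_equal(fuse_leads(0.2, 0.3)$label, 0L)
  expect_equal(fuse_leads(0.9, 0.2)$label, 1L)  # one confident lead wins
  expect_error(fuse_leads(1.4, 0.2), "\\[0, 1\\]")
})

test_that("decision rules agree with grid enumeration of their regions", {
  g <- seq(0, 1, by = 0.01)
  expect_equal(classify_score(g), as.integer(g > 0.5))
  grid <- expand.grid(y1 = g, y2 = g)
  fused <- fuse_leads(grid$y1, grid$y2)
  expect_equal(fused$label, as.integer(grid$y1 + grid$y2 - 0.5 >= 0.5))
  # when both leads agree, fusion never overturns them
  both0 <- grid$y1 <= 0.5 & grid$y2 <= 0.5 &
    !(grid$y1 == 0.5 & grid$y2 == 0.5)       # the printed boundary case
  expect_true(all(fused$label[grid$y1 > 0.5 & grid$y2 > 0.5] == 1L))
  expect_true(all(fused$label[grid$y1 < 0.5 & grid$y2 < 0.5] == 0L))
})

test_that("the LR schedule starts at 0.1 and halves every decay_every", {
  cfg <- fusion_config(decay_every = 10, seed = 1)
  lrs <- vapply(1:25, ecgfusion:::.lr_at, numeric(1), config = cfg)
  expect_equal(lrs[1:10], rep(0.1, 10))
  expect_equal(lrs[11:20], rep(0.05, 10))
  expect_equal(lrs[21:25], rep(0.025, 5))
})

test_that("early stopping fires after two consecutive validation drops", {
  stop_at <- function(accs) {
    for (e in seq_along(accs)) {
      if (ecgfusion:::.should_stop(accs[1:e], 2)) return(e)
    }
    NA_integer_
  }
  expect_equal(stop_at(c(0.8, 0.9, 0.85, 0.8)), 4L)
  expect_equal(stop_at(c(0.8, 0.9, 0.85, 0.85)), NA_integer_)
  expect_equal(stop_at(c(0.9, 0.8, 0.7, 0.95)), 3L)
  expect_equal(stop_at(c(0.5, 0.6, 0.7, 0.8)), NA_integer_)
})

test_that("training separates linearly separable data and reproduces", {
  set.seed(42)
  n <- 200
  imgs <- array(runif(12 * 12 * n), c(12, 12, 1, n))
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(rnorm(n * 9), n, 9)
  feats[, 1] <- labels * 2 + rnorm(n, sd = 0.1)
  cfg <- fusion_config(backbone = "tiny-test", n_handcrafted = 9,
                       max_epochs = 30, seed = 7)
  fit <- fusion_fit(imgs, feats, labels, cfg)
  expect_s3_class(fit, "ecg_fusion")
  expect_gte(mean(predict(fit, imgs, feats, type = "label") == labels), 0.95)
  expect_lte(nrow(fit$history), 30)
  expect_equal(fit$history$lr[1], 0.1)

  fit2 <- fusion_fit(imgs, feats, labels, cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(fusion_fit(imgs, feats[, 1:5], labels, cfg), "expects")
})
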