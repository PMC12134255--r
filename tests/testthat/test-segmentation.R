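# ResUnet construction, loss, schedule, augmentation, training contracts.

test_that("step_lr follows the x0.1-every-30-epochs schedule", {
  expect_equal(step_lr(0, 1e-3, 30, 0.1), 1e-3)
  expect_equal(step_lr(29, 1e-3, 30, 0.1), 1e-3)
  expect_equal(step_lr(30, 1e-3, 30, 0.1), 1e-4)
  expect_equal(step_lr(65, 1e-3, 30, 0.1), 1e-5)   # floor(65/30) = 2
  expect_equal(step_lr(0, 0.05, 10, 0.5), 0.05)
})

test_that("bce_dice_loss matches hand arithmetic and basic properties", {
  pred <- matrix(0.5, 2, 2); targ <- matrix(1, 2, 2)
  # BCE = ln 2; soft dice = (2*2)/(2+4) = 2/3 -> loss = ln2 + 1/3
  expect_equal(bce_dice_loss(pred, targ), log(2) + 1 / 3, tolerance = 1e-10)
  ones <- matrix(1, 3, 3)
  expect_lt(bce_dice_loss(ones, ones), 1e-6)
  # permutation invariance (sums only)
  set.seed(2)
  p <- matrix(runif(16), 4, 4); t_ <- matrix(rbinom(16, 1, 0.5), 4, 4)
  o <- sample(16)
  expect_equal(bce_dice_loss(p, t_),
               bce_dice_loss(matrix(p[o], 4), matrix(t_[o], 4)),
               tolerance = 1e-12)
  expect_error(bce_dice_loss(p, t_[1:3, 1:3]), "shapes differ")
  expect_error(bce_dice_loss(p * 2, t_), "\\[0, 1\\]")
  # soft dice of identical binary masks is exactly 1, so the dice term vanishes
  expect_identical(dice(t_, t_), 1)
})

test_that("augmentation is seeded, geometric on both rasters, intensity on image only", {
  s <- generate_sample(benign_spec(seed = 44))
  a1 <- augment(s, seed = 10)
  a2 <- augment(s, seed = 10)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  # foreground count is invariant under rotation/flip
  g <- augment(s, seed = 3, intensity = FALSE)
  expect_equal(sum(g$mask), sum(s$mask))
  expect_true(all(sort(unique(as.vector(g$image))) %in% sort(unique(as.vector(s$image)))))
  # intensity-only jitter leaves the mask untouched byte-for-byte
  j <- augment(s, seed = 5, rotate = FALSE, flip = FALSE, intensity = TRUE)
  expect_identical(j$mask, s$mask)
  expect_false(identical(j$image, s$image))
})

test_that("build_resunet output lies in [0,1] with the input's spatial dims", {
  m <- build_resunet(resunet_config(depth = 3, base_channels = 8), seed = 1)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  pm <- predict_mask(m, img, threshold = 0.5)
  expect_identical(dim(pm), c(64L, 64L))
  expect_true(all(pm %in% c(0, 1)))
  expect_true(all(predict_mask(m, img, threshold = 0) == 1))
  # deterministic forward: same weights, same input, identical output
  expect_identical(predict_mask(m, img), predict_mask(m, img))
  expect_error(predict_mask(m, array(0, c(60, 60, 3))), "divisible")
})

test_that("parameter count matches an independent layer-by-layer tally", {
  model <- build_resunet(resunet_config(depth = 4, base_channels = 32), seed = 1)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  block_n <- function(cin, cout)
    conv_n(3, cin, cout) + conv_n(3, cout, cout) +
    if (cin != cout) conv_n(1, cin, cout) else 0
  chs <- c(32, 64, 128, 256)
  expected <- conv_n(3, 3, 32)                       # stem
  prev <- 32
  for (i in 1:4) { expected <- expected + block_n(prev, chs[i]); prev <- chs[i] }
  expected <- expected + block_n(256, 512)           # bottleneck
  prev <- 512
  for (i in 4:1) {
    expected <- expected + conv_n(3, prev, chs[i]) + block_n(2 * chs[i], chs[i])
    prev <- chs[i]
  }
  expected <- expected + conv_n(1, 32, 1)            # head
  expect_identical(n_parameters(model), as.integer(expected))
})

test_that("training histories are seed-reproducible and seed-distinct", {
  train <- synth_samples(1:4, master_seed = 9)
  val <- synth_samples(5:6, master_seed = 9)
  cfg <- resunet_config(depth = 2, base_channels = 8)
  run <- function(seed) train_segmentation(
    train, val, cfg, seg_train_config(epochs = 2, batch_size = 2, seed = seed))
  f42a <- run(42); f42b <- run(42)
  expect_identical(f42a$history, f42b$history)
  # the three-seed protocol: distinct but individually reproducible histories
  f21 <- run(21); f84 <- run(84)
  expect_false(identical(f21$history$loss, f42a$history$loss))
  expect_false(identical(f84$history$loss, f42a$history$loss))
  expect_false(identical(f21$history$loss, f84$history$loss))
  expect_equal(nrow(f42a$history), 2)            # history length == epochs
  expect_error(train_segmentation(list(), val, cfg), "empty")
})

test_that("config validation", {
  expect_error(resunet_config(depth = 1), "depth")
  expect_error(resunet_config(base_channels = 4), "base_channels")
  expect_error(seg_train_config(lr_gamma = 0), "lr_gamma")
  expect_error(seg_train_config(bce_weight = 0, dice_weight = 0), "weights")
})
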