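# Feature-map colormap panels and Grad-CAM attribution.

test_that("featuremap_colormap tiles every channel and maps extrema", {
  set.seed(6)
  acts <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  panel <- featuremap_colormap(acts)
  expect_equal(attr(panel, "tiles"), 5)
  expect_equal(attr(panel, "tile_rows") * attr(panel, "tile_cols") >= 5, TRUE)
  expect_identical(dim(panel)[3], 3L)
  # constant channel renders as a uniform mid-scale tile, with a note
  acts[, , 2] <- 7
  expect_message(p2 <- featuremap_colormap(acts), "constant")
  tile2 <- p2[1:8, 9:16, ]
  expect_equal(length(unique(as.vector(tile2))), 3)    # one color, 3 channels
  # deterministic given the same input
  expect_identical(featuremap_colormap(acts[, , 1, drop = FALSE]),
                   featuremap_colormap(acts[, , 1, drop = FALSE]))
})

test_that("tokenizer_activations exposes the pre-flatten feature map", {
  m <- small_evt()
  img <- generate_sample(benign_spec(seed = 9))$image
  acts <- tokenizer_activations(m, img)                # block 3 pool output
  expect_identical(dim(acts), c(8L, 8L, as.integer(m$config$embed_dim)))
  panel <- featuremap_colormap(acts[, , 1:4])
  expect_equal(attr(panel, "tiles"), 4)
})

test_that("grad_cam produces normalized heatmaps at the two named layers", {
  m <- build_evt(evt_config(), seed = 2)               # default EVT
  img <- generate_sample(malignant_spec(seed = 13))$image
  for (lp in c("model.tokenizer.conv_layers[0][0]",
               "model.tokenizer.conv_layers[2][2]")) {
    hm <- grad_cam(m, lp, img, target_class = "malignant")
    expect_s3_class(hm, "heatmap")
    expect_identical(dim(hm$values), dim(img)[1:2])
    expect_gte(min(hm$values), 0)
    expect_equal(max(hm$values), 1)                    # max-normalized
    expect_identical(dim(hm$overlay), dim(img))
  }
  expect_error(grad_cam(m, "model.encoder.layers[0]", img), "available paths")
  expect_error(grad_cam(m, "model.tokenizer.conv_layers[5][0]", img),
               "out of range")
})

test_that("grad_cam of a constant-output head is all zero", {
  m <- small_evt()
  m$params$head.W[] <- 0                               # logit ignores features
  img <- generate_sample(benign_spec(seed = 21))$image
  hm <- grad_cam(m, "model.tokenizer.conv_layers[2][2]", img,
                 target_class = "benign")
  expect_true(all(hm$values == 0))
})

test_that("occlusion consistency: masking a hot region lowers its heat source", {
  fit <- get_cls_fit()
  man <- get_cls_dataset()
  img <- read_image(man$image[1])
  hm <- grad_cam(fit$model, "model.tokenizer.conv_layers[2][2]", img)
  # zero out the hottest quadrant of the input; the class logit must change
  q <- which(hm$values >= stats::quantile(hm$values, 0.75), arr.ind = TRUE)
  occluded <- img
  for (c in 1:3) occluded[, , c][q] <- 0
  p1 <- predict_class(fit$model, img)
  p2 <- predict_class(fit$model, occluded)
  expect_false(isTRUE(all.equal(p1$logits, p2$logits)))
})
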