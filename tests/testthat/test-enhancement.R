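# Nuclear information enhancement: resize rule, mask-driven Canny, fusion,
# normalization, and the locality of the whole transform.

test_that("resize_to_multiple rounds each axis to the nearest multiple of 32", {
  img <- array(runif(700 * 460 * 3, 0, 255), c(700, 460, 3))
  out <- resize_to_multiple(img)
  expect_identical(dim(out)[1:2], c(704L, 448L))
  img64 <- array(round(runif(64 * 64 * 3, 0, 255)), c(64, 64, 3))
  expect_identical(resize_to_multiple(img64), img64)   # byte-identical
  expect_identical(dim(resize_to_multiple(array(0, c(10, 10, 3))))[1:2],
                   c(32L, 32L))                        # minimum clamp
  expect_error(resize_to_multiple(img64, multiple = 0), "positive")
})

test_that("canny_on_mask consumes masks only and matches the boundary oracle", {
  mask <- matrix(0, 64, 64); mask[23:42, 23:42] <- 1   # 20x20 filled square
  em <- canny_on_mask(mask)
  expect_true(all(em %in% c(0, 1)))
  # edge pixels lie within 1 px of the morphological boundary
  band <- nievt:::dilate1(mask_boundary(mask))
  expect_true(all(em[band == 0] == 0))
  # the boundary is fully covered within 1 px (closed ring)
  eband <- nievt:::dilate1(em)
  expect_true(all(mask_boundary(mask)[eband == 0] == 0))
  expect_equal(count_components(em), 1)                # single closed ring
  # degenerate masks give empty edge maps
  expect_equal(sum(canny_on_mask(matrix(0, 32, 32))), 0)
  expect_equal(sum(canny_on_mask(matrix(1, 32, 32))), 0)
  # raw images are rejected
  expect_error(canny_on_mask(matrix(runif(64, 0, 255), 8, 8)), "binary")
})

test_that("fuse_edges is exact on edges and byte-identical elsewhere", {
  img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  empty <- matrix(0, 64, 64)
  expect_identical(fuse_edges(img, empty), img)        # identity case
  edges <- matrix(0, 64, 64); edges[10, 10:20] <- 1
  f0 <- fuse_edges(img, edges, edge_gain = 0)
  for (c in 1:3) {
    expect_true(all(f0[, , c][edges == 1] == 0))
    expect_identical(f0[, , c][edges == 0], img[, , c][edges == 0])
  }
  # idempotence at gain 0
  expect_identical(fuse_edges(f0, edges, 0), f0)
  # direct multiplication example
  px <- array(0, c(1, 1, 3)); px[1, 1, ] <- c(200, 100, 50)
  expect_equal(as.vector(fuse_edges(px, matrix(1, 1, 1), 0.5)), c(100, 50, 25))
  expect_error(fuse_edges(img, matrix(0, 8, 8)), "match")
})

test_that("normalization uses the ImageNet constants and inverts exactly", {
  img <- array(0, c(8, 8, 3)); img[, , 1] <- 255
  n <- normalize_for_classifier(img)
  expect_identical(dim(unclass(n)), c(3L, 8L, 8L))     # channel-first
  expect_equal(n[1, 1, 1], (1 - 0.485) / 0.229, tolerance = 1e-9)
  img2 <- array(123.675, c(4, 4, 3))                   # 0.485 * 255
  expect_equal(normalize_for_classifier(img2)[1, 1, 1], 0, tolerance = 1e-9)
  set.seed(3)
  img3 <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  back <- denormalize(normalize_for_classifier(img3))
  expect_equal(back, img3 / 255, tolerance = 1e-6)
  expect_error(normalize_for_classifier(matrix(0, 4, 4)), "H x W x 3")
})

test_that("enhancement changes pixels only within the mask boundary band", {
  samples <- synth_samples(1:16, master_seed = 33)
  for (s in samples) {
    edges <- canny_on_mask(s$mask)
    fused <- fuse_edges(s$image, edges, edge_gain = 0)
    diff <- (fused != s$image)
    band <- nievt:::dilate1(mask_boundary(s$mask))
    for (c in 1:3) expect_true(all(diff[, , c][band == 0] == FALSE))
  }
})

test_that("enhance_dataset with oracle masks writes a reproducible manifest", {
  dir <- file.path(tempdir(), "enh_src")
  man <- generate_dataset(3, benign_spec(), malignant_spec(), seed = 12,
                          out_dir = dir)
  out1 <- enhance_dataset(man, seg_model = NULL,
                          out_dir = file.path(tempdir(), "enh_a"))
  expect_equal(nrow(out1), 6)
  expect_true(all(out1$status == "ok"))
  expect_true(all(file.exists(out1$enhanced)))
  expect_true(all(out1$edge_pixels > 0))
  for (p in out1$enhanced) {
    d <- dim(read_image(p))
    expect_true(all(d[1:2] %% 32 == 0))
  }
  # rerun -> byte-identical outputs
  out2 <- enhance_dataset(man, seg_model = NULL,
                          out_dir = file.path(tempdir(), "enh_b"))
  for (i in seq_len(nrow(out1)))
    expect_identical(read_image(out1$enhanced[i]), read_image(out2$enhanced[i]))
  # a missing file is recorded per item; the run continues
  man2 <- man
  man2$image[2] <- file.path(dir, "missing.png")
  out3 <- enhance_dataset(man2, seg_model = NULL,
                          out_dir = file.path(tempdir(), "enh_c"))
  expect_false(out3$status[2] == "ok")
  expect_equal(sum(out3$status == "ok"), 5)
})

test_that("channel_difference_view renders an H x 3W panel", {
  img <- generate_sample(benign_spec(seed = 2))$image
  n1 <- normalize_for_classifier(img)
  pan0 <- channel_difference_view(n1, n1)
  expect_identical(dim(pan0), c(64L, 192L))            # 3x input width
  expect_true(all(pan0[, 129:192] == 0))               # zero difference tile
  edges <- canny_on_mask(generate_sample(benign_spec(seed = 2))$mask)
  n2 <- normalize_for_classifier(fuse_edges(img, edges, 0))
  pan <- channel_difference_view(n1, n2)
  difftile <- pan[, 129:192]
  # nonzero exactly on edge pixels (where the zero-gain fusion changed ch 3)
  changed <- (edges == 1) & (img[, , 3] > 0)
  expect_true(all((difftile > 0) == changed))
  expect_error(channel_difference_view(n1, n2, channel_index = 5), "channel_index")
})
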