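# Synthetic histology generator: determinism, geometry, class structure, I/O.

test_that("identical spec and seed give byte-identical samples", {
  s1 <- generate_sample(benign_spec(seed = 123))
  s2 <- generate_sample(benign_spec(seed = 123))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_sample(benign_spec(seed = 124))
  expect_false(identical(s3$image, s1$image))
})

test_that("n_nuclei is honored exactly (flood-fill component oracle)", {
  s <- generate_sample(benign_spec(n_nuclei = 5, seed = 5))
  expect_equal(count_components(s$mask), 5)
  s0 <- generate_sample(benign_spec(n_nuclei = 0, seed = 5))
  expect_true(all(s0$mask == 0))
})

test_that("mask agrees exactly with the generating ellipse equations", {
  s <- generate_sample(malignant_spec(seed = 31))
  inside_any <- matrix(FALSE, nrow(s$mask), ncol(s$mask))
  for (k in seq_len(nrow(s$nuclei))) {
    e <- s$nuclei[k, ]
    for (r in seq_len(nrow(s$mask))) for (cc in seq_len(ncol(s$mask))) {
      dx <- cc - e$cx; dy <- r - e$cy
      u <- dx * cos(e$theta) + dy * sin(e$theta)
      v <- -dx * sin(e$theta) + dy * cos(e$theta)
      if ((u / e$a)^2 + (v / e$b)^2 <= 1) inside_any[r, cc] <- TRUE
    }
  }
  expect_identical(s$mask == 1, inside_any)
})

test_that("generator rejects impossible packing with a clear error", {
  sp <- benign_spec(n_nuclei = 500, radius_range = c(6, 8), seed = 1)
  expect_error(generate_sample(sp), "cannot place nuclei")
})

test_that("spec validation catches bad field values", {
  expect_error(synthetic_spec(width = 32), ">= 64")
  expect_error(synthetic_spec(radius_range = c(5, 3)), "min > max")
  expect_error(synthetic_spec(eccentricity_range = c(0, 1)), "\\[0, 1\\)")
  expect_error(synthetic_spec(class_label = "other"), "benign")
})

test_that("malignant preset is strictly larger and more eccentric than benign", {
  b <- benign_spec(); m <- malignant_spec()
  expect_gt(mean(m$radius_range), mean(b$radius_range))
  expect_gt(mean(m$eccentricity_range), mean(b$eccentricity_range))
  expect_gt(m$n_nuclei, b$n_nuclei)
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  m1 <- generate_dataset(8, benign_spec(), malignant_spec(), seed = 99, out_dir = d1)
  m2 <- generate_dataset(8, benign_spec(), malignant_spec(), seed = 99, out_dir = d2)
  expect_equal(nrow(m1), 16)
  expect_equal(sum(m1$label == "benign"), 8)
  expect_equal(sum(m1$label == "malignant"), 8)
  expect_true(all(file.exists(m1$image)), all(file.exists(m1$mask)))
  # identical content across runs with the same master seed
  for (i in seq_len(nrow(m1)))
    expect_identical(read_image(m1$image[i]), read_image(m2$image[i]))
  # PNG round trip is lossless for 8-bit data
  img <- read_image(m1$image[1])
  p <- tempfile(fileext = ".png")
  write_image(img, p)
  expect_identical(read_image(p), img)
  msk <- read_mask(m1$mask[1])
  expect_true(all(msk %in% c(0, 1)))
})

test_that("class separability: malignant nuclei are >= 1.5x larger on average", {
  m <- cache_fixture("sep_dataset", function() {
    generate_dataset(8, benign_spec(), malignant_spec(), seed = 17,
                     out_dir = file.path(tempdir(), "synth_sep"))
  })
  area <- vapply(seq_len(nrow(m)), function(i) {
    msk <- read_mask(m$mask[i])
    sum(msk) / max(1, count_components(msk))
  }, numeric(1))
  ratio <- mean(area[m$label == "malignant"]) / mean(area[m$label == "benign"])
  expect_gte(ratio, 1.5)
})
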