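# Deterministic synthetic H&E-like fixtures: pink stroma, darker elliptical
# nuclei, exact paired masks. Malignant presets have larger, more eccentric,
# denser nuclei than benign ones, mimicking the nuclear enlargement and shape
# change that distinguishes malignant epithelium in real sections.

#' Specification for one synthetic histology image
#'
#' @param width,height image dimensions in pixels (>= 64).
#' @param n_nuclei number of non-overlapping nuclei to draw (>= 0).
#' @param radius_range (min, max) semi-major axis length in pixels.
#' @param eccentricity_range (min, max) ellipse eccentricity in \[0, 1).
#' @param nucleus_color,stroma_color RGB triples in \[0, 255\]; defaults give
#'   hematoxylin-like purple nuclei on eosin-like pink stroma.
#' @param noise_sd additive Gaussian noise standard deviation (intensity units).
#' @param blur_sigma Gaussian blur sigma in pixels (applied before noise).
#' @param class_label `"benign"` or `"malignant"`.
#' @param seed integer seed that fully determines the sample.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 64, height = 64, n_nuclei = 6,
                           radius_range = c(3, 5),
                           eccentricity_range = c(0.0, 0.3),
                           nucleus_color = c(64, 32, 128),
                           stroma_color = c(230, 180, 200),
                           noise_sd = 8, blur_sigma = 0.8,
                           class_label = "benign", seed = 1L) {
  if (width < 64 || height < 64) stopf("width and height must be >= 64")
  if (n_nuclei < 0) stopf("n_nuclei must be >= 0")
  if (radius_range[1] > radius_range[2]) stopf("radius_range min > max")
  if (eccentricity_range[1] < 0 || eccentricity_range[2] >= 1)
    stopf("eccentricity must lie in [0, 1)")
  if (!class_label %in% c("benign", "malignant"))
    stopf("class_label must be 'benign' or 'malignant'")
  structure(list(width = width, height = height, n_nuclei = n_nuclei,
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 nucleus_color = nucleus_color, stroma_color = stroma_color,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 class_label = class_label, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default benign-class synthetic preset
#' @param ... overrides passed to [synthetic_spec()].
#' @return `synthetic_spec`.
#' @export
benign_spec <- function(...) {
  args <- list(...)
  do.call(synthetic_spec, modifyList(list(class_label = "benign"), args))
}

#' Default malignant-class synthetic preset
#'
#' Strictly larger mean radius and eccentricity, and higher density, than the
#' benign preset.
#' @param ... overrides passed to [synthetic_spec()].
#' @return `synthetic_spec`.
#' @export
malignant_spec <- function(...) {
  args <- list(...)
  do.call(synthetic_spec, modifyList(
    list(class_label = "malignant", n_nuclei = 8, radius_range = c(5, 8),
         eccentricity_range = c(0.4, 0.8)), args))
}

#' Bundle an image, optional mask and label into a labeled sample
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param mask optional H x W binary matrix (1 = nucleus).
#' @param label optional class label.
#' @param id sample identifier string.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(image, mask = NULL, label = NULL, id = "sample") {
  d <- check_rgb(image)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2]))
      stopf("mask dims [%s] do not match image [%s]",
            paste(dim(mask), collapse = ","), paste(d[1:2], collapse = ","))
    if (!is_binary(mask)) stopf("mask values must be in {0,1}")
  }
  structure(list(image = image, mask = mask, label = label, id = id),
            class = "labeled_image")
}

# pixel membership of an ellipse, restricted to its bounding box
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  r <- ceiling(a) + 1L
  xs <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = ys[idx[, 1]], col = xs[idx[, 2]])
}

# separable Gaussian blur with edge replication; sigma <= 0 is a no-op
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(m, along) {
    out <- m * 0
    n <- if (along == 1) nrow(m) else ncol(m)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- clamp(seq_len(n) + off, 1L, n)
      out <- out + k[j] * (if (along == 1) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  for (c in seq_len(dim(x)[3])) x[, , c] <- blur1(blur1(x[, , c], 1), 2)
  x
}

#' Generate one synthetic histology sample
#'
#' Draws `n_nuclei` non-overlapping filled ellipses in `nucleus_color` on a
#' `stroma_color` background, blurs, adds Gaussian noise and clips to
#' \[0, 255\]. The returned mask is exact with respect to the pre-blur ellipse
#' geometry. Placement uses rejection sampling bounded at 1000 retries per
#' nucleus.
#'
#' @param spec a [synthetic_spec()].
#' @return a [labeled_image()] with `image`, `mask`, `label`.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    W <- spec$width; H <- spec$height
    mask <- matrix(0, H, W)
    img <- array(0, c(H, W, 3))
    for (c in 1:3) img[, , c] <- spec$stroma_color[c]
    nuclei <- list()
    placed <- 0L
    while (placed < spec$n_nuclei) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        a <- runif(1, spec$radius_range[1], spec$radius_range[2])
        ecc <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
        b <- a * sqrt(1 - ecc^2)
        theta <- runif(1, 0, pi)
        cx <- runif(1, a + 2, W - a - 1)
        cy <- runif(1, a + 2, H - a - 1)
        px <- ellipse_pixels(cx, cy, a, b, theta, W, H)
        if (nrow(px) == 0L) next
        lin <- px[, 1] + (px[, 2] - 1L) * H
        if (any(mask[lin] == 1)) next
        mask[lin] <- 1
        for (c in 1:3) {
          ch <- img[, , c]; ch[lin] <- spec$nucleus_color[c]; img[, , c] <- ch
        }
        nuclei[[placed + 1L]] <- data.frame(cx = cx, cy = cy, a = a, b = b,
                                            theta = theta)
        ok <- TRUE
        break
      }
      if (!ok)
        stopf("cannot place nuclei: %d of %d placed after 1000 retries",
              placed, spec$n_nuclei)
      placed <- placed + 1L
    }
    img <- gaussian_blur(img, spec$blur_sigma)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round_half_up(clamp(img, 0, 255))
    s <- labeled_image(img, mask, spec$class_label,
                       id = sprintf("%s_seed%d", spec$class_label, spec$seed))
    # provenance: the exact ellipse parameters behind the mask
    s$nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
      data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                 b = numeric(0), theta = numeric(0))
    s
  })
}

#' Generate a two-class synthetic dataset on disk
#'
#' Writes `2 * n_per_class` images and masks as PNG plus a manifest CSV with
#' columns `id,image,mask,label`. Per-sample seeds are derived
#' deterministically from `seed`, so identical calls produce identical files.
#'
#' @param n_per_class samples per class (>= 1).
#' @param benign_spec,malignant_spec class presets ([synthetic_spec()]); their
#'   `seed` fields are overridden by the derived per-sample seeds.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; manifest CSV written as
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n_per_class, benign_spec, malignant_spec,
                             seed, out_dir) {
  stopifnot(n_per_class >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  specs <- list(benign = benign_spec, malignant = malignant_spec)
  rows <- list()
  i <- 0L
  for (lab in names(specs)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sp <- specs[[lab]]
      sp$seed <- derive_seed(seed, i)
      sp$class_label <- lab
      s <- generate_sample(sp)
      id <- sprintf("%s_%03d", lab, j)
      img_path <- file.path(out_dir, paste0(id, ".png"))
      mask_path <- file.path(out_dir, paste0(id, "_mask.png"))
      write_image(s$image, img_path)
      write_mask(s$mask, mask_path)
      rows[[i]] <- data.frame(id = id, image = img_path, mask = mask_path,
                              label = lab, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
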