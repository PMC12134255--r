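# Nuclear information enhancement: resize to a 32-divisible size, take the
# nuclear segmentation mask, extract its Canny edges, and fuse the edge pixels
# multiplicatively into the original image. The Canny stage always consumes
# the MASK (scaled to 8-bit), never the raw image, so boundaries come
# exclusively from segmented nuclei.

#' ImageNet channel normalization constants
#'
#' @return list with `mean = c(0.485, 0.456, 0.406)` and
#'   `std = c(0.229, 0.224, 0.225)`.
#' @export
imagenet_constants <- function() {
  list(mean = c(0.485, 0.456, 0.406), std = c(0.229, 0.224, 0.225))
}

# center-aligned bilinear sampling of one channel matrix to H2 x W2
bilinear_matrix <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ys <- (seq_len(H2) - 0.5) * H / H2 + 0.5
  xs <- (seq_len(W2) - 0.5) * W / W2 + 0.5
  y0 <- clamp(floor(ys), 1, H); y1 <- pmin(y0 + 1, H); wy <- clamp(ys - y0, 0, 1)
  x0 <- clamp(floor(xs), 1, W); x1 <- pmin(x0 + 1, W); wx <- clamp(xs - x0, 0, 1)
  (1 - wy) %o% (1 - wx) * m[y0, x0, drop = FALSE] +
    (1 - wy) %o% wx * m[y0, x1, drop = FALSE] +
    wy %o% (1 - wx) * m[y1, x0, drop = FALSE] +
    wy %o% wx * m[y1, x1, drop = FALSE]
}

#' Bilinear resize of an RGB image
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param height,width target dimensions.
#' @return resized integer-valued array in \[0, 255\].
#' @export
resize_image <- function(image, height, width) {
  check_rgb(image)
  out <- array(0, c(height, width, 3))
  for (c in 1:3) out[, , c] <- bilinear_matrix(image[, , c], height, width)
  round_half_up(clamp(out, 0, 255))
}

#' Nearest-neighbor resize of a binary mask
#'
#' @param mask H x W binary matrix.
#' @param height,width target dimensions.
#' @return resized binary matrix.
#' @export
resize_mask <- function(mask, height, width) {
  ys <- clamp(ceiling((seq_len(height) - 0.5) * nrow(mask) / height), 1, nrow(mask))
  xs <- clamp(ceiling((seq_len(width) - 0.5) * ncol(mask) / width), 1, ncol(mask))
  mask[ys, xs, drop = FALSE]
}

#' Resize an image so both dimensions are multiples of a given number
#'
#' Each axis is rounded independently to the NEAREST multiple of `multiple`
#' (ties round up), clamped below at `multiple` itself; e.g. 700 x 460 with
#' multiple 32 becomes 704 x 448. Already-divisible images are returned
#' unchanged (byte-identical).
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param multiple required divisor of the output dimensions (default 32).
#' @return resized image array.
#' @export
resize_to_multiple <- function(image, multiple = 32) {
  if (multiple <= 0) stopf("multiple must be positive")
  d <- check_rgb(image)
  tgt <- pmax(multiple, round_half_up(d[1:2] / multiple) * multiple)
  if (all(tgt == d[1:2])) return(image)
  resize_image(image, tgt[1], tgt[2])
}

# 3x3 Sobel gradients with replicated borders
sobel <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[c(1, 1:(H - 1)), , drop = FALSE]
  dn <- m[c(2:H, H), , drop = FALSE]
  sh <- function(x, dir) { # shift columns: dir -1 = left neighbor
    if (dir < 0) x[, c(1, 1:(W - 1)), drop = FALSE] else x[, c(2:W, W), drop = FALSE]
  }
  gx <- (sh(up, 1) + 2 * sh(m, 1) + sh(dn, 1)) -
        (sh(up, -1) + 2 * sh(m, -1) + sh(dn, -1))
  gy <- (sh(dn, -1) + 2 * dn + sh(dn, 1)) -
        (sh(up, -1) + 2 * up + sh(up, 1))
  list(gx = gx, gy = gy)
}

#' Canny edge detection on a binary nuclear mask
#'
#' The mask is scaled to an 8-bit \{0, 255\} raster so the hysteresis
#' thresholds (default 100 and 200) are meaningful; gradients are 3x3 Sobel
#' with the L1 magnitude, followed by 4-direction non-maximum suppression and
#' hysteresis linking (8-connectivity). Passing anything non-binary raises an
#' error: edges are extracted from segmentation masks, never raw images.
#'
#' @param mask H x W matrix with values in \{0, 1\}.
#' @param low,high hysteresis thresholds on the 8-bit gradient magnitude.
#' @param source_mask_id optional provenance string stored on the result.
#' @return binary edge map (class `edge_map`): H x W matrix in \{0, 1\}.
#' @export
canny_on_mask <- function(mask, low = 100, high = 200, source_mask_id = "") {
  if (!is.matrix(mask) || !is_binary(mask))
    stopf("canny_on_mask expects a binary {0,1} mask; did you pass a raw image?")
  m <- mask * 255
  g <- sobel(m)
  mag <- abs(g$gx) + abs(g$gy)
  H <- nrow(m); W <- ncol(m)
  # quantize gradient direction to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180
  bin <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  padmag <- matrix(0, H + 2, W + 2); padmag[2:(H + 1), 2:(W + 1)] <- mag
  nb <- function(dy, dx) padmag[2:(H + 1) + dy, 2:(W + 1) + dx]
  # neighbors along the gradient direction for each orientation bin
  keep <- (bin == 0L & mag >= nb(0, -1) & mag >= nb(0, 1)) |
          (bin == 45L & mag >= nb(-1, 1) & mag >= nb(1, -1)) |
          (bin == 90L & mag >= nb(-1, 0) & mag >= nb(1, 0)) |
          (bin == 135L & mag >= nb(-1, -1) & mag >= nb(1, 1))
  nms <- mag * keep
  strong <- nms > high
  weak <- nms > low
  # hysteresis: BFS from strong pixels through weak ones (8-connectivity)
  edge <- strong
  frontier <- which(strong)
  while (length(frontier) > 0L) {
    rows <- (frontier - 1L) %% H + 1L
    cols <- (frontier - 1L) %/% H + 1L
    cand <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      r <- rows + dy; cc <- cols + dx
      okp <- r >= 1 & r <= H & cc >= 1 & cc <= W
      cand <- c(cand, (cc[okp] - 1L) * H + r[okp])
    }
    cand <- unique(cand)
    cand <- cand[weak[cand] & !edge[cand]]
    edge[cand] <- TRUE
    frontier <- cand
  }
  structure((edge & weak) * 1, dim = dim(mask),
            source_mask_id = source_mask_id, class = c("edge_map", "matrix"))
}

#' Morphological boundary of a binary mask
#'
#' Mask minus its 4-connected erosion; the reference ("oracle") boundary used
#' to validate edge maps.
#'
#' @param mask binary matrix.
#' @return binary matrix of boundary pixels.
#' @export
mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- mask
  er <- p[2:(H + 1), 2:(W + 1)] * p[1:H, 2:(W + 1)] * p[3:(H + 2), 2:(W + 1)] *
    p[2:(H + 1), 1:W] * p[2:(H + 1), 3:(W + 2)]
  (mask - er) * 1
}

# dilate a binary matrix by one pixel (8-connectivity)
dilate1 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- mask
  out <- matrix(0, H, W)
  for (dy in 0:2) for (dx in 0:2)
    out <- pmax(out, p[(1:H) + dy, (1:W) + dx])
  out
}

#' Fuse an edge map multiplicatively into an image
#'
#' Pixels where the edge map is 1 are multiplied by `edge_gain` (identically
#' on all channels) and clipped to \[0, 255\]; all other pixels are untouched,
#' byte for byte. The default gain 0 draws dark nuclear contours.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param edges H x W binary edge map.
#' @param edge_gain multiplicative gain applied on edge pixels (default 0).
#' @return fused image array.
#' @export
fuse_edges <- function(image, edges, edge_gain = 0) {
  d <- check_rgb(image)
  if (!identical(dim2(edges)[1:2], d[1:2]))
    stopf("edge map dims [%s] do not match image [%s]",
          paste(dim2(edges), collapse = ","), paste(d[1:2], collapse = ","))
  idx <- which(edges == 1)
  if (length(idx) == 0L) return(image)
  n <- d[1] * d[2]
  for (c in 0:2) {
    at <- idx + c * n
    v <- round_half_up(clamp(image[at] * edge_gain, 0, 255))
    # keep the input's storage mode so non-edge pixels stay byte-identical
    image[at] <- if (is.integer(image)) as.integer(v) else v
  }
  image
}

#' Normalize an 8-bit RGB image for the classifier
#'
#' Applies `(x / 255 - mean) / std` per channel and returns a channel-first
#' 3 x H x W floating array, the layout the tokenizer consumes.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param constants list with `mean`, `std` triples; default ImageNet.
#' @return 3 x H x W numeric array (class `normalized_array`).
#' @export
normalize_for_classifier <- function(image, constants = imagenet_constants()) {
  d <- check_rgb(image)
  if (any(constants$std <= 0)) stopf("std components must be > 0")
  out <- array(0, c(3, d[1], d[2]))
  for (c in 1:3)
    out[c, , ] <- (image[, , c] / 255 - constants$mean[c]) / constants$std[c]
  structure(out, class = c("normalized_array", "array"))
}

#' Invert [normalize_for_classifier()]
#'
#' @param x 3 x H x W normalized array.
#' @param constants the constants used for normalization.
#' @return H x W x 3 array of intensities in \[0, 1\] (i.e. original / 255).
#' @export
denormalize <- function(x, constants = imagenet_constants()) {
  d <- dim(x)
  out <- array(0, c(d[2], d[3], 3))
  for (c in 1:3) out[, , c] <- x[c, , ] * constants$std[c] + constants$mean[c]
  out
}

#' Enhance every image in a manifest
#'
#' Per image: [resize_to_multiple()], obtain the nuclear mask (from
#' `seg_model` via [predict_mask()], or from the manifest's ground-truth
#' `mask` column when `seg_model = NULL` — the "oracle segmenter"),
#' [canny_on_mask()], [fuse_edges()]. Enhanced PNGs and a manifest mapping
#' original to enhanced paths are written to `out_dir`; per-image failures are
#' recorded in the `status` column and the run continues.
#'
#' @param manifest_in manifest data.frame or CSV path (`id,image[,mask,label]`).
#' @param seg_model trained segmentation model, or `NULL` to use ground-truth
#'   masks.
#' @param out_dir output directory.
#' @param edge_gain fusion gain (default 0).
#' @param multiple dimension divisor (default 32).
#' @param low,high Canny hysteresis thresholds.
#' @return manifest data.frame with columns
#'   `id,image,enhanced,label,edge_pixels,status`; also written to
#'   `out_dir/manifest.csv`.
#' @export
enhance_dataset <- function(manifest_in, seg_model = NULL, out_dir,
                            edge_gain = 0, multiple = 32,
                            low = 100, high = 200) {
  m <- if (is.character(manifest_in)) read_manifest(manifest_in) else manifest_in
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- m
  out$enhanced <- rep(NA_character_, nrow(m))
  out$edge_pixels <- rep(NA_integer_, nrow(m))
  out$status <- rep("ok", nrow(m))
  if (is.null(out$label)) out$label <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    res <- tryCatch({
      img <- read_image(m$image[i])
      img <- resize_to_multiple(img, multiple)
      mask <- if (is.null(seg_model)) {
        if (is.null(m$mask) || is.na(m$mask[i]))
          stopf("no seg_model and no mask column for id %s", m$id[i])
        resize_mask(read_mask(m$mask[i]), dim(img)[1], dim(img)[2])
      } else {
        predict_mask(seg_model, img)
      }
      edges <- canny_on_mask(mask, low = low, high = high,
                             source_mask_id = m$id[i])
      fused <- fuse_edges(img, edges, edge_gain = edge_gain)
      path <- file.path(out_dir, paste0(m$id[i], "_enhanced.png"))
      write_image(fused, path)
      list(path = path, n_edge = sum(edges))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[i] <- conditionMessage(res)
    } else {
      out$enhanced[i] <- res$path
      out$edge_pixels[i] <- res$n_edge
    }
  }
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}

#' Side-by-side view of one normalized channel before/after enhancement
#'
#' Renders the selected channel of the original and the enhanced normalized
#' arrays plus their difference as one 8-bit grayscale panel (H x 3W). The
#' channel index is zero-based, so the default 2 selects the third channel.
#' The two channel tiles are min-max scaled; the difference tile is scaled by
#' its maximum absolute value so that an all-zero difference stays all zero.
#'
#' @param original,enhanced 3 x H x W normalized arrays (same constants).
#' @param channel_index zero-based channel index (default 2).
#' @return H x 3W integer matrix in \[0, 255\].
#' @export
channel_difference_view <- function(original, enhanced, channel_index = 2) {
  if (channel_index < 0 || channel_index > 2)
    stopf("channel_index must be 0, 1 or 2")
  c1 <- original[channel_index + 1, , ]
  c2 <- enhanced[channel_index + 1, , ]
  mm <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(x * 0 + 128)
    (x - rng[1]) / (rng[2] - rng[1]) * 255
  }
  dif <- c1 - c2
  dmax <- max(abs(dif))
  dt <- if (dmax == 0) dif * 0 else abs(dif) / dmax * 255
  round_half_up(cbind(mm(c1), mm(c2), dt))
}
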