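# Inspection tools: per-channel colormap panels of tokenizer feature maps and
# Grad-CAM attribution on named tokenizer layers.

# map a [0,1] matrix through a palette to an RGB array in [0,255]
apply_colormap <- function(m, palette = "viridis") {
  cols <- grDevices::hcl.colors(256, palette)
  rgb <- grDevices::col2rgb(cols)
  idx <- pmin(255L, pmax(0L, round_half_up(m * 255))) + 1L
  out <- array(0, c(dim(m), 3))
  for (c in 1:3) out[, , c] <- matrix(rgb[c, idx], nrow(m), ncol(m))
  out
}

#' Per-channel colormap panel of tokenizer activations
#'
#' Each channel is min-max normalized, scaled by 255 and rendered through a
#' colormap; tiles are arranged in a near-square grid. Constant channels
#' cannot be normalized and are rendered mid-scale (a note is emitted).
#'
#' @param activations H x W x C activation array (the feature map before the
#'   tokenizer's flatten step).
#' @param palette `grDevices::hcl.colors` palette name (default "viridis").
#' @return 8-bit RGB raster array with attribute `tiles = C`; tile layout in
#'   attributes `tile_rows`, `tile_cols`.
#' @export
featuremap_colormap <- function(activations, palette = "viridis") {
  d <- dim(activations)
  if (length(d) != 3L) stopf("expected an H x W x C activation array")
  C <- d[3]
  cols <- ceiling(sqrt(C)); rows <- ceiling(C / cols)
  panel <- array(0, c(rows * d[1], cols * d[2], 3))
  for (ch in seq_len(C)) {
    a <- activations[, , ch]
    rng <- range(a)
    if (rng[1] == rng[2]) {
      message(sprintf("channel %d is constant (min = max); rendered mid-scale", ch))
      norm <- a * 0 + 0.5
    } else norm <- (a - rng[1]) / (rng[2] - rng[1])
    tile <- apply_colormap(norm, palette)
    r0 <- ((ch - 1) %/% cols) * d[1]
    c0 <- ((ch - 1) %% cols) * d[2]
    panel[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- tile
  }
  structure(panel, tiles = C, tile_rows = rows, tile_cols = cols)
}

#' Tokenizer activations of an EVT model for one image
#'
#' @param model an `evt` model.
#' @param image H x W x 3 array in \[0, 255\] (32-divisible dims).
#' @param block tokenizer block 1..3 (default 3: the map before flattening).
#' @param stage `"conv"`, `"relu"` or `"pool"` (default `"pool"`).
#' @return H' x W' x C activation array.
#' @export
tokenizer_activations <- function(model, image, block = 3, stage = "pool") {
  x <- as_chw_input(unclass(normalize_for_classifier(image)))
  fw <- tokenizer_fwd(model$params, x)
  a <- fw$acts[[block]][[stage]]
  array(a, dim(a)[1:3])
}

# parse "model.tokenizer.conv_layers[b][s]" -> list(block = b+1, stage)
parse_layer_path <- function(layer_path) {
  m <- regmatches(layer_path,
                  regexec("conv_layers\\[([0-9]+)\\]\\[([0-9]+)\\]$", layer_path))[[1]]
  stages <- c("conv", "relu", "pool")
  if (length(m) != 3L)
    stopf(paste0("cannot resolve layer path '%s'; available paths: ",
                 paste(sprintf("model.tokenizer.conv_layers[%d][%d]",
                               rep(0:2, each = 3), rep(0:2, 3)),
                       collapse = ", ")), layer_path)
  b <- as.integer(m[2]); s <- as.integer(m[3])
  if (b > 2 || s > 2)
    stopf("layer path indices out of range (blocks 0-2, stages 0-2)")
  list(block = b + 1L, stage = stages[s + 1L])
}

#' Grad-CAM attribution for an EVT classification
#'
#' Standard Grad-CAM at a tokenizer layer addressed by the dotted-index path
#' syntax (e.g. `model.tokenizer.conv_layers[0][0]` is the first convolution,
#' `model.tokenizer.conv_layers[2][2]` the last max-pool): channel weights
#' are the spatial means of the class-logit gradient, the weighted activation
#' sum is rectified, bilinearly upsampled to input size, and max-normalized.
#'
#' @param model trained `evt` model.
#' @param layer_path layer identifier string.
#' @param image H x W x 3 array in \[0, 255\] (32-divisible dims).
#' @param target_class class label or index (default: the predicted class).
#' @return object of class `heatmap`: list with `values` (H x W in \[0, 1\]),
#'   `layer_path`, `overlay` (RGB blend with the input).
#' @export
grad_cam <- function(model, layer_path, image, target_class = NULL) {
  loc <- parse_layer_path(layer_path)
  x <- as_chw_input(unclass(normalize_for_classifier(image)))
  fw <- evt_fwd(model, x, training = FALSE)
  if (is.null(target_class)) target_class <- which.max(fw$probs)
  if (is.character(target_class))
    target_class <- match(target_class, model$classes)
  if (is.na(target_class) || target_class < 1 || target_class > length(fw$logits))
    stopf("unknown target class")
  dlogits <- numeric(length(fw$logits))
  dlogits[target_class] <- 1
  bw <- evt_bwd(model, dlogits, fw, want_act_grads = TRUE)
  A <- fw$cache$tk$acts[[loc$block]][[loc$stage]]
  dA <- bw$act_grads[[paste0(loc$block, ".", loc$stage)]]
  d <- dim(A)
  w <- colMeans(matrix(dA, d[1] * d[2], d[3]))
  cam <- matrix(matrix(A, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  cam <- bilinear_matrix(cam, dim(image)[1], dim(image)[2])
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  hm <- apply_colormap(cam)
  overlay <- round_half_up(0.5 * image + 0.5 * hm)
  structure(list(values = cam, layer_path = layer_path, overlay = overlay,
                 target_class = model$classes[target_class]),
            class = "heatmap")
}
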