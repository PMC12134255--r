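# PNG and manifest I/O. Images are held in memory as integer arrays in
# [0, 255] (H x W x 3 for RGB, H x W in {0, 1} for masks); files are 8-bit PNG.

#' Write an RGB image to an 8-bit PNG file
#'
#' @param image H x W x 3 array with values in \[0, 255\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  png::writePNG(array(as.vector(image) / 255, dim(image)), path)
  invisible(path)
}

#' Read an 8-bit PNG image as an RGB array in \[0, 255\]
#'
#' Grayscale files are expanded to three identical channels; an alpha channel,
#' if present, is dropped.
#'
#' @param path PNG file path.
#' @return H x W x 3 integer-valued array in \[0, 255\].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
  array(round_half_up(as.vector(a) * 255), dim(a))
}

#' Write a binary mask as a single-channel PNG (values 0 / 255)
#'
#' @param mask H x W matrix with values in \{0, 1\}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is_binary(mask)) stopf("mask must be binary {0,1}")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG written by [write_mask()]
#'
#' Any pixel above 0.5 (of full scale) is foreground.
#'
#' @param path PNG file path.
#' @return H x W matrix in \{0, 1\}.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (a > 0.5) * 1
}

#' Read a dataset manifest CSV
#'
#' Manifests are CSV tables with at least columns `id,image`; `mask` and
#' `label` columns are optional depending on the stage.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "image") %in% names(m)))
    stopf("manifest %s lacks required columns id,image", path)
  m
}

#' Write a dataset manifest CSV
#'
#' @param manifest data.frame with at least `id,image` columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
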