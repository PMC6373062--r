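#' Convert an RGB microscopy image to grayscale
#'
#' Weighted luminance conversion `0.3*R + 0.59*G + 0.11*B`, the perceptual
#' weighting used throughout the pipeline. Values are kept real-valued;
#' quantisation to 8-bit happens only on file export.
#'
#' @param img numeric array `H x W x 3` with channels (R, G, B) in
#'   `[0, 255]`, optionally carrying a `pixel_size_um` attribute.
#' @return numeric matrix `H x W` in `[0, 255]`; the `pixel_size_um`
#'   attribute, if present, is preserved.
#' @examples
#' x <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_gray(x)  # 76.5
#' @export
rgb_to_gray <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("`img` must be an H x W x 3 array with channels (R, G, B)", call. = FALSE)
  }
  out <- matrix(0.3 * img[, , 1] + 0.59 * img[, , 2] + 0.11 * img[, , 3],
                dim(img)[1], dim(img)[2])
  attr(out, "pixel_size_um") <- attr(img, "pixel_size_um")
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clipped histogram and bilinear
#' interpolation between tiles. `clip_limit` is the normalised clipping
#' factor: 2.0 clips each tile histogram at twice its mean bin height, the
#' operating point used for pap-smear enhancement. Images with zero dynamic
#' range are returned unchanged (there is no contrast to redistribute).
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param clip_limit positive clipping factor (default 2.0).
#' @param tile_grid integer vector of length 2, tiles along rows/columns
#'   (default `c(8, 8)`).
#' @param bins number of histogram bins per tile.
#' @return enhanced matrix in `[0, 255]`, same shape, `pixel_size_um`
#'   attribute preserved.
#' @export
enhance <- function(img, clip_limit = 2, tile_grid = c(8, 8), bins = 256) {
  stopifnot(is.matrix(img))
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0) {
    stop("`clip_limit` must be a single positive number", call. = FALSE)
  }
  ps <- attr(img, "pixel_size_um")
  rng <- range(img)
  if (diff(rng) == 0) return(img)
  x01 <- (img - rng[1]) / diff(rng)
  # tile counts must divide the image size; pad by edge replication, crop back
  pr <- (tile_grid[1] - nrow(x01) %% tile_grid[1]) %% tile_grid[1]
  pc <- (tile_grid[2] - ncol(x01) %% tile_grid[2]) %% tile_grid[2]
  xp <- x01[c(seq_len(nrow(x01)), rep(nrow(x01), pr)),
            c(seq_len(ncol(x01)), rep(ncol(x01), pc)), drop = FALSE]
  out <- EBImage::clahe(xp, nx = tile_grid[1], ny = tile_grid[2],
                        bins = bins, limit = clip_limit, keep.range = FALSE)
  out <- matrix(pmin(pmax(as.numeric(out), 0), 1), nrow(xp), ncol(xp))
  out <- out[seq_len(nrow(img)), seq_len(ncol(img)), drop = FALSE] * 255
  attr(out, "pixel_size_um") <- ps
  out
}

#' Read an image file as RGB or grayscale pixel data
#'
#' Reads PNG/TIFF/JPEG via EBImage. Grayscale files come back as a matrix,
#' colour files as an `H x W x 3` array, both scaled to `[0, 255]`.
#'
#' @param path file path.
#' @param pixel_size_um physical pixel edge length in micrometres attached
#'   as an attribute (default 0.201, the calibration of a typical
#'   frame-grabber cervical-cytology setup).
#' @return matrix or 3-channel array with a `pixel_size_um` attribute.
#' @export
read_image <- function(path, pixel_size_um = 0.201) {
  im <- EBImage::readImage(path)
  dat <- EBImage::imageData(im)
  if (length(dim(dat)) == 2L) {
    out <- t(dat) * 255
  } else {
    dat <- dat[, , 1:3, drop = FALSE]
    out <- aperm(dat, c(2, 1, 3)) * 255
  }
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Write pixel data to an image file
#'
#' Quantises to the file format's 8-bit range on export; in-memory pixel
#' values stay real-valued throughout the pipeline.
#'
#' @param img matrix (gray) or `H x W x 3` array (RGB) in `[0, 255]`.
#' @param path output path; format from the extension (png, tiff, jpeg).
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  if (is.matrix(x)) {
    EBImage::writeImage(EBImage::Image(t(x)), path)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color"), path)
  }
  invisible(path)
}
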