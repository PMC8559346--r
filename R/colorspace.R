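#' Extract a segmentation channel from an RGB crop
#'
#' Returns the 2-D plane the white-region segmentation thresholds: either the
#' raw green channel of RGB or the complement of the magenta component under
#' the naive (profile-free) CMYK conversion, both on the 0-255 scale. The
#' naive conversion uses K = 1 - max(R, G, B)/255 and
#' M = (1 - G/255 - K) / (1 - K), with M = 0 for pure black.
#'
#' @param img H x W x 3 numeric array, 8-bit intensities in `[0, 255]`.
#' @param channel `"rgb_green"` or `"cmyk_magenta_complement"`.
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
channel_plane <- function(img, channel = c("rgb_green", "cmyk_magenta_complement")) {
  assert_raster(img)
  channel <- match.arg(channel)
  if (channel == "rgb_green") {
    return(img[, , 2] + 0)
  }
  r <- img[, , 1] / 255
  g <- img[, , 2] / 255
  b <- img[, , 3] / 255
  k <- 1 - pmax(r, g, b)
  denom <- 1 - k
  m <- ifelse(denom < 1e-12, 0, (1 - g - k) / denom)
  255 * (1 - m)
}

#' Luminance (grayscale) of an RGB crop
#'
#' Standard Rec. 601 weighting: 0.2989 R + 0.5870 G + 0.1140 B.
#'
#' @inheritParams channel_plane
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
luminance <- function(img) {
  assert_raster(img)
  0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
}

# per-pixel CIELAB a,b (sRGB, D65); returns n-pixel x 2 matrix, column-major
# pixel order matching as.vector() of the image planes
lab_ab <- function(img) {
  assert_raster(img)
  rgb01 <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                 as.vector(img[, , 3])) / 255
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  lab[, 2:3, drop = FALSE]
}
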