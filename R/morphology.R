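#' White-region mask from a single colour channel
#'
#' First stage of the Bowman's-space segmentation: binarise one channel at a
#' fixed whiteness threshold (190 by default), clean the result with binary
#' median filtering, erosion and dilation (disk structuring elements), and
#' refine the shape with a region-based active contour (morphological
#' Chan-Vese) run on the channel image for a fixed number of iterations.
#'
#' Setting `clean_radius = 0` or `ac_iterations = 0` skips the respective
#' stage, which exposes the raw binarisation for auditing.
#'
#' @param img H x W x 3 array, 8-bit intensities.
#' @param channel `"rgb_green"` or `"cmyk_magenta_complement"`.
#' @param threshold whiteness threshold in `[0, 255]`; pixels with channel
#'   value `>= threshold` are kept.
#' @param clean_radius disk radius (1-3) for the cleaning operators.
#' @param ac_iterations active-contour iterations (default 200).
#' @return H x W logical mask.
#' @export
white_mask_from_channel <- function(img,
                                    channel = c("rgb_green",
                                                "cmyk_magenta_complement"),
                                    threshold = 190,
                                    clean_radius = 2,
                                    ac_iterations = 200) {
  stopifnot(threshold >= 0, threshold <= 255)
  channel <- match.arg(channel)
  plane <- channel_plane(img, channel)
  mask <- plane >= threshold
  if (clean_radius > 0) mask <- clean_mask(mask, clean_radius)
  if (ac_iterations > 0) mask <- refine_mask_ac(mask, plane, ac_iterations)
  mask
}

# binary median (majority over a disk), erosion, dilation -- in that order
clean_mask <- function(mask, radius = 2) {
  stopifnot(radius >= 1, radius <= 3)
  m <- mask * 1
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  maj <- EBImage::filter2(m, brush / sum(brush), boundary = "replicate")
  m <- (maj >= 0.5) * 1
  m <- EBImage::erode(m, brush)
  m <- EBImage::dilate(m, brush)
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

# morphological Chan-Vese refinement on the (0-255) channel image
refine_mask_ac <- function(mask, plane, iterations = 200) {
  init <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  out <- acwe_evolve(plane / 255, init, as.integer(iterations), 1L)
  matrix(out == 1L, nrow(mask), ncol(mask))
}

#' White-region mask from CIELAB k-means clustering
#'
#' Clusters the per-pixel (a, b) chromaticity pairs of the crop with k-means
#' (k clusters, best of `replicates` seeded restarts by total within-cluster
#' sum of squares) and keeps the cluster whose mean grayscale intensity in
#' the original crop is greatest, i.e. the white structures. The retained
#' mask then runs through the same cleaning and active-contour steps as
#' [white_mask_from_channel()] (the contour evolves on the luminance image).
#'
#' @param img H x W x 3 array, 8-bit intensities.
#' @param k number of clusters (default 5). If the crop has fewer distinct
#'   (a, b) values than `k`, `k` is reduced with a warning.
#' @param replicates number of k-means restarts (default 3).
#' @inheritParams white_mask_from_channel
#' @param seed integer seed for the restarts.
#' @return H x W logical mask.
#' @export
lab_cluster_mask <- function(img, k = 5, replicates = 3,
                             clean_radius = 2, ac_iterations = 200,
                             seed = 1L) {
  assert_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  ab <- lab_ab(img)
  distinct <- unique(ab)
  keff <- min(k, nrow(distinct))
  if (keff < k) {
    warning(sprintf("only %d distinct (a,b) values; reducing k from %d",
                    keff, k))
  }
  gray <- luminance(img)
  if (keff == 1) {
    cl <- rep(1L, nrow(ab))
  } else {
    best <- NULL
    withr::with_seed(seed, {
      for (r in seq_len(replicates)) {
        centers <- distinct[sample(nrow(distinct), keff), , drop = FALSE]
        km <- suppressWarnings(
          stats::kmeans(ab, centers = centers, iter.max = 100,
                        algorithm = "Lloyd")
        )
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
    })
    cl <- best$cluster
  }
  mean_int <- tapply(as.vector(gray), cl, mean)
  sel <- as.integer(names(mean_int))[which.max(mean_int)]
  mask <- matrix(cl == sel, H, W)
  if (clean_radius > 0) mask <- clean_mask(mask, clean_radius)
  if (ac_iterations > 0) mask <- refine_mask_ac(mask, gray, ac_iterations)
  mask
}

#' Fuse channel masks by majority vote and filter the result
#'
#' Keeps pixels set in at least two of the three input masks, removes
#' connected components (8-connectivity) smaller than `min_region` pixels,
#' and intersects the result with a centered disk of diameter
#' `(7/8) * min(H, W)`, which drops peripheral structures that do not belong
#' to the glomerulus.
#'
#' @param m1,m2,m3 logical masks sharing one extent.
#' @param min_region minimum connected-component area in pixels
#'   (default 1000).
#' @return H x W logical mask.
#' @export
fuse_and_filter <- function(m1, m2, m3, min_region = 1000) {
  stopifnot(is_binary_mask(m1), is_binary_mask(m2), is_binary_mask(m3))
  if (!all(dim(m1) == dim(m2)) || !all(dim(m1) == dim(m3))) {
    stop("mask extents differ", call. = FALSE)
  }
  fused <- (as_mask(m1) + as_mask(m2) + as_mask(m3)) >= 2
  H <- nrow(fused); W <- ncol(fused)
  if (any(fused) && min_region > 0) {
    lab <- EBImage::bwlabel(fused * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_region)
    fused <- matrix(lab %in% keep & lab > 0, H, W)
  }
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- (7 / 8) * min(H, W) / 2
  disk <- (row(fused) - cy)^2 + (col(fused) - cx)^2 <= r^2
  fused & disk
}

#' Full Bowman's-space segmentation of a crop
#'
#' Runs the three parallel segmentations (RGB green channel, CMYK magenta
#' complement, CIELAB k-means) and fuses them with [fuse_and_filter()].
#'
#' @inheritParams white_mask_from_channel
#' @inheritParams lab_cluster_mask
#' @inheritParams fuse_and_filter
#' @return H x W logical mask of the white regions of the glomerulus.
#' @export
glomerulus_mask <- function(img, threshold = 190, clean_radius = 2,
                            ac_iterations = 200, k = 5, replicates = 3,
                            min_region = 1000, seed = 1L) {
  m1 <- white_mask_from_channel(img, "rgb_green", threshold,
                                clean_radius, ac_iterations)
  m2 <- white_mask_from_channel(img, "cmyk_magenta_complement", threshold,
                                clean_radius, ac_iterations)
  m3 <- lab_cluster_mask(img, k, replicates, clean_radius, ac_iterations,
                         seed = seed)
  fuse_and_filter(m1, m2, m3, min_region)
}

#' Morphological features of the final mask
#'
#' Two features: the white area fraction (mask pixel count divided by the
#' image area) and the equivalent radius, i.e. the radius of the circle with
#' the same area as the convex hull of the mask. An empty mask yields (0, 0).
#'
#' @param mask H x W logical mask.
#' @return one-row tibble with `morph_area` and `morph_radius`.
#' @export
morphological_features <- function(mask) {
  stopifnot(is_binary_mask(mask))
  mask <- as_mask(mask)
  n <- sum(mask)
  if (n == 0) {
    return(tibble(morph_area = 0, morph_radius = 0))
  }
  frac <- n / length(mask)
  pts <- which(mask, arr.ind = TRUE)  # (row, col) = (y, x)
  hull_area <- 0
  if (nrow(unique(pts)) >= 3) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    hx <- pts[h, 2]; hy <- pts[h, 1]
    j <- c(seq_along(h)[-1], 1)
    hull_area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  }
  tibble(morph_area = frac, morph_radius = sqrt(hull_area / pi))
}

#' Export a binary mask as a 1-bit-style PNG
#'
#' Writes the mask as a black/white PNG for visual auditing of the
#' segmentation stages.
#'
#' @param mask H x W logical mask.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  im <- EBImage::Image(t(as_mask(mask) * 1))
  EBImage::writeImage(im, path)
  invisible(path)
}
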