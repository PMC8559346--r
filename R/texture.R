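#' Rotation-invariant uniform LBP histogram
#'
#' Computes local binary pattern codes with `neighbors` samples on a circle
#' of the given radius (bilinear interpolation for off-grid samples; offsets
#' within 1e-9 of a grid point are snapped to it), maps them to the
#' rotation-invariant uniform (riu2) labels, and returns the normalized
#' histogram over the `neighbors + 2` labels (with 8 neighbors: 9 uniform
#' labels 0-8 plus one non-uniform label, i.e. 10 bins). Border pixels
#' without a complete neighborhood are excluded from the histogram.
#'
#' @param channel_image 2-D numeric matrix (one 8-bit colour plane).
#' @param radius circle radius in pixels.
#' @param neighbors number of circular samples (default 8).
#' @return normalized numeric histogram of length `neighbors + 2`.
#' @export
lbp_riu_histogram <- function(channel_image, radius, neighbors = 8L) {
  codes <- lbp_riu_codes(channel_image, radius, neighbors)
  h <- tabulate(as.vector(codes) + 1L, nbins = neighbors + 2L)
  h / sum(h)
}

# riu2 label matrix for the valid interior region
lbp_riu_codes <- function(channel_image, radius, neighbors = 8L) {
  stopifnot(is.matrix(channel_image), radius >= 1)
  H <- nrow(channel_image); W <- ncol(channel_image)
  rc <- ceiling(radius)
  if (H < 2 * rc + 1 || W < 2 * rc + 1) {
    stop(sprintf("image too small for LBP radius %s (needs > %d px per side)",
                 radius, 2 * rc), call. = FALSE)
  }
  rows <- (rc + 1):(H - rc)
  cols <- (rc + 1):(W - rc)
  center <- channel_image[rows, cols, drop = FALSE]

  snap <- function(z) if (abs(z - round(z)) < 1e-9) round(z) else z
  bits <- vector("list", neighbors)
  for (k in seq_len(neighbors) - 1L) {
    ang <- 2 * pi * k / neighbors
    dx <- snap(radius * cos(ang))
    dy <- snap(-radius * sin(ang))
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    sub <- function(oy, ox) channel_image[rows + oy, cols + ox, drop = FALSE]
    val <- (1 - fy) * (1 - fx) * sub(y0, x0)
    if (fx > 0) val <- val + (1 - fy) * fx * sub(y0, x0 + 1)
    if (fy > 0) val <- val + fy * (1 - fx) * sub(y0 + 1, x0)
    if (fx > 0 && fy > 0) val <- val + fy * fx * sub(y0 + 1, x0 + 1)
    bits[[k + 1L]] <- (val >= center) * 1L
  }

  ones <- Reduce(`+`, bits)
  trans <- matrix(0L, nrow(center), ncol(center))
  for (k in seq_len(neighbors)) {
    nxt <- if (k == neighbors) 1L else k + 1L
    trans <- trans + abs(bits[[k]] - bits[[nxt]])
  }
  out <- ones
  out[trans > 2] <- neighbors + 1L
  out
}

#' Multi-radial colour LBP feature block
#'
#' Applies [lbp_riu_histogram()] to each RGB channel at radii 1, 3, 9 and 27
#' and concatenates the histograms channel-major, radius-minor: 3 channels x
#' 4 radii x 10 bins = 120 features.
#'
#' @param img H x W x 3 array, at least 55 px per side (to fit radius 27).
#' @param radii LBP radii (default `c(1, 3, 9, 27)`).
#' @return named numeric vector of length `3 * length(radii) * 10`, names
#'   `lbp_<channel>_<radius>_<bin>`.
#' @export
mrclbp_features <- function(img, radii = c(1, 3, 9, 27)) {
  assert_raster(img)
  need <- 2 * ceiling(max(radii)) + 1
  if (dim(img)[1] < need || dim(img)[2] < need) {
    stop(sprintf("crop must be at least %d px per side for LBP radius %d",
                 need, max(radii)), call. = FALSE)
  }
  chn <- c("r", "g", "b")
  out <- numeric(0)
  for (c3 in 1:3) {
    plane <- img[, , c3] + 0
    for (r in radii) {
      h <- lbp_riu_histogram(plane, r)
      names(h) <- sprintf("lbp_%s_%d_%d", chn[c3], r, seq_along(h) - 1L)
      out <- c(out, h)
    }
  }
  out
}

#' Grey-level co-occurrence matrix
#'
#' Quantizes a grayscale image into `levels` equal-width bins over
#' `[0, max_value]` and counts co-occurring level pairs at the given offset
#' direction and distance. The matrix is symmetrized (each pair counted in
#' both orders) and normalized to sum 1. Direction offsets (row, col) are
#' 0 degrees = (0, d), 45 = (-d, d), 90 = (-d, 0), 135 = (-d, -d).
#'
#' @param gray 2-D numeric matrix.
#' @param direction one of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param distance offset length in pixels (default 1).
#' @param levels number of grey levels (default 64).
#' @param max_value full-scale input value (default 255).
#' @return `levels` x `levels` normalized symmetric matrix.
#' @export
glcm <- function(gray, direction = c("0", "45", "90", "135"),
                 distance = 1L, levels = 64L, max_value = 255) {
  stopifnot(is.matrix(gray), distance >= 1)
  direction <- match.arg(as.character(direction[1]),
                         c("0", "45", "90", "135"))
  off <- switch(direction,
                "0"   = c(0L, 1L),
                "45"  = c(-1L, 1L),
                "90"  = c(-1L, 0L),
                "135" = c(-1L, -1L)) * as.integer(distance)
  H <- nrow(gray); W <- ncol(gray)
  if (H <= abs(off[1]) || W <= abs(off[2])) {
    stop("image smaller than the co-occurrence offset", call. = FALSE)
  }
  q <- pmin(floor(gray / ((max_value + 1) / levels)) + 1L, levels)
  q <- pmax(q, 1L)
  rows <- max(1, 1 - off[1]):min(H, H - off[1])
  cols <- max(1, 1 - off[2]):min(W, W - off[2])
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1], cols + off[2], drop = FALSE]
  idx <- (as.vector(a) - 1L) * levels + as.vector(b)
  P <- matrix(tabulate(idx, nbins = levels * levels),
              levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

#' The 14 Haralick texture indices
#'
#' Computes the classic 14 Haralick statistics of a normalized symmetric
#' co-occurrence matrix, in this fixed order: angular second moment,
#' contrast, correlation, variance, inverse difference moment, sum average,
#' sum variance (about the sum average), sum entropy, entropy, difference
#' variance, difference entropy, the two information measures of
#' correlation, and the maximal correlation coefficient (square root of the
#' second-largest eigenvalue of the Q matrix). All logarithms are natural
#' with `0 log 0 = 0`; on degenerate (single-level) matrices the
#' correlation-type indices are defined as 0.
#'
#' @param P square normalized co-occurrence matrix (sum within 1e-6 of 1).
#' @return named numeric vector of length 14.
#' @export
haralick14 <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-6) {
    stop("co-occurrence matrix is not normalized (sum != 1)", call. = FALSE)
  }
  N <- nrow(P)
  lev <- seq_len(N)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx > 0 && sy > 0) {
    (sum(i * j * P) - mux * muy) / (sx * sy)
  } else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))

  s <- i + j
  ks <- 2:(2 * N)
  psum <- vapply(ks, function(k) sum(P[s == k]), numeric(1))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * logg(psum))

  entropy <- -sum(P * logg(P))

  d <- abs(i - j)
  kd <- 0:(N - 1)
  pdiff <- vapply(kd, function(k) sum(P[d == k]), numeric(1))
  mud <- sum(kd * pdiff)
  diff_variance <- sum((kd - mud)^2 * pdiff)
  diff_entropy <- -sum(pdiff * logg(pdiff))

  hx <- -sum(px * logg(px)); hy <- -sum(py * logg(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * logg(pxpy))
  hxy2 <- -sum(pxpy * logg(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  nz <- px > 0
  max_cor <- 0
  if (sum(nz) >= 2) {
    A <- P[nz, nz, drop = FALSE]
    Q <- sweep(A %*% t(sweep(A, 2, py[nz], "/")), 1, px[nz], "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2 && is.finite(ev[2])) {
      max_cor <- sqrt(max(ev[2], 0))
    }
  }
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2,
    max_cor = max_cor)
}

#' Direction-reduced Haralick feature block
#'
#' Computes the 14 Haralick indices for the four co-occurrence directions
#' (56 values) and reduces them to the per-index mean and range (max - min)
#' across directions: 28 values.
#'
#' @inheritParams glcm
#' @return named numeric vector of length 28
#'   (`har_mean_*` then `har_range_*`).
#' @export
haralick_block <- function(gray, distance = 1L, levels = 64L,
                           max_value = 255) {
  dirs <- c("0", "45", "90", "135")
  M <- vapply(dirs,
              function(d) haralick14(glcm(gray, d, distance, levels,
                                          max_value)),
              numeric(14))
  mn <- rowMeans(M)
  rg <- apply(M, 1, max) - apply(M, 1, min)
  stats::setNames(c(mn, rg),
                  c(paste0("har_mean_", names(mn)),
                    paste0("har_range_", names(mn))))
}
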