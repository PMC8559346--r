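# Independent naive-loop oracles used to validate the vectorized
# implementations, plus small image builders shared across tests.

# per-pixel LBP riu2 histogram: direct transcription of the definition with
# explicit loops and scalar bilinear interpolation
oracle_lbp_hist <- function(im, R, P = 8) {
  H <- nrow(im); W <- ncol(im); rc <- ceiling(R)
  labs <- integer(0)
  for (y in (rc + 1):(H - rc)) {
    for (x in (rc + 1):(W - rc)) {
      bits <- integer(P)
      for (k in 0:(P - 1)) {
        ang <- 2 * pi * k / P
        dx <- R * cos(ang); dy <- -R * sin(ang)
        if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
        if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
        yy <- y + dy; xx <- x + dx
        y0 <- floor(yy); x0 <- floor(xx)
        fy <- yy - y0; fx <- xx - x0
        v <- (1 - fy) * (1 - fx) * im[y0, x0]
        if (fx > 0) v <- v + (1 - fy) * fx * im[y0, x0 + 1]
        if (fy > 0) v <- v + fy * (1 - fx) * im[y0 + 1, x0]
        if (fx > 0 && fy > 0) v <- v + fy * fx * im[y0 + 1, x0 + 1]
        bits[k + 1] <- as.integer(v >= im[y, x])
      }
      U <- sum(abs(bits - bits[c(2:P, 1)]))
      labs <- c(labs, if (U <= 2) sum(bits) else P + 1L)
    }
  }
  tabulate(labs + 1L, nbins = P + 2L) / length(labs)
}

# literal transcription of the 14 Haralick formulas with explicit sums
oracle_haralick <- function(P) {
  N <- nrow(P)
  lg <- function(x) if (x > 0) log(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:N) * px); muy <- sum((1:N) * py)
  sx <- sqrt(sum(((1:N) - mux)^2 * px))
  sy <- sqrt(sum(((1:N) - muy)^2 * py))
  f1 <- 0; f2 <- 0; fcor <- 0; f4 <- 0; f5 <- 0; f9 <- 0
  hxy1 <- 0; hxy2 <- 0
  psum <- numeric(2 * N - 1); pdif <- numeric(N)
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    f1 <- f1 + p^2
    f2 <- f2 + (i - j)^2 * p
    fcor <- fcor + i * j * p
    f4 <- f4 + (i - mux)^2 * p
    f5 <- f5 + p / (1 + (i - j)^2)
    f9 <- f9 - p * lg(p)
    hxy1 <- hxy1 - p * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  f3 <- if (sx > 0 && sy > 0) (fcor - mux * muy) / (sx * sy) else 0
  ks <- 2:(2 * N)
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(vapply(psum, function(q) q * lg(q), 0))
  kd <- 0:(N - 1)
  mud <- sum(kd * pdif)
  f10 <- sum((kd - mud)^2 * pdif)
  f11 <- -sum(vapply(pdif, function(q) q * lg(q), 0))
  hx <- -sum(vapply(px, function(q) q * lg(q), 0))
  hy <- -sum(vapply(py, function(q) q * lg(q), 0))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  nz <- which(px > 0)
  f14 <- 0
  if (length(nz) >= 2) {
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      Q[a, b] <- sum(P[nz[a], nz] * P[nz[b], nz] / (px[nz[a]] * py[nz]))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2 && is.finite(ev[2])) f14 <- sqrt(max(ev[2], 0))
  }
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

# brute-force minimum of the corner-distance objective over every candidate
# threshold, by direct counting
oracle_threshold_b <- function(scores, labels) {
  pos <- labels == "sclerotic"
  cands <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in cands) {
    pred <- scores >= t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 && sens > best$sens)) {
      best <- list(t = t, d = d, sens = sens)
    }
  }
  best$t
}

# flat RGB test image builders
uniform_crop <- function(value, size = 64) {
  img <- array(value, c(size, size, 3))
  storage.mode(img) <- "integer"
  img
}

random_crop <- function(size = 64, seed = 1) {
  withr::with_seed(seed, {
    img <- array(sample(0:255, size * size * 3, replace = TRUE),
                 c(size, size, 3))
    storage.mode(img) <- "integer"
    img
  })
}

random_gray <- function(size = 64, seed = 1) {
  withr::with_seed(seed, matrix(sample(0:255, size * size, replace = TRUE),
                                size, size))
}

random_mask <- function(size = 32, p = 0.5, seed = 1) {
  withr::with_seed(seed, matrix(runif(size * size) < p, size, size))
}

# crop tibble with trivial pixels, for split tests that ignore the raster
meta_crops <- function(biopsy_sizes) {
  n <- sum(biopsy_sizes)
  tibble::tibble(
    crop_id = sprintf("c%03d", seq_len(n)),
    pixels = replicate(n, uniform_crop(128, 4), simplify = FALSE),
    label = factor(rep_len(c("non_sclerotic", "sclerotic"), n),
                   levels = c("non_sclerotic", "sclerotic")),
    biopsy_id = rep(sprintf("b%02d", seq_along(biopsy_sizes)), biopsy_sizes)
  )
}

# well-separated two-class Gaussian blobs in feature space
blob_data <- function(n_per_class = 60, d = 2, sep = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
    colnames(X) <- paste0("f", seq_len(d))
    tibble::as_tibble(X) |>
      dplyr::mutate(label = factor(rep(c("non_sclerotic", "sclerotic"),
                                       each = n_per_class),
                                   levels = c("non_sclerotic", "sclerotic")))
  })
}
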