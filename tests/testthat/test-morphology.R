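test_that("channel binarisation behaves on uniform crops", {
  white <- uniform_crop(255, 48)
  m <- white_mask_from_channel(white, "rgb_green", clean_radius = 0,
                               ac_iterations = 0)
  expect_true(all(m))
  dark <- uniform_crop(50, 48)
  m2 <- white_mask_from_channel(dark, "rgb_green", clean_radius = 0,
                                ac_iterations = 0)
  expect_false(any(m2))
})

test_that("a white square on dark stained background is recovered within 15%", {
  # dark pink background (neutral grays carry no magenta signal)
  img <- uniform_crop(0, 96)
  img[, , 1] <- 120L; img[, , 2] <- 60L; img[, , 3] <- 90L
  img[30:69, 30:69, ] <- 245L  # 40 x 40 square
  for (ch in c("rgb_green", "cmyk_magenta_complement")) {
    m <- white_mask_from_channel(img, ch)
    expect_lt(abs(sum(m) - 1600) / 1600, 0.15)
    expect_gt(sum(m & (row(m) %in% 30:69) & (col(m) %in% 30:69)) / sum(m), 0.95)
  }
})

test_that("raising the threshold never grows the pre-cleaning mask", {
  img <- random_crop(48, seed = 11)
  prev <- white_mask_from_channel(img, "rgb_green", threshold = 100,
                                  clean_radius = 0, ac_iterations = 0)
  for (t in c(140, 190, 230)) {
    cur <- white_mask_from_channel(img, "rgb_green", threshold = t,
                                   clean_radius = 0, ac_iterations = 0)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("Lab k-means keeps the brightest cluster", {
  img <- uniform_crop(0, 64)
  img[, 1:32, 1] <- 240L; img[, 1:32, 2] <- 240L; img[, 1:32, 3] <- 240L
  img[, 33:64, 1] <- 200L; img[, 33:64, 2] <- 110L; img[, 33:64, 3] <- 150L
  m <- suppressWarnings(
    lab_cluster_mask(img, clean_radius = 1, ac_iterations = 0, seed = 2)
  )
  truth <- col(m[, , drop = TRUE]) <= 32
  overlap <- sum(m == truth) / length(m)
  expect_gte(overlap, 0.95)
})

test_that("uniform crops collapse to one effective cluster covering everything", {
  img <- uniform_crop(120, 40)
  expect_warning(
    m <- lab_cluster_mask(img, clean_radius = 0, ac_iterations = 0, seed = 1),
    "distinct"
  )
  expect_true(all(m))
})

test_that("lab_cluster_mask is deterministic under a fixed seed", {
  crops <- generate_glomerulus("non_sclerotic", synthesis_params(), seed = 4)
  img <- crops$pixels[[1]]
  expect_identical(lab_cluster_mask(img, seed = 31),
                   lab_cluster_mask(img, seed = 31))
})

test_that("majority fusion keeps pixels in >= 2 masks and filters the rest", {
  sz <- 64
  empty <- matrix(FALSE, sz, sz)
  m1 <- empty; m1[10:40, 10:40] <- TRUE
  m2 <- empty; m2[10:40, 10:40] <- TRUE
  # pixel present in exactly two masks survives fusion (no size filter)
  f <- fuse_and_filter(m1, m2, empty, min_region = 0)
  inside <- f[20, 20]
  expect_true(inside)
  # all empty -> empty
  expect_false(any(fuse_and_filter(empty, empty, empty)))
  # a 900-px blob is removed by the 1000-px region filter
  b <- empty
  b[18:47, 18:47] <- TRUE  # 900 px centered blob
  expect_equal(sum(b), 900)
  expect_false(any(fuse_and_filter(b, b, empty, min_region = 1000)))
  expect_error(fuse_and_filter(m1, m2, matrix(FALSE, 10, 10)), "extent")
})

test_that("fusion is symmetric and bounded by the union and the disk", {
  for (s in 1:10) {
    m <- lapply(1:3, function(i) random_mask(40, p = 0.6, seed = s * 10 + i))
    ref <- fuse_and_filter(m[[1]], m[[2]], m[[3]], min_region = 5)
    for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_identical(fuse_and_filter(m[[p[1]]], m[[p[2]]], m[[p[3]]],
                                       min_region = 5), ref)
    }
    expect_true(all(!ref | (m[[1]] | m[[2]] | m[[3]])))
    cy <- (40 + 1) / 2; r <- (7 / 8) * 40 / 2
    disk <- (row(ref) - cy)^2 + (col(ref) - cy)^2 <= r^2
    expect_true(all(!ref | disk))
  }
})

test_that("morphological features handle degenerate and exact cases", {
  empty <- matrix(FALSE, 50, 50)
  expect_equal(morphological_features(empty),
               tibble::tibble(morph_area = 0, morph_radius = 0))
  full <- matrix(TRUE, 100, 100)
  expect_equal(morphological_features(full)$morph_area, 1.0)
  disk <- (row(matrix(0, 101, 101)) - 51)^2 +
    (col(matrix(0, 101, 101)) - 51)^2 <= 30^2
  mf <- morphological_features(disk)
  expect_lt(abs(mf$morph_radius - 30), 1)
})

test_that("masks export as black/white PNG for auditing", {
  m <- random_mask(32, seed = 5)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  back <- EBImage::imageData(EBImage::readImage(path))
  expect_identical(t(back) > 0.5, m)
})
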