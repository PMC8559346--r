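test_that("constant images put all LBP mass in the all-ones uniform bin", {
  im <- matrix(100, 32, 32)
  for (r in c(1, 3, 9)) {
    h <- lbp_riu_histogram(im, r)
    expect_equal(h[[9]], 1)  # label 8 = eight ones
    expect_equal(sum(h), 1)
  }
})

test_that("LBP histograms are invariant to 90-degree rotation", {
  im <- random_gray(48, seed = 2)
  rot <- t(im)[ncol(im):1, ]
  h1 <- lbp_riu_histogram(im, 1)
  h2 <- lbp_riu_histogram(rot, 1)
  expect_lt(sum(abs(h1 - h2)) / 2, 1e-6)
})

test_that("vectorized LBP matches the per-pixel oracle", {
  for (s in 1:3) {
    im <- random_gray(64, seed = s)
    for (r in c(1, 3)) {
      expect_equal(lbp_riu_histogram(im, r), oracle_lbp_hist(im, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("LBP rejects images too small for the radius", {
  expect_error(lbp_riu_histogram(matrix(0, 10, 10), 9), "radius 9")
})

test_that("mrcLBP emits 120 ordered features with per-channel structure", {
  img <- random_crop(64, seed = 4)
  f <- mrclbp_features(img)
  expect_length(f, 120)
  expect_true(all(f >= 0))
  expect_equal(names(f)[1], "lbp_r_1_0")
  expect_equal(names(f)[120], "lbp_b_27_9")
  # each of the 12 histograms sums to 1
  sums <- colSums(matrix(f, nrow = 10))
  expect_equal(sums, rep(1, 12), tolerance = 1e-9)
  # grayscale crop: identical per-channel sub-blocks
  g <- random_gray(64, seed = 5)
  gray3 <- array(c(g, g, g), c(64, 64, 3))
  fg <- mrclbp_features(gray3)
  expect_equal(unname(fg[1:40]), unname(fg[41:80]))
  expect_equal(unname(fg[1:40]), unname(fg[81:120]))
  expect_identical(mrclbp_features(img), mrclbp_features(img))
  expect_error(mrclbp_features(random_crop(40, seed = 1)), "55")
})

test_that("GLCM counts, symmetrizes and normalizes correctly", {
  const <- matrix(100, 16, 16)
  P <- glcm(const, "0")
  q <- floor(100 / (256 / 64)) + 1
  expect_equal(P[q, q], 1)
  expect_equal(sum(P != 0), 1)

  two <- matrix(c(0, 0, 255, 255), 2, 2)  # [[0,1],[0,1]] pattern at 2 levels
  P2 <- glcm(two, "0", levels = 2)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)

  for (s in 1:5) {
    g <- random_gray(20, seed = s)
    for (d in c("0", "45", "90", "135")) {
      P <- glcm(g, d)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P))
    }
  }
  expect_error(glcm(matrix(0, 1, 5), "90"), "offset")
})

test_that("Haralick indices match hand-derivable cases", {
  Pc <- glcm(matrix(42, 16, 16), "0")
  h <- haralick14(Pc)
  expect_equal(h[["asm"]], 1)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["entropy"]], 0)

  checker <- 255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  Pch <- glcm(checker, "0", levels = 2)
  expect_equal(haralick14(Pch)[["contrast"]], 1)

  expect_error(haralick14(matrix(0.3, 2, 2)), "normalized")
})

test_that("Haralick indices match the literal formula transcription", {
  for (s in 1:5) {
    g <- random_gray(32, seed = s + 10)
    for (d in c("0", "90")) {
      P <- glcm(g, d, levels = 16)
      expect_equal(unname(haralick14(P)), oracle_haralick(P),
                   tolerance = 1e-9)
    }
  }
})

test_that("the directional block reduces 56 values to 28 means and ranges", {
  g <- random_gray(32, seed = 7)
  blk <- haralick_block(g)
  expect_length(blk, 28)
  ranges <- blk[grepl("^har_range_", names(blk))]
  expect_length(ranges, 14)
  expect_true(all(ranges >= 0))

  iso <- matrix(50, 24, 24)
  blk_iso <- haralick_block(iso)
  expect_equal(unname(blk_iso[grepl("^har_range_", names(blk_iso))]),
               rep(0, 14))

  stripes <- matrix(rep(c(0, 255), each = 24, length.out = 24 * 24), 24, 24)
  blk_str <- haralick_block(stripes)
  expect_gt(blk_str[["har_range_contrast"]], 0)
})

test_that("the full descriptor has exactly 150 features", {
  crop <- generate_glomerulus("non_sclerotic", synthesis_params(image_size = 96),
                              seed = 12)
  feats <- extract_features(crop, min_region = 200)
  expect_length(feature_columns(feats), 150)
  expect_length(grep("^lbp_", names(feats)), 120)
  expect_length(grep("^har_", names(feats)), 28)
  expect_length(grep("^morph_", names(feats)), 2)
})
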