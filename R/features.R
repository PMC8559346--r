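#' Extract the full 150-feature descriptor for every crop
#'
#' Per crop: the Bowman's-space segmentation yields 2 morphological features
#' (white area fraction and equivalent radius), the multi-radial colour LBP
#' yields 120 texture features, and the direction-reduced Haralick block on
#' the luminance image yields 28 more, for 150 features in total.
#'
#' @param crops crop tibble (from [generate_dataset()] or [load_crops()]),
#'   optionally carrying a `split` column which is passed through.
#' @param threshold,clean_radius,ac_iterations,k,replicates,min_region
#'   segmentation parameters, see [glomerulus_mask()].
#' @param glcm_distance,glcm_levels co-occurrence parameters, see [glcm()].
#' @param seed integer seed (drives the k-means restarts per crop).
#' @return tibble with `crop_id`, `biopsy_id`, `label` (and `split` if
#'   present) followed by 150 named feature columns.
#' @export
extract_features <- function(crops, threshold = 190, clean_radius = 2,
                             ac_iterations = 200, k = 5, replicates = 3,
                             min_region = 1000, glcm_distance = 1L,
                             glcm_levels = 64L, seed = 1L) {
  rows <- vector("list", nrow(crops))
  for (idx in seq_len(nrow(crops))) {
    img <- crops$pixels[[idx]]
    mask <- glomerulus_mask(img, threshold, clean_radius, ac_iterations,
                            k, replicates, min_region,
                            seed = child_seed(seed, "kmeans", idx))
    morph <- morphological_features(mask)
    lbp <- mrclbp_features(img)
    har <- haralick_block(luminance(img), glcm_distance, glcm_levels)
    rows[[idx]] <- tibble::as_tibble_row(c(
      morph_area = morph$morph_area, morph_radius = morph$morph_radius,
      as.list(lbp), as.list(har)
    ))
  }
  meta_cols <- intersect(c("crop_id", "biopsy_id", "label", "split"),
                         names(crops))
  dplyr::bind_cols(crops[meta_cols], dplyr::bind_rows(rows))
}

#' Names of the feature columns of a feature table
#'
#' @param features a tibble from [extract_features()].
#' @return character vector of the numeric feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features),
          c("crop_id", "biopsy_id", "section_id", "label", "split",
            "artifact"))
}
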