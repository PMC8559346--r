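#' Read an RGB image as an 8-bit array
#'
#' Reads a PNG or TIFF image and returns it as an H x W x 3 integer array
#' with intensities in `[0, 255]`, rows indexing y and columns indexing x.
#'
#' @param path file path to a PNG or TIFF image.
#' @return H x W x 3 integer array.
#' @export
read_image <- function(path) {
  im <- EBImage::readImage(path)
  dat <- EBImage::imageData(im)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  arr <- aperm(dat, c(2, 1, 3)) * 255
  storage.mode(arr) <- "integer"
  arr
}

#' Write an 8-bit RGB array to PNG or TIFF
#'
#' @param img H x W x 3 array, intensities in `[0, 255]`.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_raster(img)
  im <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(im, path)
  invisible(path)
}

#' Read polygon annotations
#'
#' Reads a JSON array of annotated glomerulus regions. Each element carries
#' `polygon` (list of `[x, y]` pixel vertices), `label` (`"sclerotic"` or
#' `"non_sclerotic"`), `biopsy_id`, `section_id` and `image` (path of the
#' source image, relative to the annotation file).
#'
#' @param path path to the annotation JSON file.
#' @return tibble with columns `polygon` (list of n x 2 matrices), `label`,
#'   `biopsy_id`, `section_id`, `image`.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(raw, function(el) {
    poly <- do.call(rbind, lapply(el$polygon, function(v) as.numeric(unlist(v))))
    if (is.null(poly) || nrow(poly) < 3L) {
      stop("annotation polygon must have at least 3 vertices", call. = FALSE)
    }
    tibble(
      polygon = list(poly),
      label = as.character(el$label),
      biopsy_id = as.character(el$biopsy_id),
      section_id = as.character(el$section_id %||% NA_character_),
      image = as.character(el$image)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$label <- as.character(as_glom_factor(out$label))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write polygon annotations
#'
#' Inverse of [read_annotations()].
#'
#' @param regions tibble as returned by [read_annotations()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  recs <- purrr::pmap(regions, function(polygon, label, biopsy_id, section_id,
                                        image, ...) {
    list(
      polygon = lapply(seq_len(nrow(polygon)), function(i) polygon[i, ]),
      label = label, biopsy_id = biopsy_id, section_id = section_id,
      image = image
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Overestimated bounding box of an annotation polygon
#'
#' Computes the tight axis-aligned bounding box of the polygon, scales each
#' side by `factor` about the box center (compensating the annotators'
#' outline variability), rounds outward to integer pixels and clamps the
#' result to the image extent. Rectangles are 0-based and half-open:
#' `[x0, x1) x [y0, y1)`.
#'
#' @param polygon n x 2 matrix of (x, y) vertices, n >= 3.
#' @param factor per-side overestimation factor, >= 1 (default 1.1).
#' @param image_extent `c(width, height)` of the source image.
#' @return named numeric vector `c(x0, y0, x1, y1)`.
#' @export
expand_bbox <- function(polygon, factor = 1.1, image_extent) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  x <- polygon[, 1]; y <- polygon[, 2]
  x0t <- min(x); x1t <- max(x); y0t <- min(y); y1t <- max(y)
  if (x1t - x0t <= 0 || y1t - y0t <= 0) {
    stop("degenerate polygon: zero width or height bounding box", call. = FALSE)
  }
  cx <- (x0t + x1t) / 2; cy <- (y0t + y1t) / 2
  hw <- (x1t - x0t) * factor / 2; hh <- (y1t - y0t) * factor / 2
  # outward rounding, tolerant of floating-point noise at exact integers
  fl <- function(z) floor(z + 1e-9)
  ce <- function(z) ceiling(z - 1e-9)
  c(
    x0 = max(0, fl(cx - hw)),
    y0 = max(0, fl(cy - hh)),
    x1 = min(image_extent[1], ce(cx + hw)),
    y1 = min(image_extent[2], ce(cy + hh))
  )
}

#' Extract a rectangular crop from a slide image
#'
#' Copies the sub-region `[x0, x1) x [y0, y1)` (0-based, half-open) out of an
#' image array and packages it with its provenance.
#'
#' @param img H x W x 3 array (a slide or section image).
#' @param rect `c(x0, y0, x1, y1)` rectangle as from [expand_bbox()].
#' @param label `"sclerotic"`, `"non_sclerotic"` or `NA`.
#' @param biopsy_id,section_id provenance strings.
#' @param crop_id identifier for the crop.
#' @return one-row crop tibble (columns `crop_id`, `pixels`, `label`,
#'   `biopsy_id`, `section_id`, `crop_rect`, `artifact`).
#' @export
extract_crop <- function(img, rect, label = NA, biopsy_id = NA_character_,
                         section_id = NA_character_, crop_id = "crop") {
  assert_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  rect <- round(rect)
  nm <- c("x0", "y0", "x1", "y1")
  if (is.null(names(rect))) names(rect) <- nm
  for (v in nm) {
    lim <- if (v %in% c("x0", "x1")) W else H
    if (rect[[v]] < 0 || rect[[v]] > lim) {
      stop(sprintf("rectangle coordinate %s = %d outside image extent [0, %d]",
                   v, rect[[v]], lim), call. = FALSE)
    }
  }
  if (rect[["x1"]] <= rect[["x0"]] || rect[["y1"]] <= rect[["y0"]]) {
    stop("empty rectangle", call. = FALSE)
  }
  px <- img[(rect[["y0"]] + 1):rect[["y1"]],
            (rect[["x0"]] + 1):rect[["x1"]], , drop = FALSE]
  tibble(
    crop_id = crop_id,
    pixels = list(px),
    label = if (is.na(label)) factor(NA, levels = glom_levels())
            else as_glom_factor(label),
    biopsy_id = biopsy_id,
    section_id = section_id,
    crop_rect = list(rect[nm]),
    artifact = FALSE
  )
}

#' Extract all annotated crops from their source images
#'
#' Applies [expand_bbox()] and [extract_crop()] to every region of an
#' annotation table, reading each distinct source image once.
#'
#' @param regions annotation tibble from [read_annotations()].
#' @param factor bounding-box overestimation factor (default 1.1).
#' @param base_dir directory that the `image` paths are relative to.
#' @return crop tibble, one row per annotated region.
#' @export
load_crops <- function(regions, factor = 1.1, base_dir = ".") {
  out <- vector("list", nrow(regions))
  cache_path <- ""
  img <- NULL
  idx <- order(regions$image)
  for (i in idx) {
    p <- file.path(base_dir, regions$image[i])
    if (!identical(p, cache_path)) {
      img <- read_image(p)
      cache_path <- p
    }
    rect <- expand_bbox(regions$polygon[[i]], factor,
                        image_extent = c(dim(img)[2], dim(img)[1]))
    out[[i]] <- extract_crop(img, rect,
                             label = regions$label[i],
                             biopsy_id = regions$biopsy_id[i],
                             section_id = regions$section_id[i],
                             crop_id = sprintf("crop_%04d", i))
  }
  dplyr::bind_rows(out)
}

#' Train/test split at biopsy level
#'
#' Assigns whole biopsies to the test set so that no biopsy contributes
#' glomeruli to both sides, choosing the assignment whose test glomerulus
#' count is closest to `test_fraction` of the total. For up to 15 biopsies
#' all subsets are enumerated (the closest achievable split is exact); beyond
#' that a seeded randomized greedy search is used. Ties between equally close
#' assignments are broken at random under `seed`.
#'
#' @param crops crop tibble with a `biopsy_id` column.
#' @param test_fraction target fraction of glomeruli in the test set.
#' @param seed integer seed controlling tie-breaks / search order.
#' @return the input tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_by_biopsy <- function(crops, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  counts <- table(crops$biopsy_id)
  ids <- names(counts)
  n_bio <- length(ids)
  if (n_bio < 2) {
    stop("need at least 2 distinct biopsies for a biopsy-level split",
         call. = FALSE)
  }
  sizes <- as.numeric(counts)
  total <- sum(sizes)

  pick <- withr::with_seed(seed, {
    if (n_bio <= 15L) {
      n_sub <- bitwShiftL(1L, n_bio)
      ss <- numeric(n_sub)
      for (m in 1:(n_sub - 1)) {
        low <- bitwAnd(m, -m)
        ss[m + 1] <- ss[bitwXor(m, low) + 1] + sizes[1 + round(log2(low))]
      }
      cand <- 1:(n_sub - 2)  # exclude empty and full subsets
      dist <- abs(ss[cand + 1] / total - test_fraction)
      best <- cand[dist == min(dist)]
      m <- if (length(best) == 1) best else sample(best, 1)
      ids[bitwAnd(bitwShiftR(m, seq_len(n_bio) - 1L), 1L) == 1L]
    } else {
      best_set <- NULL
      best_dist <- Inf
      for (r in 1:200) {
        ord <- sample(n_bio)
        sel <- logical(n_bio)
        cur <- 0
        for (b in ord) {
          new <- cur + sizes[b]
          if (abs(new / total - test_fraction) <= abs(cur / total - test_fraction) &&
              sum(sel) < n_bio - 1) {
            sel[b] <- TRUE
            cur <- new
          }
        }
        if (!any(sel)) { sel[ord[1]] <- TRUE; cur <- sizes[ord[1]] }
        d <- abs(cur / total - test_fraction)
        if (d < best_dist) { best_dist <- d; best_set <- ids[sel] }
      }
      best_set
    }
  })

  crops$split <- ifelse(crops$biopsy_id %in% pick, "test", "train")
  crops
}
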