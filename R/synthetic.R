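#' Parameters for the synthetic PAS-like glomerulus generator
#'
#' Bundles and validates the generator settings. Defaults emulate the
#' conditions the classifier is designed for: crops of 128 px, capsule
#' semi-axes of 38-50 px, a 5.5:1 non-sclerotic to sclerotic imbalance, 10
#' biopsies of 30 glomeruli each, per-biopsy colour/saturation offsets and no
#' artifacts.
#'
#' @param image_size side length of the square crop, in pixels.
#' @param glomerulus_radius_range range of capsule semi-axes, in pixels.
#' @param class_ratio non-sclerotic glomeruli per sclerotic one.
#' @param n_biopsies number of simulated biopsies.
#' @param glomeruli_per_biopsy crops per biopsy.
#' @param saturation_jitter strength of per-biopsy colour offsets in
#'   `[0, 1]`; 0 disables biopsy-to-biopsy stain variability.
#' @param artifact_rate probability in `[0, 1]` that a crop carries an
#'   artifact (edge-truncated glomerulus or stain blob).
#' @param seed master integer seed.
#' @return a validated `synthesis_params` list.
#' @export
synthesis_params <- function(image_size = 128,
                             glomerulus_radius_range = c(38, 50),
                             class_ratio = 5.5,
                             n_biopsies = 10,
                             glomeruli_per_biopsy = 30,
                             saturation_jitter = 0.15,
                             artifact_rate = 0,
                             seed = 1L) {
  stopifnot(
    image_size > 0, n_biopsies > 0, glomeruli_per_biopsy > 0,
    class_ratio > 0,
    length(glomerulus_radius_range) == 2,
    all(glomerulus_radius_range > 0),
    saturation_jitter >= 0, saturation_jitter <= 1,
    artifact_rate >= 0, artifact_rate <= 1
  )
  if (image_size < 2 * min(glomerulus_radius_range) + 4) {
    stop("image_size too small to contain the minimum glomerulus radius",
         call. = FALSE)
  }
  structure(
    list(
      image_size = as.integer(image_size),
      glomerulus_radius_range = as.numeric(glomerulus_radius_range),
      class_ratio = class_ratio,
      n_biopsies = as.integer(n_biopsies),
      glomeruli_per_biopsy = as.integer(glomeruli_per_biopsy),
      saturation_jitter = saturation_jitter,
      artifact_rate = artifact_rate,
      seed = as.integer(seed)
    ),
    class = "synthesis_params"
  )
}

# reference colours (RGB, 0-255): chosen so whites sit well above the 190
# white threshold while stained tissue sits below it on the green and
# magenta-complement channels
synth_palette <- function() {
  list(
    background = c(210, 140, 180),
    matrix     = c(200, 120, 160),
    white      = c(242, 243, 246),
    nucleus    = c(60, 60, 140),
    ring       = c(175, 105, 145),
    blob       = c(120, 70, 110)
  )
}

# paint filled disks into a list of 3 channel matrices (in place semantics
# via return value)
paint_disks <- function(ch, cx, cy, r, col) {
  S <- nrow(ch[[1]])
  for (d in seq_along(cx)) {
    x0 <- max(1, floor(cx[d] - r[d])); x1 <- min(S, ceiling(cx[d] + r[d]))
    y0 <- max(1, floor(cy[d] - r[d])); y1 <- min(S, ceiling(cy[d] + r[d]))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy[d])^2, (xs - cx[d])^2, "+") <= r[d]^2
    for (c3 in 1:3) {
      sub <- ch[[c3]][ys, xs, drop = FALSE]
      sub[dd] <- col[c3]
      ch[[c3]][ys, xs] <- sub
    }
  }
  ch
}

# smooth random bump field in roughly [-1, 1]
bump_field <- function(S, n_bumps = 15) {
  f <- matrix(0, S, S)
  xx <- col(f); yy <- row(f)
  for (b in seq_len(n_bumps)) {
    bx <- runif(1, 1, S); by <- runif(1, 1, S)
    sg <- runif(1, 6, 14); amp <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    f <- f + amp * exp(-((xx - bx)^2 + (yy - by)^2) / (2 * sg^2))
  }
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

#' Generate one synthetic glomerulus crop
#'
#' Draws a PAS-like glomerulus. Non-sclerotic crops show an elliptic capsule
#' with a near-white annular Bowman's space, white capillary lumens and
#' dark-blue nuclei over a mottled pink-magenta mesangial matrix (the
#' "pomegranate" texture). Sclerotic crops show a homogeneous pink-magenta
#' ellipse with obliterated lumens, at most one residual white blob and
#' sparse nuclei. Fully deterministic given `seed`.
#'
#' @param class_label `"sclerotic"` or `"non_sclerotic"`.
#' @param params a [synthesis_params()] object.
#' @param seed integer seed for this crop.
#' @param biopsy_offset length-3 additive RGB offset emulating the biopsy's
#'   staining/saturation profile.
#' @param crop_id,biopsy_id,section_id provenance strings.
#' @return one-row crop tibble.
#' @export
generate_glomerulus <- function(class_label, params = synthesis_params(),
                                seed = params$seed,
                                biopsy_offset = c(0, 0, 0),
                                crop_id = "crop_001",
                                biopsy_id = "biopsy_01",
                                section_id = NA_character_) {
  class_label <- match.arg(class_label, glom_levels())
  pal <- synth_palette()
  S <- params$image_size
  r0 <- params$glomerulus_radius_range[1]
  r1 <- params$glomerulus_radius_range[2]
  sclerotic <- class_label == "sclerotic"

  res <- withr::with_seed(seed, {
    base <- matrix(0, S, S)
    xx <- col(base); yy <- row(base)
    cx <- S / 2 + runif(1, -3, 3)
    cy <- S / 2 + runif(1, -3, 3)

    artifact <- runif(1) < params$artifact_rate
    art_type <- if (artifact) sample(c("truncation", "blob"), 1) else "none"
    if (art_type == "truncation") cx <- cx + 0.45 * S

    a <- runif(1, r0, r1); b <- runif(1, r0, r1)
    th <- runif(1, 0, pi)
    u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    e <- (u / a)^2 + (v / b)^2
    cap <- e <= 1
    ts <- if (sclerotic) 1 else runif(1, 0.78, 0.86)
    tuft <- e <= ts^2
    ring <- e > 1 & e <= 1.12

    ch <- lapply(1:3, function(c3) matrix(pal$background[c3], S, S))
    f <- bump_field(S)
    amp <- if (sclerotic) c(4, 6, 5) else c(12, 20, 14)
    for (c3 in 1:3) {
      ch[[c3]][tuft] <- pal$matrix[c3] + amp[c3] * f[tuft]
      if (!sclerotic) {
        ch[[c3]][cap & !tuft] <- pal$white[c3]
        ch[[c3]][ring] <- pal$ring[c3]
      }
    }

    # capillary lumens (white blobs) inside the tuft
    n_lum <- if (sclerotic) stats::rbinom(1, 1, 0.25) else sample(8:14, 1)
    if (n_lum > 0) {
      ang <- runif(n_lum, 0, 2 * pi)
      rr <- sqrt(runif(n_lum)) * 0.72
      lx <- cx + ts * (a * rr * cos(ang) * cos(th) - b * rr * sin(ang) * sin(th))
      ly <- cy + ts * (a * rr * cos(ang) * sin(th) + b * rr * sin(ang) * cos(th))
      lr <- if (sclerotic) runif(n_lum, 1.5, 3) else runif(n_lum, 2.5, 5)
      ch <- paint_disks(ch, lx, ly, lr, pal$white)
    }

    # cell nuclei (small dark-blue dots)
    n_nuc <- if (sclerotic) sample(4:10, 1) else sample(30:60, 1)
    ang <- runif(n_nuc, 0, 2 * pi)
    rr <- sqrt(runif(n_nuc)) * 0.93
    nx <- cx + ts * (a * rr * cos(ang) * cos(th) - b * rr * sin(ang) * sin(th))
    ny <- cy + ts * (a * rr * cos(ang) * sin(th) + b * rr * sin(ang) * cos(th))
    nr <- runif(n_nuc, 1.2, 2)
    ch <- paint_disks(ch, nx, ny, nr, pal$nucleus)

    if (art_type == "blob") {
      ch <- paint_disks(ch, runif(1, S * 0.2, S * 0.8),
                        runif(1, S * 0.2, S * 0.8),
                        runif(1, 10, 18), pal$blob)
    }

    noise_sd <- if (sclerotic) 4 else 8
    img <- array(0, c(S, S, 3))
    for (c3 in 1:3) {
      img[, , c3] <- ch[[c3]] + biopsy_offset[c3] +
        matrix(rnorm(S * S, 0, noise_sd), S, S)
    }
    img <- pmin(pmax(round(img), 0), 255)
    storage.mode(img) <- "integer"
    list(img = img, artifact = artifact, ellipse = cap)
  })

  out <- tibble(
    crop_id = crop_id,
    pixels = list(res$img),
    label = as_glom_factor(class_label),
    biopsy_id = biopsy_id,
    section_id = section_id,
    crop_rect = list(c(x0 = 0, y0 = 0, x1 = S, y1 = S)),
    artifact = res$artifact
  )
  attr(out, "ellipse_mask") <- res$ellipse
  out
}

#' Generate a full labelled synthetic dataset
#'
#' Simulates `n_biopsies x glomeruli_per_biopsy` crops. The number of
#' sclerotic crops is `round(total / (class_ratio + 1))`, placed at random
#' positions across biopsies; each biopsy carries one colour-offset profile
#' applied to all of its crops. Deterministic given `params$seed`.
#'
#' @param params a [synthesis_params()] object.
#' @return crop tibble with one row per glomerulus.
#' @export
generate_dataset <- function(params = synthesis_params()) {
  n_total <- params$n_biopsies * params$glomeruli_per_biopsy
  n_scl <- round(n_total / (params$class_ratio + 1))
  n_scl <- max(1L, min(n_total - 1L, n_scl))

  plan <- withr::with_seed(params$seed, {
    offsets <- matrix(runif(params$n_biopsies * 3, -1, 1) *
                        60 * params$saturation_jitter,
                      nrow = params$n_biopsies)
    labels <- sample(c(rep("sclerotic", n_scl),
                       rep("non_sclerotic", n_total - n_scl)))
    list(offsets = offsets, labels = labels)
  })

  bio <- rep(seq_len(params$n_biopsies), each = params$glomeruli_per_biopsy)
  pos <- sequence(rep(params$glomeruli_per_biopsy, params$n_biopsies))
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    rows[[i]] <- generate_glomerulus(
      plan$labels[i], params,
      seed = child_seed(params$seed, "crop", i),
      biopsy_offset = plan$offsets[bio[i], ],
      crop_id = sprintf("crop_%04d", i),
      biopsy_id = sprintf("biopsy_%02d", bio[i]),
      section_id = sprintf("biopsy_%02d_s%d", bio[i], ceiling(pos[i] / 10))
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset to disk
#'
#' Writes each crop as an 8-bit PNG plus a single `annotations.json` in the
#' dialect read by [read_annotations()] (the polygon is the crop rectangle).
#'
#' @param crops crop tibble from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the annotation file path, invisibly.
#' @export
write_dataset <- function(crops, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- purrr::pmap(crops, function(crop_id, pixels, label, biopsy_id,
                                         section_id, ...) {
    fn <- paste0(crop_id, ".png")
    write_image(pixels, file.path(dir, fn))
    H <- dim(pixels)[1]; W <- dim(pixels)[2]
    tibble(
      polygon = list(rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))),
      label = as.character(label),
      biopsy_id = biopsy_id,
      section_id = section_id,
      image = fn
    )
  })
  path <- file.path(dir, "annotations.json")
  write_annotations(dplyr::bind_rows(regions), path)
  invisible(path)
}
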