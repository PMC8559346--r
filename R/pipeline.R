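#' Pipeline configuration with the workflow's default parameters
#'
#' Single nested configuration covering every stage. Defaults are the
#' workflow's operating point: segmentation threshold 190, cleaning disk
#' radius 2, 200 active-contour iterations, k-means with 5 clusters and 3
#' replicates, 1000-pixel minimum region, LBP radii 1/3/9/27, 4-direction
#' GLCM with distance 1 and 64 levels, z-score + PCA at 99.9% variance,
#' 10-fold ensemble of 27-unit networks with 5 initializations per fold,
#' 6-epoch validation-fail early stop, ROC Approach B thresholds, and a
#' 20% biopsy-level test split.
#'
#' @param ... named overrides for any nested field, e.g.
#'   `synthesis = list(n_biopsies = 4)`.
#' @param yaml_file optional YAML file of overrides applied before `...`.
#' @param seed master seed (propagated to every stochastic stage).
#' @return nested list of class `glom_config`.
#' @export
pipeline_config <- function(..., yaml_file = NULL, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    synthesis = list(
      image_size = 128, glomerulus_radius_range = c(38, 50),
      class_ratio = 5.5, n_biopsies = 10, glomeruli_per_biopsy = 30,
      saturation_jitter = 0.15, artifact_rate = 0
    ),
    split = list(test_fraction = 0.2),
    morphology = list(
      threshold = 190, clean_radius = 2, ac_iterations = 200,
      kmeans_k = 5, kmeans_replicates = 3, min_region_px = 1000
    ),
    texture = list(glcm_distance = 1, glcm_levels = 64),
    preprocess = list(variance_threshold = 0.999, fit_scope = "train_only"),
    classifier = list(
      hidden_size = 27, k_folds = 10, inits_per_fold = 5,
      early_stop_window = 6, max_epochs = 1000, val_fraction = 0.15,
      threshold_method = "B"
    )
  )
  apply_overrides <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- apply_overrides(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  if (!is.null(yaml_file)) {
    cfg <- apply_overrides(cfg, yaml::read_yaml(yaml_file))
  }
  dots <- list(...)
  if (length(dots)) cfg <- apply_overrides(cfg, dots)
  structure(cfg, class = "glom_config")
}

cfg_synthesis_params <- function(config) {
  s <- config$synthesis
  synthesis_params(
    image_size = s$image_size,
    glomerulus_radius_range = s$glomerulus_radius_range,
    class_ratio = s$class_ratio, n_biopsies = s$n_biopsies,
    glomeruli_per_biopsy = s$glomeruli_per_biopsy,
    saturation_jitter = s$saturation_jitter,
    artifact_rate = s$artifact_rate,
    seed = child_seed(config$seed, "synthesis")
  )
}

cfg_network_config <- function(config) {
  cl <- config$classifier
  network_config(
    hidden_size = cl$hidden_size, inits_per_fold = cl$inits_per_fold,
    early_stop_window = cl$early_stop_window, max_epochs = cl$max_epochs,
    val_fraction = cl$val_fraction, threshold_method = cl$threshold_method
  )
}

#' Run the end-to-end workflow
#'
#' Executes the requested stages in order: `simulate` (synthetic dataset +
#' biopsy-level split), `features` (150-feature table), `train`
#' (preprocessing fit on the training portion + k-fold ensemble), `predict`
#' (hard-voted test-set labels) and `evaluate` (confusion matrix and the
#' four metrics). Each stage writes its artifact under `out_dir` along with
#' a resolved copy of the configuration; a stage whose upstream artifact is
#' missing fails with an error naming the stage to run first. Reruns with
#' an identical configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "features", "train", "predict", "evaluate")`, in order.
#' @param write_images if `TRUE`, the simulate stage also writes PNG crops
#'   and the annotation JSON under `out_dir/crops`.
#' @return invisible list with the in-memory artifacts of the executed
#'   stages (`crops`, `features`, `model`, `predictions`, `metrics`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("glom_run_"),
                         stages = c("simulate", "features", "train",
                                    "predict", "evaluate"),
                         write_images = FALSE) {
  all_stages <- c("simulate", "features", "train", "predict", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  state <- list()
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    model = file.path(out_dir, "model"),
    predictions = file.path(out_dir, "predictions.csv"),
    metrics = file.path(out_dir, "metrics.json")
  )
  need <- function(what, stage_needed) {
    if (!is.null(state[[what]])) return(state[[what]])
    p <- paths[[what]]
    ok <- if (what == "model") dir.exists(p) else file.exists(p)
    if (!ok) {
      stop(sprintf("missing %s artifact: run stage '%s' first",
                   what, stage_needed), call. = FALSE)
    }
    switch(what,
           features = {
             f <- tibble::as_tibble(read.csv(p, check.names = FALSE))
             f$label <- as_glom_factor(f$label)
             f
           },
           model = load_model(p),
           predictions = {
             pr <- tibble::as_tibble(read.csv(p, check.names = FALSE))
             pr$truth <- as_glom_factor(pr$truth)
             pr$.pred <- as_glom_factor(pr$.pred)
             pr
           })
  }

  for (st in stages) {
    if (st == "simulate") {
      crops <- generate_dataset(cfg_synthesis_params(config))
      crops <- split_by_biopsy(crops, config$split$test_fraction,
                               seed = child_seed(config$seed, "split"))
      if (write_images) write_dataset(crops, file.path(out_dir, "crops"))
      state$crops <- crops
    } else if (st == "features") {
      if (is.null(state$crops)) {
        stop("missing crops in memory: run stage 'simulate' first",
             call. = FALSE)
      }
      m <- config$morphology; tx <- config$texture
      feats <- extract_features(
        state$crops, threshold = m$threshold, clean_radius = m$clean_radius,
        ac_iterations = m$ac_iterations, k = m$kmeans_k,
        replicates = m$kmeans_replicates, min_region = m$min_region_px,
        glcm_distance = tx$glcm_distance, glcm_levels = tx$glcm_levels,
        seed = child_seed(config$seed, "features")
      )
      write.csv(feats, paths$features, row.names = FALSE)
      state$features <- feats
    } else if (st == "train") {
      feats <- need("features", "features")
      train_tbl <- feats[feats$split == "train", , drop = FALSE]
      prep_data <- if (config$preprocess$fit_scope == "whole_dataset") {
        feats
      } else {
        train_tbl
      }
      prep <- preprocess_fit(prep_data, config$preprocess$variance_threshold,
                             config$preprocess$fit_scope)
      reduced <- preprocess_transform(train_tbl, prep)
      model <- train_ensemble(reduced, k = config$classifier$k_folds,
                              config = cfg_network_config(config),
                              seed = child_seed(config$seed, "ensemble"),
                              prep = prep)
      save_model(model, paths$model)
      state$model <- model
    } else if (st == "predict") {
      feats <- need("features", "features")
      model <- need("model", "train")
      test_tbl <- feats[feats$split == "test", , drop = FALSE]
      if (nrow(test_tbl) == 0) stop("test split is empty", call. = FALSE)
      pred <- predict(model, test_tbl)
      out <- dplyr::bind_cols(
        test_tbl[intersect(c("crop_id", "biopsy_id"), names(test_tbl))],
        tibble(truth = test_tbl$label), pred
      )
      write.csv(out, paths$predictions, row.names = FALSE)
      state$predictions <- out
    } else if (st == "evaluate") {
      pr <- need("predictions", "predict")
      cm <- confusion_matrix(pr$truth, pr$.pred)
      met <- classification_metrics(cm)
      by_biopsy <- pr |>
        dplyr::group_by(.data$biopsy_id) |>
        dplyr::summarise(
          n = dplyr::n(),
          accuracy = mean(.data$truth == .data$.pred),
          .groups = "drop"
        )
      report <- list(
        confusion_matrix = list(tp = cm$tp, fp = cm$fp, fn = cm$fn,
                                tn = cm$tn),
        metrics = as.list(met),
        flags = attr(met, "flags"),
        per_biopsy = by_biopsy,
        seed = config$seed
      )
      jsonlite::write_json(report, paths$metrics, auto_unbox = TRUE,
                           digits = NA)
      state$metrics <- report
    }
  }
  invisible(state)
}

#' Save / load an ensemble model bundle
#'
#' The bundle is a directory holding a JSON manifest (configuration, fold
#' thresholds, seeds, preprocessing parameters) plus the flat weight vectors
#' of the fold networks, all as text.
#'
#' @param model a `glom_ensemble`.
#' @param path bundle directory.
#' @return `path` (for `save_model`) or the restored `glom_ensemble`.
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    version = 1L,
    k = model$k,
    seed = model$seed,
    config = unclass(model$config),
    feature_names = model$feature_names,
    folds = lapply(model$folds, function(f) {
      list(fold_index = f$fold_index, threshold = f$threshold,
           validation_mcc = f$validation_mcc, d = f$net$d, h = f$net$h,
           seed = f$net$seed, par = f$net$par)
    })
  )
  if (!is.null(model$prep)) {
    manifest$prep <- list(
      features = model$prep$features,
      means = model$prep$zscore$means,
      stds = model$prep$zscore$stds,
      zero_var = model$prep$zscore$zero_var,
      pca_center = model$prep$pca$center,
      rotation = model$prep$pca$rotation,
      explained_variance_ratio = model$prep$pca$explained_variance_ratio,
      n_retained = model$prep$pca$n_retained,
      variance_threshold = model$prep$pca$variance_threshold,
      fit_scope = model$prep$pca$fit_scope
    )
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- jsonlite::read_json(file.path(path, "manifest.json"),
                           simplifyVector = TRUE)
  cfg <- network_config(
    hidden_size = m$config$hidden_size,
    inits_per_fold = m$config$inits_per_fold,
    early_stop_window = m$config$early_stop_window,
    max_epochs = m$config$max_epochs,
    val_fraction = m$config$val_fraction,
    threshold_method = m$config$threshold_method
  )
  folds <- lapply(seq_len(m$k), function(i) {
    f <- if (is.data.frame(m$folds)) {
      as.list(m$folds[i, ])
    } else {
      m$folds[[i]]
    }
    par <- unlist(f$par)
    list(net = structure(list(par = par, d = f$d, h = f$h,
                              seed = f$seed, epochs = NA_integer_),
                         class = "glom_net"),
         threshold = f$threshold, fold_index = f$fold_index,
         validation_mcc = f$validation_mcc)
  })
  prep <- NULL
  if (!is.null(m$prep)) {
    rot <- m$prep$rotation
    if (is.list(rot)) rot <- do.call(rbind, lapply(rot, unlist))
    zs <- structure(list(means = unlist(m$prep$means),
                         stds = unlist(m$prep$stds),
                         zero_var = unlist(m$prep$zero_var),
                         features = m$prep$features),
                    class = "glom_zscore")
    names(zs$means) <- names(zs$stds) <- m$prep$features
    pca <- structure(list(rotation = rot,
                          center = unlist(m$prep$pca_center),
                          explained_variance_ratio =
                            unlist(m$prep$explained_variance_ratio),
                          n_retained = m$prep$n_retained,
                          variance_threshold = m$prep$variance_threshold,
                          fit_scope = m$prep$fit_scope),
                     class = "glom_pca")
    prep <- structure(list(zscore = zs, pca = pca,
                           features = m$prep$features),
                      class = "glom_prep")
  }
  structure(
    list(folds = folds, k = m$k, config = cfg, seed = m$seed,
         feature_names = m$feature_names, prep = prep),
    class = "glom_ensemble"
  )
}

#' Workflow stability over repeated training runs
#'
#' Repeats the full pipeline with independent master seeds and summarizes
#' the test-set metrics as mean and standard deviation, mirroring a
#' repeated-initialization stability experiment.
#'
#' @param config a [pipeline_config()].
#' @param n_runs number of independent runs.
#' @param seeds optional explicit seeds (length `n_runs`).
#' @return list with the per-run `runs` tibble and the `summary` tibble.
#' @export
run_stability <- function(config = pipeline_config(), n_runs = 3,
                          seeds = NULL) {
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_runs), function(i) child_seed(config$seed, "run", i),
                    integer(1))
  }
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    res <- run_pipeline(cfg, out_dir = tempfile("glom_stab_"))
    dplyr::bind_cols(tibble(seed = s),
                     tibble::as_tibble(res$metrics$metrics))
  })
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    tidyr::pivot_longer(-"seed", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  list(runs = runs, summary = summary)
}
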