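#' Fit per-feature z-score standardization
#'
#' Stores the per-column mean and standard deviation (population convention,
#' denominator N). Columns with zero spread are flagged and given a stored
#' standard deviation of 1 so their transformed values are exactly 0.
#'
#' @param X data frame or matrix of numeric features (rows = crops).
#' @return object of class `glom_zscore` with `means`, `stds`, `zero_var`.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  means <- colMeans(X)
  stds <- sqrt(colMeans(sweep(X, 2, means)^2))
  zero_var <- stds <= 0
  stds[zero_var] <- 1
  structure(list(means = means, stds = stds, zero_var = zero_var,
                 features = colnames(X)),
            class = "glom_zscore")
}

#' Apply a fitted z-score standardization
#'
#' @param X data frame or matrix with the same columns the fit saw.
#' @param params a `glom_zscore` object from [zscore_fit()].
#' @return numeric matrix of standardized features.
#' @export
zscore_transform <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$means)) {
    stop("feature count does not match the standardization fit",
         call. = FALSE)
  }
  sweep(sweep(X, 2, params$means), 2, params$stds, "/")
}

#' Fit PCA retaining a fixed share of variance
#'
#' Principal component analysis of already-standardized features; the number
#' of retained components is the smallest m whose cumulative explained
#' variance reaches `variance_threshold` (default 99.9%).
#'
#' @param X_standardized numeric matrix from [zscore_transform()].
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @param fit_scope `"train_only"` (default; the model is fit on training
#'   rows only, avoiding information leakage) or `"whole_dataset"` (fit on
#'   all rows; label-free, but the test distribution informs the basis).
#'   Recorded for provenance; the caller supplies the matching rows.
#' @return object of class `glom_pca` with the orthonormal `rotation`
#'   (p x m), `explained_variance_ratio`, `n_retained`.
#' @export
pca_fit <- function(X_standardized, variance_threshold = 0.999,
                    fit_scope = c("train_only", "whole_dataset")) {
  fit_scope <- match.arg(fit_scope)
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("`variance_threshold` must be in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(X_standardized, center = TRUE, scale. = FALSE)
  var_comp <- pc$sdev^2
  ratio <- var_comp / sum(var_comp)
  cum <- cumsum(ratio)
  n_ret <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(n_ret)) n_ret <- length(ratio)
  structure(
    list(rotation = pc$rotation[, seq_len(n_ret), drop = FALSE],
         center = pc$center,
         explained_variance_ratio = ratio,
         n_retained = n_ret,
         variance_threshold = variance_threshold,
         fit_scope = fit_scope),
    class = "glom_pca"
  )
}

#' Standardize and project a feature table
#'
#' Applies a fitted standardization and PCA model, returning the reduced
#' coordinates.
#'
#' @param X data frame or matrix of raw features.
#' @param params a `glom_zscore` object.
#' @param model a `glom_pca` object.
#' @return tibble with `n_retained` columns `PC1..PCm`.
#' @export
transform_features <- function(X, params, model) {
  Z <- zscore_transform(X, params)
  Z <- sweep(Z, 2, model$center)
  proj <- Z %*% model$rotation
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  as_tibble(proj)
}

#' Fit the full preprocessing bundle on a feature table
#'
#' Convenience wrapper: z-score fit plus PCA fit on the feature columns of a
#' table from [extract_features()].
#'
#' @param features feature tibble.
#' @param variance_threshold see [pca_fit()].
#' @param fit_scope see [pca_fit()].
#' @return object of class `glom_prep` bundling both fits.
#' @export
preprocess_fit <- function(features, variance_threshold = 0.999,
                           fit_scope = c("train_only", "whole_dataset")) {
  fit_scope <- match.arg(fit_scope)
  fc <- feature_columns(features)
  zs <- zscore_fit(features[fc])
  pca <- pca_fit(zscore_transform(features[fc], zs), variance_threshold,
                 fit_scope)
  structure(list(zscore = zs, pca = pca, features = fc),
            class = "glom_prep")
}

#' Apply a preprocessing bundle to a feature table
#'
#' @param features feature tibble (metadata columns pass through).
#' @param prep a `glom_prep` object from [preprocess_fit()].
#' @return tibble: metadata columns followed by the reduced `PC` columns.
#' @export
preprocess_transform <- function(features, prep) {
  red <- transform_features(features[prep$features], prep$zscore, prep$pca)
  meta <- setdiff(names(features), prep$features)
  dplyr::bind_cols(features[meta], red)
}
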