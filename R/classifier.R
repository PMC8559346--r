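#' Empirical ROC curve of positive-class scores
#'
#' One point per distinct score threshold (prediction rule: sclerotic iff
#' score >= threshold) plus the degenerate all-negative endpoint, computed
#' by direct counting. Endpoints (sensitivity, specificity) = (0, 1) and
#' (1, 0) are always present.
#'
#' @param scores numeric sclerotic-class scores.
#' @param labels true labels; both classes must be present.
#' @return tibble of class `glom_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_glom_factor(labels)
  pos <- labels == "sclerotic"
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  np <- sum(pos); nn <- sum(!pos)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    sens[i] <- sum(pred & pos) / np
    spec[i] <- sum(!pred & !pos) / nn
  }
  out <- tibble(threshold = ths, sensitivity = sens, specificity = spec,
                fpr = 1 - spec, tpr = sens)
  class(out) <- c("glom_roc", class(out))
  out
}

#' Decision threshold by the imbalance-slope tangent (Approach A)
#'
#' Slides a line of slope `n_negative / n_positive` down from the perfect
#' corner (FPR, TPR) = (0, 1); the first curve point it touches — the point
#' maximizing TPR - slope * FPR — gives the threshold. Ties go to the point
#' with higher sensitivity.
#'
#' @param roc a `glom_roc` tibble.
#' @param n_negative,n_positive class counts defining the slope.
#' @return the selected threshold.
#' @export
threshold_approach_a <- function(roc, n_negative, n_positive) {
  stopifnot(n_negative > 0, n_positive > 0)
  slope <- n_negative / n_positive
  obj <- roc$tpr - slope * roc$fpr
  ord <- order(-obj, -roc$sensitivity)
  roc$threshold[ord[1]]
}

#' Decision threshold by minimum distance to the perfect corner (Approach B)
#'
#' Selects the curve point minimizing
#' sqrt((1 - sensitivity)^2 + (1 - specificity)^2), the Euclidean distance
#' to (FPR, TPR) = (0, 1). Ties go to the point with higher sensitivity.
#'
#' @param roc a `glom_roc` tibble.
#' @return the selected threshold.
#' @export
threshold_approach_b <- function(roc) {
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  ord <- order(d2, -roc$sensitivity)
  roc$threshold[ord[1]]
}

# stratified k-fold assignment (1..k per row), deterministic in seed
stratified_kfold <- function(labels, k, seed) {
  labels <- as_glom_factor(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# stratified validation indicator (~frac of rows, >= 1 per class)
stratified_holdout <- function(labels, frac, seed) {
  labels <- as_glom_factor(labels)
  val <- logical(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2) {
        stop(sprintf("class '%s' has fewer than 2 rows; cannot hold out a validation set", cl),
             call. = FALSE)
      }
      n_val <- max(1L, round(frac * length(idx)))
      n_val <- min(n_val, length(idx) - 1L)
      val[sample(idx, n_val)] <- TRUE
    }
  })
  val
}

#' Train the k-fold shallow-network ensemble
#'
#' Splits the training crops into k stratified folds. For each fold, the
#' other k-1 folds form the training pool, of which a stratified 15% (by
#' default) is held out as the validation part used for early stopping,
#' initialization selection and ROC threshold selection. `inits_per_fold`
#' networks are trained per fold and the one with the best validation MCC is
#' kept; its decision threshold is chosen on the validation scores by ROC
#' Approach B (or A, per `config`). Prediction is by hard majority voting of
#' the k fold networks, ties resolved toward sclerotic.
#'
#' @param data tibble of reduced features with a `label` column (any other
#'   non-numeric columns are ignored).
#' @param k number of folds (default 10).
#' @param config a [network_config()] object.
#' @param seed master integer seed.
#' @param prep optional `glom_prep` bundle stored with the model so that
#'   [predict.glom_ensemble()] can accept raw feature tables.
#' @return object of class `glom_ensemble`.
#' @export
train_ensemble <- function(data, k = 10L, config = network_config(),
                           seed = 1L, prep = NULL) {
  stopifnot(k >= 2)
  labels <- as_glom_factor(data$label)
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "label")
  X <- as.matrix(data[num_cols])
  if (min(table(labels)) < k / 2) {
    warning("very few rows of the minority class; folds may be fragile")
  }
  fold <- stratified_kfold(labels, k, child_seed(seed, "folds"))

  folds <- vector("list", k)
  for (f in seq_len(k)) {
    pool <- which(fold != f)
    y_pool <- labels[pool]
    val <- stratified_holdout(y_pool, config$val_fraction,
                              child_seed(seed, "val", f))
    tr_idx <- pool[!val]; va_idx <- pool[val]
    if (length(unique(as.character(labels[tr_idx]))) < 2) {
      stop("a training fold lost one class entirely", call. = FALSE)
    }
    best <- NULL
    for (init in seq_len(config$inits_per_fold)) {
      net <- train_network(X[tr_idx, , drop = FALSE], labels[tr_idx],
                           X[va_idx, , drop = FALSE], labels[va_idx],
                           config, seed = child_seed(seed, "init", f, init))
      sc <- net_score(net, X[va_idx, , drop = FALSE])
      cm <- confusion_matrix(labels[va_idx],
                             ifelse(sc >= 0.5, "sclerotic", "non_sclerotic"))
      mcc <- classification_metrics(cm)$mcc
      if (is.null(best) || mcc > best$mcc) best <- list(net = net, mcc = mcc,
                                                        scores = sc,
                                                        va_idx = va_idx)
    }
    roc <- roc_curve(best$scores, labels[best$va_idx])
    thr <- if (config$threshold_method == "A") {
      threshold_approach_a(roc, n_negative = sum(labels[best$va_idx] == "non_sclerotic"),
                           n_positive = sum(labels[best$va_idx] == "sclerotic"))
    } else {
      threshold_approach_b(roc)
    }
    thr <- min(max(thr, 0), 1)
    pred <- ifelse(best$scores >= thr, "sclerotic", "non_sclerotic")
    val_mcc <- classification_metrics(
      confusion_matrix(labels[best$va_idx], pred))$mcc
    folds[[f]] <- list(net = best$net, threshold = thr, fold_index = f,
                       validation_mcc = val_mcc)
  }
  structure(
    list(folds = folds, k = as.integer(k), config = config, seed = seed,
         feature_names = num_cols, prep = prep),
    class = "glom_ensemble"
  )
}

#' Predict with the ensemble by hard voting
#'
#' Each fold network votes sclerotic iff its sclerotic-class score reaches
#' its own decision threshold; the final label is the majority vote, with
#' ties resolved toward sclerotic (favouring recall on the disease class).
#'
#' @param object a `glom_ensemble`.
#' @param new_data tibble or matrix of reduced features; if the ensemble
#'   carries a preprocessing bundle, a raw feature table is accepted and
#'   reduced automatically.
#' @param ... unused.
#' @return tibble with `.pred` (factor), `votes_sclerotic` and the per-fold
#'   vote matrix in the `votes` list-column attribute-free form.
#' @export
predict.glom_ensemble <- function(object, new_data, ...) {
  if (!is.null(object$prep) && is.data.frame(new_data) &&
      all(object$prep$features %in% names(new_data))) {
    new_data <- preprocess_transform(new_data, object$prep)
  }
  if (is.data.frame(new_data)) {
    X <- as.matrix(new_data[intersect(object$feature_names, names(new_data))])
  } else {
    X <- as.matrix(new_data)
  }
  if (ncol(X) != length(object$feature_names)) {
    stop(sprintf("input width %d does not match model input width %d",
                 ncol(X), length(object$feature_names)), call. = FALSE)
  }
  votes <- vapply(object$folds, function(fm) {
    net_score(fm$net, X) >= fm$threshold
  }, logical(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  n_pos <- rowSums(votes)
  lab <- ifelse(n_pos >= object$k / 2, "sclerotic", "non_sclerotic")
  out <- tibble(.pred = as_glom_factor(lab), votes_sclerotic = n_pos)
  attr(out, "votes") <- votes
  out
}

#' Hidden-layer size selection by cross-validated mean MCC
#'
#' For each candidate hidden size, trains the full k-fold ensemble and
#' records the mean validation MCC and accuracy across folds; the size with
#' the best mean MCC is selected, ties going to the smaller network.
#'
#' @param data reduced feature tibble with a `label` column.
#' @param sizes integer vector of candidate hidden sizes.
#' @param k folds (default 10).
#' @param config base [network_config()]; its `hidden_size` is overridden.
#' @param seed master seed (fresh derived initialization seeds per
#'   candidate).
#' @return object of class `glom_size_sweep`: `best_size` plus the
#'   (size, mean MCC, mean accuracy) `trace`.
#' @export
select_hidden_size <- function(data, sizes, k = 10L,
                               config = network_config(), seed = 1L) {
  stopifnot(length(sizes) >= 1)
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    cfg <- config
    cfg$hidden_size <- as.integer(sizes[si])
    ens <- train_ensemble(data, k = k, config = cfg,
                          seed = child_seed(seed, "sweep", sizes[si]))
    mccs <- vapply(ens$folds, function(f) f$validation_mcc, numeric(1))
    labels <- as_glom_factor(data$label)
    pred <- predict(ens, data)
    acc <- classification_metrics(
      confusion_matrix(labels, pred$.pred))$accuracy
    rows[[si]] <- tibble(hidden_size = sizes[si], mean_mcc = mean(mccs),
                         mean_accuracy = acc)
  }
  trace <- dplyr::bind_rows(rows)
  structure(list(best_size = pick_best_size(trace), trace = trace),
            class = "glom_size_sweep")
}

# best size = max mean MCC, ties toward the smaller network
pick_best_size <- function(trace) {
  ord <- order(-trace$mean_mcc, trace$hidden_size)
  as.integer(trace$hidden_size[ord[1]])
}

#' @exportS3Method generics::tidy
tidy.glom_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$folds, function(f) {
    tibble(fold = f$fold_index, threshold = f$threshold,
           validation_mcc = f$validation_mcc,
           epochs = f$net$epochs)
  }))
}

#' @exportS3Method generics::glance
glance.glom_ensemble <- function(x, ...) {
  tibble(k = x$k, hidden_size = x$config$hidden_size,
         n_inputs = length(x$feature_names),
         mean_validation_mcc = mean(vapply(x$folds,
                                           function(f) f$validation_mcc,
                                           numeric(1))))
}

#' @exportS3Method generics::tidy
tidy.glom_size_sweep <- function(x, ...) x$trace
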