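make_roc <- function(sens, spec) {
  n <- length(sens)
  structure(
    tibble::tibble(threshold = seq(0.9, 0.1, length.out = n),
                   sensitivity = sens, specificity = spec,
                   fpr = 1 - spec, tpr = sens),
    class = c("glom_roc", class(tibble::tibble()))
  )
}

test_that("the network fits separable blobs perfectly", {
  dat <- blob_data(60, sep = 5, seed = 2)
  X <- as.matrix(dat[, 1:2])
  idx <- rep(c(TRUE, FALSE), length.out = nrow(dat))
  cfg <- network_config(hidden_size = 2, max_epochs = 300)
  net <- train_network(X[idx, ], dat$label[idx], X[!idx, ], dat$label[!idx],
                       cfg, seed = 3)
  sc <- net_score(net, X[idx, ])
  pred <- ifelse(sc >= 0.5, "sclerotic", "non_sclerotic")
  mcc <- classification_metrics(confusion_matrix(dat$label[idx], pred))$mcc
  expect_equal(mcc, 1.0)
})

test_that("training is deterministic and rejects single-class targets", {
  dat <- blob_data(30, seed = 4)
  X <- as.matrix(dat[, 1:2])
  cfg <- network_config(hidden_size = 3, max_epochs = 50)
  n1 <- train_network(X, dat$label, X[1:10, ], dat$label[1:10], cfg, seed = 7)
  n2 <- train_network(X, dat$label, X[1:10, ], dat$label[1:10], cfg, seed = 7)
  expect_identical(n1$par, n2$par)
  expect_error(
    train_network(X[1:30, ], dat$label[1:30], X, dat$label, cfg, seed = 1),
    "single class"
  )
})

test_that("early stopping halts within the window when validation only worsens", {
  # monotone counter as validation loss: no epoch ever improves on epoch 0
  counter <- 0
  fit <- glomclass:::scg_train(
    par0 = rep(0.1, 5),
    fg = function(p) list(loss = sum(p^2), grad = 2 * p),
    val_fn = function(p) { counter <<- counter + 1; counter },
    max_epochs = 1000, window = 6
  )
  expect_lte(fit$epochs, 7)
  # and the returned weights are the pre-deterioration best
  expect_equal(fit$par, rep(0.1, 5))

  # flipped-label validation set worsens as training improves
  dat <- blob_data(40, sep = 4, seed = 9)
  X <- as.matrix(dat[, 1:2])
  flipped <- factor(ifelse(dat$label == "sclerotic", "non_sclerotic",
                           "sclerotic"),
                    levels = levels(dat$label))
  cfg <- network_config(hidden_size = 2, max_epochs = 500)
  net <- train_network(X, dat$label, X, flipped, cfg, seed = 5)
  expect_lt(net$epochs, 500)
})

test_that("ROC curves match brute-force counting and carry both endpoints", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      n <- 30
      scores <- round(runif(n), 2)
      labels <- sample(c("sclerotic", "non_sclerotic"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      roc <- roc_curve(scores, labels)
      pos <- labels == "sclerotic"
      for (i in seq_len(nrow(roc))) {
        pred <- scores >= roc$threshold[i]
        expect_equal(roc$sensitivity[i], sum(pred & pos) / sum(pos))
        expect_equal(roc$specificity[i], sum(!pred & !pos) / sum(!pos))
      }
      expect_true(any(roc$sensitivity == 0 & roc$specificity == 1))
      expect_true(any(roc$sensitivity == 1 & roc$specificity == 0))
      expect_true(all(diff(roc$sensitivity) >= 0))  # rows ordered by falling threshold
    }
  })
  expect_error(roc_curve(runif(5), rep("sclerotic", 5)), "both classes")
})

test_that("perfectly separated scores reach the ideal ROC corner", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c("non_sclerotic", "non_sclerotic", "sclerotic", "sclerotic")
  roc <- roc_curve(scores, labels)
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  # all-identical scores: only degenerate endpoints
  roc2 <- roc_curve(rep(0.5, 4), labels)
  expect_equal(nrow(roc2), 2)
})

test_that("Approach A follows the sliding imbalance line", {
  roc <- make_roc(sens = c(0, 0.9, 0.95, 1), spec = c(1, 0.9, 0.7, 0))
  # balanced slope: objectives 0, 0.8, 0.65, 0 -> the (fpr .1, tpr .9) point
  expect_equal(threshold_approach_a(roc, 10, 10), roc$threshold[2])
  # perfect classifier: the (0, 1) corner wins
  perf <- make_roc(sens = c(0, 1, 1), spec = c(1, 1, 0))
  expect_equal(threshold_approach_a(perf, 5, 5), perf$threshold[2])
  # extreme imbalance: any positive FPR is dominated
  imb <- make_roc(sens = c(0, 0.6, 1), spec = c(1, 1, 0.2))
  expect_equal(threshold_approach_a(imb, 1e6, 1), imb$threshold[2])
})

test_that("Approach B minimizes the distance to the perfect corner", {
  roc <- make_roc(sens = c(0, 0.9, 0.7, 1), spec = c(1, 0.8, 0.95, 0))
  # distances: 1, 0.2236, 0.3041, 1 -> (0.9, 0.8)
  expect_equal(threshold_approach_b(roc), roc$threshold[2])
  perf <- make_roc(sens = c(0, 1, 1), spec = c(1, 1, 0))
  expect_equal(threshold_approach_b(perf), perf$threshold[2])
})

test_that("Approaches A and B agree on a symmetric balanced curve", {
  roc <- make_roc(sens = c(0, 0.6, 0.8, 0.9, 1),
                  spec = c(1, 0.9, 0.8, 0.6, 0))
  expect_equal(threshold_approach_a(roc, 50, 50), threshold_approach_b(roc))
})

test_that("Approach B equals brute-force minimization on random score sets", {
  withr::with_seed(15, {
    for (rep in 1:100) {
      n <- sample(10:40, 1)
      scores <- round(runif(n), sample(1:3, 1))
      labels <- sample(c("sclerotic", "non_sclerotic"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      roc <- roc_curve(scores, labels)
      expect_equal(threshold_approach_b(roc), oracle_threshold_b(scores, labels))
    }
  })
})

test_that("the ensemble trains k fold models with thresholds in [0, 1]", {
  dat <- blob_data(60, d = 3, sep = 4, seed = 20)
  cfg <- network_config(hidden_size = 3, inits_per_fold = 2, max_epochs = 200)
  ens <- train_ensemble(dat, k = 5, config = cfg, seed = 42)
  expect_length(ens$folds, 5)
  thr <- vapply(ens$folds, function(f) f$threshold, numeric(1))
  expect_true(all(thr >= 0 & thr <= 1))
  mccs <- vapply(ens$folds, function(f) f$validation_mcc, numeric(1))
  expect_true(all(mccs >= 0.9))  # separable data
  # determinism
  ens2 <- train_ensemble(dat, k = 5, config = cfg, seed = 42)
  expect_equal(tidy(ens), tidy(ens2))
  expect_identical(ens$folds[[1]]$net$par, ens2$folds[[1]]$net$par)
})

test_that("stratification keeps both classes in every training fold", {
  dat <- blob_data(30, seed = 31)
  fold <- glomclass:::stratified_kfold(dat$label, 5,  seed = 3)
  for (f in 1:5) {
    expect_length(unique(as.character(dat$label[fold != f])), 2)
  }
})

test_that("hard voting majorities and ties resolve as declared", {
  dat <- blob_data(60, d = 2, sep = 5, seed = 25)
  cfg <- network_config(hidden_size = 2, inits_per_fold = 1, max_epochs = 100)
  ens <- train_ensemble(dat, k = 4, config = cfg, seed = 3)
  # force vote patterns by overriding thresholds
  mk <- function(thrs) {
    e <- ens
    for (i in seq_along(e$folds)) e$folds[[i]]$threshold <- thrs[i]
    e
  }
  x <- dat[1, 1:2]  # a non-sclerotic blob point, score near 0
  # all folds forced to vote positive (threshold 0)
  expect_equal(as.character(predict(mk(rep(0, 4)), x)$.pred), "sclerotic")
  # 2 vs 2 tie -> sclerotic
  p <- predict(mk(c(0, 0, 1.1, 1.1)), x)
  expect_equal(p$votes_sclerotic, 2)
  expect_equal(as.character(p$.pred), "sclerotic")
  # 1 vs 3 -> non-sclerotic
  p2 <- predict(mk(c(0, 1.1, 1.1, 1.1)), x)
  expect_equal(as.character(p2$.pred), "non_sclerotic")
  # flipping two votes flips the label
  p3 <- predict(mk(c(0, 0, 0, 1.1)), x)
  expect_equal(as.character(p3$.pred), "sclerotic")
  # prediction invariant to fold order
  e_rev <- ens; e_rev$folds <- rev(e_rev$folds)
  expect_equal(predict(ens, dat)$.pred, predict(e_rev, dat)$.pred)
  expect_error(predict(ens, dat[, 1, drop = FALSE]), "width")
})

test_that("hidden-size selection maximizes mean MCC with smaller-size ties", {
  trace <- tibble::tibble(hidden_size = c(2, 5, 9),
                          mean_mcc = c(0.7, 0.9, 0.9))
  expect_equal(glomclass:::pick_best_size(trace), 5L)
  dat <- blob_data(40, seed = 33)
  cfg <- network_config(hidden_size = 1, inits_per_fold = 1, max_epochs = 100)
  sw <- select_hidden_size(dat, sizes = 3, k = 3, config = cfg, seed = 2)
  expect_equal(sw$best_size, 3L)
})

test_that("XOR-like data needs at least two hidden units", {
  withr::with_seed(44, {
    n <- 40
    cl <- rbind(
      cbind(rnorm(n, 0, 0.15), rnorm(n, 0, 0.15)),
      cbind(rnorm(n, 1, 0.15), rnorm(n, 1, 0.15)),
      cbind(rnorm(n, 0, 0.15), rnorm(n, 1, 0.15)),
      cbind(rnorm(n, 1, 0.15), rnorm(n, 0, 0.15))
    )
    colnames(cl) <- c("f1", "f2")
    dat <- tibble::as_tibble(cl)
    dat$label <- factor(rep(c("sclerotic", "sclerotic", "non_sclerotic",
                              "non_sclerotic"), each = n),
                        levels = c("non_sclerotic", "sclerotic"))
  })
  cfg <- network_config(inits_per_fold = 3, max_epochs = 300)
  sw <- select_hidden_size(dat, sizes = c(1, 4), k = 4, config = cfg,
                           seed = 11)
  expect_gte(sw$best_size, 2)
  expect_gt(sw$trace$mean_mcc[sw$trace$hidden_size == 4],
            sw$trace$mean_mcc[sw$trace$hidden_size == 1])
})
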