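# Shallow feed-forward network: one hidden layer with hyperbolic-tangent
# sigmoid units, 2-unit softmax output, cross-entropy loss, trained
# full-batch by scaled conjugate gradient (Moller 1993) with a
# validation-fail early stop.

#' Training configuration for the shallow network ensemble
#'
#' @param hidden_size number of hidden units (default 27).
#' @param inits_per_fold independent weight initializations per fold; the
#'   one with the best validation MCC is kept (default 5).
#' @param early_stop_window training stops once the validation loss has not
#'   improved for this many consecutive epochs (default 6).
#' @param max_epochs epoch cap (default 1000; early stopping dominates).
#' @param val_fraction fraction of each training fold held out, stratified,
#'   for early stopping and threshold selection (default 0.15).
#' @param threshold_method `"B"` (minimum distance to the perfect corner,
#'   default) or `"A"` (imbalance-slope tangent line).
#' @return a `glom_net_config` list.
#' @export
network_config <- function(hidden_size = 27L, inits_per_fold = 5L,
                           early_stop_window = 6L, max_epochs = 1000L,
                           val_fraction = 0.15,
                           threshold_method = c("B", "A")) {
  stopifnot(hidden_size >= 1, early_stop_window >= 1, inits_per_fold >= 1,
            max_epochs >= 1, val_fraction > 0, val_fraction < 0.5)
  structure(
    list(hidden_size = as.integer(hidden_size),
         inits_per_fold = as.integer(inits_per_fold),
         early_stop_window = as.integer(early_stop_window),
         max_epochs = as.integer(max_epochs),
         val_fraction = val_fraction,
         threshold_method = match.arg(threshold_method)),
    class = "glom_net_config"
  )
}

net_npar <- function(d, h) d * h + h + 2 * h + 2

net_init <- function(d, h, seed) {
  withr::with_seed(seed, {
    c(rnorm(d * h, sd = 1 / sqrt(d)), rep(0, h),
      rnorm(h * 2, sd = 1 / sqrt(h)), rep(0, 2))
  })
}

net_unpack <- function(par, d, h) {
  i <- 0
  W1 <- matrix(par[(i + 1):(i + d * h)], d, h); i <- i + d * h
  b1 <- par[(i + 1):(i + h)]; i <- i + h
  W2 <- matrix(par[(i + 1):(i + 2 * h)], h, 2); i <- i + 2 * h
  b2 <- par[(i + 1):(i + 2)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward <- function(par, X, d, h) {
  w <- net_unpack(par, d, h)
  A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+")
  Z2 <- Z2 - apply(Z2, 1, max)
  E <- exp(Z2)
  P <- E / rowSums(E)
  colnames(P) <- glom_levels()
  list(P = P, A1 = A1)
}

# mean cross-entropy and its gradient, one pass
net_loss_grad <- function(par, X, Y, d, h) {
  w <- net_unpack(par, d, h)
  fw <- net_forward(par, X, d, h)
  n <- nrow(X)
  loss <- -sum(Y * logg(fw$P)) / n
  dZ2 <- (fw$P - Y) / n
  gW2 <- crossprod(fw$A1, dZ2)
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(w$W2)
  dZ1 <- dA1 * (1 - fw$A1^2)
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

net_loss <- function(par, X, Y, d, h) {
  -sum(Y * logg(net_forward(par, X, d, h)$P)) / nrow(X)
}

# one-hot targets in the fixed (non_sclerotic, sclerotic) column order
one_hot <- function(y) {
  y <- as_glom_factor(y)
  cbind(non_sclerotic = as.numeric(y == "non_sclerotic"),
        sclerotic = as.numeric(y == "sclerotic"))
}

# Scaled conjugate gradient with per-epoch validation monitoring.
# One SCG iteration = one epoch; the weights at the best validation epoch
# are returned, and training stops after `window` consecutive epochs
# without a validation improvement.
scg_train <- function(par0, fg, val_fn, max_epochs, window) {
  w <- par0
  E <- fg(w)
  g <- E$grad
  r <- -g
  p <- r
  success <- TRUE
  lambda <- 5e-7; lambdab <- 0
  sigma0 <- 5e-5
  delta <- 0

  best_val <- val_fn(w)
  best_w <- w
  fail <- 0L
  epoch <- 0L
  val_trace <- numeric(0)

  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    p2 <- sum(p * p)
    if (p2 < 1e-24) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      gplus <- fg(w + sigma * p)$grad
      s <- (gplus - g) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambdab) * p2
    if (delta <= 0) {
      lambdab <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdab
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    Enew <- fg(w + alpha * p)
    Delta <- 2 * delta * (E$loss - Enew$loss) / mu^2

    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      gnew <- Enew$grad
      rnew <- -gnew
      lambdab <- 0
      success <- TRUE
      if (epoch %% length(w) == 0) {
        p <- rnew
      } else {
        beta <- (sum(rnew * rnew) - sum(rnew * r)) / mu
        p <- rnew + beta * p
      }
      if (Delta >= 0.75) lambda <- lambda / 4
      r <- rnew
      g <- gnew
      E <- Enew
    } else {
      lambdab <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) {
      lambda <- lambda + delta * (1 - Delta) / p2
    }
    if (!is.finite(lambda) || lambda > 1e15) lambda <- 1e15

    v <- val_fn(w)
    val_trace <- c(val_trace, v)
    if (v < best_val - 1e-12) {
      best_val <- v
      best_w <- w
      fail <- 0L
    } else {
      fail <- fail + 1L
    }
    if (fail >= window) break
    if (success && sqrt(sum(r * r)) < 1e-10) break
  }
  list(par = best_w, epochs = epoch, best_val = best_val,
       val_trace = val_trace)
}

#' Train one shallow network with early stopping
#'
#' Trains the tanh/softmax network on the training rows by scaled conjugate
#' gradient, monitoring the cross-entropy on the validation rows each epoch;
#' training halts once the validation loss has not improved inside the
#' early-stop window, and the weights of the best validation epoch are
#' returned. Deterministic for a fixed `seed`.
#'
#' @param X_train,X_val numeric matrices (rows = crops, columns = reduced
#'   features).
#' @param y_train,y_val labels (`"sclerotic"` / `"non_sclerotic"`).
#' @param config a [network_config()] object.
#' @param seed integer seed for the weight initialization.
#' @return object of class `glom_net`.
#' @export
train_network <- function(X_train, y_train, X_val, y_val,
                          config = network_config(), seed = 1L) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (length(unique(as.character(y_train))) < 2) {
    stop("training targets contain a single class", call. = FALSE)
  }
  d <- ncol(X_train); h <- config$hidden_size
  Y <- one_hot(y_train); Yv <- one_hot(y_val)
  par0 <- net_init(d, h, seed)
  fit <- scg_train(
    par0,
    fg = function(p) net_loss_grad(p, X_train, Y, d, h),
    val_fn = function(p) net_loss(p, X_val, Yv, d, h),
    max_epochs = config$max_epochs,
    window = config$early_stop_window
  )
  structure(list(par = fit$par, d = d, h = h, epochs = fit$epochs,
                 best_val = fit$best_val, val_trace = fit$val_trace,
                 seed = seed),
            class = "glom_net")
}

#' Positive-class (sclerotic) scores of a trained network
#'
#' @param net a `glom_net` object.
#' @param X numeric matrix of reduced features.
#' @return numeric vector of softmax sclerotic-class probabilities.
#' @export
net_score <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$d) {
    stop(sprintf("input width %d does not match network input width %d",
                 ncol(X), net$d), call. = FALSE)
  }
  net_forward(net$par, X, net$d, net$h)$P[, "sclerotic"]
}
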