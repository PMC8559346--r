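#' Confusion matrix with sclerotic as the positive class
#'
#' @param truth true labels.
#' @param estimate predicted labels.
#' @param tp,fp,fn,tn alternatively, supply the four counts directly via
#'   [glom_cm()].
#' @return object of class `glom_cm` holding TP, FP, FN, TN.
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` have different lengths", call. = FALSE)
  }
  truth <- as_glom_factor(truth)
  estimate <- as_glom_factor(estimate)
  pos <- "sclerotic"
  glom_cm(
    tp = sum(truth == pos & estimate == pos),
    fp = sum(truth != pos & estimate == pos),
    fn = sum(truth == pos & estimate != pos),
    tn = sum(truth != pos & estimate != pos)
  )
}

#' @rdname confusion_matrix
#' @export
glom_cm <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "glom_cm")
}

#' @export
print.glom_cm <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("sclerotic", "non_sclerotic"),
                              true = c("sclerotic", "non_sclerotic")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and Matthews correlation coefficient
#'
#' The four standard metrics of a binary confusion matrix with sclerotic as
#' the positive class:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is defined as 0 (the random-predictor
#' value for MCC) and listed in the `"flags"` attribute.
#'
#' @param cm a `glom_cm` object.
#' @return one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `mcc`; attribute `"flags"` names any zero-denominator metrics.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "glom_cm"))
  tp <- as.double(cm$tp); fp <- as.double(cm$fp)
  fn <- as.double(cm$fn); tn <- as.double(cm$tn)
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)

  flags <- character(0)
  accuracy <- (tp + tn) / total
  if (tp + fp > 0) {
    precision <- tp / (tp + fp)
  } else {
    precision <- 0; flags <- c(flags, "precision")
  }
  if (tp + fn > 0) {
    recall <- tp / (tp + fn)
  } else {
    recall <- 0; flags <- c(flags, "recall")
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom > 0) {
    mcc <- (tp * tn - fp * fn) / sqrt(denom)
  } else {
    mcc <- 0; flags <- c(flags, "mcc")
  }
  out <- tibble(accuracy = accuracy, precision = precision,
                recall = recall, mcc = mcc)
  attr(out, "flags") <- flags
  out
}

#' @exportS3Method generics::tidy
tidy.glom_cm <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn))
}

#' @exportS3Method generics::glance
glance.glom_cm <- function(x, ...) {
  classification_metrics(x)
}
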