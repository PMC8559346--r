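# Internal helpers shared across modules.

# Deterministic child seeds: every stochastic step derives its own seed from
# the master seed plus a stream tag, kept inside 32-bit integer range.
child_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483629
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    h <- (h * 48271 + as.double(p) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

# guarded log: 0 * log(0) terms contribute 0
logg <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- log(x[pos])
  out
}

assert_raster <- function(img, arg = "img") {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    stop(sprintf("`%s` must be an H x W x 3 array of 8-bit intensities", arg),
         call. = FALSE)
  }
  invisible(img)
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  if (is.logical(m)) m else matrix(m != 0, nrow(m), ncol(m))
}

# label handling: positive class is "sclerotic" throughout
glom_levels <- function() c("non_sclerotic", "sclerotic")

as_glom_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), glom_levels())
  if (length(bad) > 0) {
    stop("labels must be one of 'sclerotic', 'non_sclerotic'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = glom_levels())
}
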