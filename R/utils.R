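#' @importFrom rlang abort warn %||%
#' @importFrom stats fft rnorm runif predict sd
#' @importFrom utils head read.csv write.csv
NULL

# Canonical class order used everywhere (confusion matrices, weights, colours).
ECG_CLASSES <- c("ARR", "CHF", "NSR")

#' Diagnostic classes recognised by the package
#'
#' @return Character vector `c("ARR", "CHF", "NSR")` in the canonical order
#'   used for factors, confusion matrices and class weights.
#' @export
ecg_classes <- function() ECG_CLASSES

# Derive a child seed from an experiment seed. Keeps results < 2^31 so the
# value is always a valid R integer, and distinct offsets give distinct
# streams for one parent seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

stop_ecg <- function(...) abort(paste0(...), class = "ecgblend_error")

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_ecg(...)
  invisible(TRUE)
}

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ECG_CLASSES)
  assert_that(length(bad) == 0,
              "unknown label(s): ", paste(bad, collapse = ", "),
              " (expected ", paste(ECG_CLASSES, collapse = "/"), ")")
  factor(labels, levels = ECG_CLASSES)
}

# Numerically safe row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

flatten_features <- function(x) as.numeric(x)
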