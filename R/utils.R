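#' @keywords internal
#' @importFrom stats sd rnorm runif quantile qt pt pbinom cor fft
#' @importFrom utils head tail
"_PACKAGE"

#' @useDynLib prestim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a fixed RNG state when `seed` is not NULL, without
# disturbing the caller's RNG stream.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a per-unit (e.g. per-subject) seed from a master seed, staying
# inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_prestim <- function(msg, class) {
  stop(structure(
    class = c(class, "prestim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Closed-interval membership on a numeric axis (ms axes throughout).
in_window <- function(x, window) {
  x >= window[1] & x <= window[2]
}

rating_levels <- function() c("negative", "positive", "neutral", "missed")
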