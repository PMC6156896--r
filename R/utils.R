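## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Clamp values into a closed interval
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` moved to the nearest bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Structured stage logging used by the pipeline; writes to message() so it
## never pollutes result files.
log_stage <- function(stage, ...) {
  kv <- list(...)
  body <- if (length(kv)) {
    paste(sprintf("%s=%s", names(kv), vapply(kv, function(v)
      paste(format(v), collapse = ","), "")), collapse = " ")
  } else ""
  message(sprintf("[hdscan] %s %s", stage, body))
}

## Deterministic seed derivation: keeps child seeds < 2^31 and distinct per tag.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
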