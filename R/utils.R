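#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# RNG stream afterwards so library calls never clobber user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Frame quantization: round a positive duration up to the next whole frame,
# never below one frame (video measurement cannot resolve below one frame).
quantize_up <- function(x, frame) {
  # small backoff so exact frame multiples are not pushed up a frame
  pmax(ceiling(x / frame - 1e-9), 1) * frame
}
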