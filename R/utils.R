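# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead (0.05 -> 0.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a deterministic RNG stream derived from (seed, stream),
# restoring the caller's RNG state afterwards. All package randomness flows
# through this so one root seed yields reproducible, independent sub-streams.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # keep derived seeds inside 32-bit integer range
  derived <- (as.numeric(seed) * 48271 + stream * 9973) %% 2147483647
  set.seed(as.integer(derived))
  force(expr)
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_domain(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}
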