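#' @keywords internal
"_PACKAGE"

## Shared internal helpers.

#' Round half away from zero
#'
#' Integer rounding used for all displayed percentages: .5 always rounds up
#' (base `round()` rounds half to even, which does not match how integer
#' percentages are conventionally reported in tables).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Stop with a classed condition so callers/tests can match on error type.
eq_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "epiquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sample standard deviation, 0 for n = 1 (callers flag n = 1 separately).
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

# Derive a deterministic 32-bit sub-seed from a base seed and a stream index,
# so independent scene components draw from independent streams.
sub_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 1000003) * 2011 + 7919 * as.numeric(stream)) %% 2147480000
}
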