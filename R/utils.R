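#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_ctg <- function(..., class) {
  stop(structure(
    class = c(class, "ctgsurv_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ..., class = "ctgsurv_validation_error") {
  if (!isTRUE(ok)) stop_ctg(..., class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= 1
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Derive a stream of child seeds from one master seed, so that every source
## of randomness in a multi-stage computation gets its own reproducible seed.
## Kept strictly below 2^31 - 1 (R integers are 32-bit).
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
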