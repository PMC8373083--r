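# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage (simulation, design
#' generation, turbulence, per-block designs, ...) gets its own seed through
#' this deterministic map, so any stage can be reproduced in isolation. The
#' result always fits in a 32-bit signed integer.
#'
#' @param seed integer master seed.
#' @param index positive integer stage/block index.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1L, 1)
#' derive_seed(1L, 2)
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index), index >= 1)
  # affine map mod a Mersenne prime; cheap, collision-free for small indexes
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647)
}

# run `code` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stop_dims <- function(what, expected, got) {
  stop(sprintf("%s: expected %s, got %s", what,
               paste(expected, collapse = " x "),
               paste(got, collapse = " x ")), call. = FALSE)
}

as_dense_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# full-precision number formatting for lossless text round-trips
format_full <- function(x) {
  is_int <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out <- sprintf("%.17g", x)
  out[is_int] <- sprintf("%.0f", x[is_int])
  out
}
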