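# Internal utilities: deterministic seed derivation, scoped RNG, small array
# helpers shared across modules.

#' Derive a child seed from a global seed and an operation path
#'
#' Every stochastic operation in the package receives a seed derived
#' deterministically from the global seed and a string naming the operation
#' ("phantom/train", "attack/case-003", ...), so that adding or removing one
#' stage never perturbs the randomness of another.
#'
#' @param seed integer global seed.
#' @param ... character or integer path components.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    for (code in utf8ToInt(p)) {
      h <- (h * 131 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Voxel coordinate grids for a (z, y, x) shape, 0-based indices.
coord_grids <- function(shape) {
  z <- array(rep(seq_len(shape[1]) - 1L, times = shape[2] * shape[3]), dim = shape)
  y <- array(rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), times = shape[3]),
             dim = shape)
  x <- array(rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2]), dim = shape)
  list(z = z, y = y, x = x)
}

assert_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("shape mismatch between %s", what)
  invisible(TRUE)
}
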