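# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483629)
}

abort_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "mdpgcn_input_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared euclidean distances between rows of X[rows, ] and all rows of X.
rowwise_sqdist <- function(X, rows, row_norms = NULL) {
  if (is.null(row_norms)) row_norms <- rowSums(X^2)
  cross <- X[rows, , drop = FALSE] %*% t(X)
  d <- outer(row_norms[rows], row_norms, "+") - 2 * cross
  d[d < 0] <- 0
  d
}

act_fun <- function(name) {
  switch(name,
    relu = function(z) pmax(z, 0),
    identity = function(z) z,
    tanh = tanh,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    abort_input("unknown activation '%s'", name)
  )
}

act_grad <- function(name) {
  switch(name,
    relu = function(z, h) (z > 0) * 1,
    identity = function(z, h) array(1, dim(z)),
    tanh = function(z, h) 1 - h^2,
    sigmoid = function(z, h) h * (1 - h),
    abort_input("unknown activation '%s'", name)
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))
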