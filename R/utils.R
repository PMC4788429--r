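# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

# Coerce a 2D point (length-2 vector) or n x 2 matrix-like to an n x 2 matrix.
as_xy <- function(p, arg = deparse(substitute(p))) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2L)
      stop(sprintf("'%s' must be a 2D point or an n x 2 matrix", arg))
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  if (ncol(p) != 2L)
    stop(sprintf("'%s' must have two columns (x, y)", arg))
  storage.mode(p) <- "double"
  unname(p)
}

# Recycle scalar/vector `x` to length n with a clear error on mismatch.
recycle_to <- function(x, n, arg = deparse(substitute(x))) {
  if (length(x) == 1L) rep(x, n)
  else if (length(x) == n) x
  else stop(sprintf("'%s' must have length 1 or %d", arg, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
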