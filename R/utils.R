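# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629L)
}

# Column-major strides of a voxel grid.
gridStrides <- function(dims) {
  cumprod(c(1L, dims[-length(dims)]))
}

# Row-major rank of each voxel (1-based linear, column-major input order).
# Used to make region identifiers deterministic under the documented
# "first voxel in row-major order" rule.
rowMajorRank <- function(dims) {
  n <- prod(dims)
  coords <- arrayInd(seq_len(n), .dim = dims)
  strides <- rev(cumprod(c(1, rev(dims[-1L]))))
  as.vector((coords - 1L) %*% strides) + 1
}

clampProb <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1)
}

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
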