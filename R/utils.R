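# Internal numerical and RNG helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream; a NULL seed uses the ambient stream unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Squared Euclidean distances from every row of X (n x d) to every row of
# C (k x d), returned as an n x k matrix.  All distance comparisons in the
# package go through this (or the single-point variant below) so that the
# floating-point accumulation order is identical on every code path.
dist2_matrix <- function(X, C) {
  n <- nrow(X)
  k <- nrow(C)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    out[, j] <- rowSums((X - rep(C[j, ], each = n))^2)
  }
  out
}

# Squared distances from one point (length-d vector) to every row of C.
dist2_to_rows <- function(x, C) {
  colSums((t(C) - x)^2)
}

# Row index of the per-row minimum, ties broken to the lowest index.
argmin_rows <- function(d2) {
  max.col(-d2, ties.method = "first")
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
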