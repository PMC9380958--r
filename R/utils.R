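# internal helpers shared across modules

# coerce positions to an N x 3 matrix; remembers if input was a bare vector
as_points <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) abort("a position must have 3 components (x, y, z)")
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) abort("positions must be an N x 3 matrix")
    storage.mode(x) <- "double"
    x
  }
}

# return matrix result in the same shape as the query (vector in, vector out)
shape_like <- function(res, x) {
  if (is.null(dim(x))) drop(res) else res
}

# row-wise cross product of N x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(paste0("`", name, "` must be a finite numeric scalar"))
  if (positive && x <= 0) abort(paste0("`", name, "` must be > 0"))
  if (nonneg && x < 0) abort(paste0("`", name, "` must be >= 0"))
  invisible(x)
}
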