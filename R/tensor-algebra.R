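#' Dense N-way tensor algebra
#'
#' Volumes are plain numeric arrays (a 3D scan is a 3rd-order tensor). The
#' functions here provide the small algebra every model in the package is
#' built from: the Frobenius norm, the entrywise inner product, mode-n
#' unfolding and its inverse, the mode-n product, and rank-one tensors formed
#' as outer products of one vector per mode.
#'
#' Unfolding convention: the mode-n unfolding puts the mode-n fibers as
#' columns, with the remaining modes enumerated in their original
#' (column-major) order. `fold()` is its exact inverse. Every algorithm in
#' the package is invariant to this choice as long as the pair is a
#' bijection.
#'
#' Modes are numbered 1..N as usual in the multilinear-algebra literature;
#' array indexing follows R's 1-based convention.
#'
#' @name tensor-algebra
NULL

stop_if_not_tensor <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric array", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries (NaN/Inf)", arg),
         call. = FALSE)
  }
  invisible(x)
}

tensor_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

#' Frobenius norm of a tensor
#'
#' Square root of the sum of squared entries, the direct generalization of
#' the matrix Frobenius norm.
#'
#' @param x numeric array with finite entries.
#' @return Non-negative scalar.
#' @export
#' @examples
#' tensor_norm(array(1, c(2, 2)))  # 2
tensor_norm <- function(x) {
  stop_if_not_tensor(x)
  sqrt(sum(x^2))
}

#' Inner product of two same-shaped tensors
#'
#' Sum of the products of corresponding entries; \code{tensor_inner(x, x)}
#' equals \code{tensor_norm(x)^2}.
#'
#' @param x,y numeric arrays of identical shape.
#' @return Scalar.
#' @export
tensor_inner <- function(x, y) {
  stop_if_not_tensor(x)
  stop_if_not_tensor(y)
  if (!identical(tensor_dim(x), tensor_dim(y))) {
    stop("tensors must have identical shapes", call. = FALSE)
  }
  sum(x * y)
}

#' Mode-n unfolding of a tensor
#'
#' Returns the matrix whose columns are the mode-n fibers of `x` (shape
#' `I_n` by the product of the remaining mode sizes).
#'
#' @param x numeric array.
#' @param mode integer in 1..N.
#' @return A matrix.
#' @seealso [fold()]
#' @export
unfold <- function(x, mode) {
  d <- tensor_dim(x)
  n <- length(d)
  if (length(mode) != 1L || mode < 1L || mode > n) {
    stop(sprintf("`mode` must be a single integer in 1..%d", n),
         call. = FALSE)
  }
  if (n == 1L) return(matrix(x, nrow = d[1L]))
  perm <- c(mode, seq_len(n)[-mode])
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Fold a mode-n unfolding back into a tensor
#'
#' Exact inverse of [unfold()]: `fold(unfold(x, m), m, dim(x))` returns `x`.
#'
#' @param m matrix produced by (or shaped like) a mode-`mode` unfolding.
#' @param mode integer in 1..N.
#' @param dims target tensor shape.
#' @return A numeric array of shape `dims`.
#' @export
fold <- function(m, mode, dims) {
  n <- length(dims)
  if (length(mode) != 1L || mode < 1L || mode > n) {
    stop(sprintf("`mode` must be a single integer in 1..%d", n),
         call. = FALSE)
  }
  if (nrow(m) != dims[mode] || ncol(m) != prod(dims[-mode])) {
    stop("matrix shape inconsistent with `dims` and `mode`", call. = FALSE)
  }
  perm <- c(mode, seq_len(n)[-mode])
  aperm(array(as.numeric(m), dims[perm]), order(perm))
}

#' Mode-n product of a tensor with a matrix
#'
#' Multiplies every mode-n fiber of `x` by `m`, replacing the mode-n size by
#' `nrow(m)`. A plain vector is interpreted as a single-row matrix, so
#' contracting a unit vector against its own mode collapses that mode to
#' size 1 (the coefficient contraction used by the coding step).
#'
#' @param x numeric array.
#' @param m matrix with `ncol(m) == dim(x)[mode]`, or a vector of that
#'   length.
#' @param mode integer in 1..N.
#' @return Numeric array with mode-`mode` size `nrow(m)`.
#' @export
ttm <- function(x, m, mode) {
  d <- tensor_dim(x)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (ncol(m) != d[mode]) {
    stop(sprintf("ncol(m) = %d does not match mode-%d size %d",
                 ncol(m), mode, d[mode]), call. = FALSE)
  }
  new_dims <- d
  new_dims[mode] <- nrow(m)
  fold(m %*% unfold(x, mode), mode, new_dims)
}

#' Construct a rank-one basis from per-mode factor vectors
#'
#' A rank-one basis is a list of N unit-norm vectors, one per mode, whose
#' outer product is a unit-norm basis tensor. Unit norm is enforced so that
#' all magnitude lives in the coefficients.
#'
#' @param factors list of N >= 2 numeric vectors, each with unit Euclidean
#'   norm.
#' @return An object of class `rank_one_basis`.
#' @export
rank_one_basis <- function(factors) {
  if (!is.list(factors) || length(factors) < 2L) {
    stop("`factors` must be a list of at least two vectors", call. = FALSE)
  }
  for (k in seq_along(factors)) {
    v <- factors[[k]]
    if (!is.numeric(v) || length(v) == 0L || !all(is.finite(v))) {
      stop(sprintf("factor %d must be a non-empty finite numeric vector", k),
           call. = FALSE)
    }
    nrm <- sqrt(sum(v^2))
    if (abs(nrm - 1) > 1e-8) {
      stop(sprintf("factor %d must have unit norm (got %.6g)", k, nrm),
           call. = FALSE)
    }
  }
  structure(list(factors = factors), class = "rank_one_basis")
}

#' Outer product of per-mode vectors as a dense tensor
#'
#' The entry at multi-index (i1, ..., iN) is the product of the
#' corresponding factor entries. With unit-norm factors the resulting
#' tensor has Frobenius norm one.
#'
#' @param b a `rank_one_basis`, or a bare list of factor vectors.
#' @return Numeric array of shape `(length(f1), ..., length(fN))`.
#' @export
rank_one_tensor <- function(b) {
  factors <- if (inherits(b, "rank_one_basis")) b$factors else b
  if (!is.list(factors) || length(factors) == 0L) {
    stop("`b` must be a rank_one_basis or non-empty list of vectors",
         call. = FALSE)
  }
  if (any(vapply(factors, length, 1L) == 0L)) {
    stop("factors must be non-empty", call. = FALSE)
  }
  out <- factors[[1L]]
  for (k in seq_along(factors)[-1L]) {
    out <- outer(out, factors[[k]])
  }
  array(out, vapply(factors, length, 1L))
}

# Deterministic sign for an eigen/factor vector: make the largest-magnitude
# entry positive (first such entry on ties). Keeps decompositions
# reproducible across linear-algebra backends.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Check a stack of samples: non-empty list of same-shape finite arrays.
check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty list of numeric arrays",
         call. = FALSE)
  }
  d <- tensor_dim(samples[[1L]])
  for (i in seq_along(samples)) {
    stop_if_not_tensor(samples[[i]], sprintf("samples[[%d]]", i))
    if (!identical(tensor_dim(samples[[i]]), d)) {
      stop(sprintf("samples[[%d]] has shape (%s); expected (%s)",
                   i, paste(tensor_dim(samples[[i]]), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
    }
  }
  d
}

# Ensemble mean of a sample list.
sample_mean <- function(samples) {
  Reduce(`+`, samples) / length(samples)
}
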