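#' Linear tensor coding: greedy rank-one decomposition of a volume ensemble
#'
#' Represents every sample in an ensemble of same-shape volumes as the mean
#' texture plus a linear combination of shared unit-norm rank-one basis
#' tensors. Bases are extracted greedily: at each step the dominant
#' rank-(1,...,1) multilinear component of the current residuals is fitted
#' (the leading per-mode eigenvector iteration of [fit_gndpca()]), each
#' sample's coefficient along the new basis is the inner product of its
#' residual with the basis tensor, and the coefficient-weighted basis is
#' deflated from every residual before the next step. Extraction stops when
#' the sum over samples of residual norms drops to the threshold, or when
#' `max_bases` bases have been extracted. With a single basis the model
#' coincides with rank-(1,...,1) GND-PCA.
#'
#' The stopping rule compares `sum_i ||residual_i||` against `threshold_r`;
#' with `relative = TRUE` the sum is divided by the same quantity for the
#' centered input, which is the scale-free form most convenient in practice.
#'
#' @param samples list of same-shape numeric arrays.
#' @param max_bases maximum number of bases to extract (default 1200, the
#'   basis budget used for full-resolution liver volumes; toy problems use
#'   far fewer).
#' @param threshold_r stop once the (relative) sum of residual norms is
#'   `<=` this value.
#' @param relative interpret `threshold_r` relative to the centered input
#'   norm sum.
#' @param subtract_mean subtract the ensemble mean first (disable only for
#'   algebra-level checks).
#' @param tol,max_sweeps convergence controls for the inner rank-one
#'   eigen-iteration.
#' @return An object of class `ltc`: `mean`, `bases` (list of per-mode unit
#'   factor-vector lists), `coefficients` (samples x bases matrix),
#'   `residual_trace` (sum of residual norms before any basis and after each
#'   one), `threshold`, `relative`, `shape`.
#' @seealso [encode()], [decode()], [reconstruction_quality()]
#' @export
fit_ltc <- function(samples, max_bases = 1200L, threshold_r = 0,
                    relative = FALSE, subtract_mean = TRUE,
                    tol = 1e-9, max_sweeps = 50L) {
  d <- check_samples(samples)
  max_bases <- as.integer(max_bases)
  if (max_bases < 1L) stop("`max_bases` must be >= 1", call. = FALSE)
  if (threshold_r < 0) stop("`threshold_r` must be >= 0", call. = FALSE)

  m <- length(samples)
  mean_tensor <- if (subtract_mean) sample_mean(samples) else array(0, d)
  residuals <- lapply(samples, function(s) s - mean_tensor)

  norm_sum <- function(rs) sum(vapply(rs, tensor_norm, 0))
  initial <- norm_sum(residuals)
  scale <- if (relative) max(initial, .Machine$double.xmin) else 1
  trace <- initial

  bases <- list()
  coefs <- NULL
  # below this the residuals are rounding noise; further bases are meaningless
  eps_floor <- 1e-12 * max(initial, 1)

  for (j in seq_len(max_bases)) {
    total <- utils::tail(trace, 1L)
    if (total / scale <= threshold_r || total <= eps_floor) break

    unit <- fit_gndpca(residuals, core_ranks = rep(1L, length(d)),
                       max_sweeps = max_sweeps, tol = tol,
                       subtract_mean = FALSE)
    factors <- lapply(unit$factors, function(u) fix_sign(as.numeric(u)))
    basis <- rank_one_tensor(factors)

    c_j <- vapply(residuals, function(r) tensor_inner(r, basis), 0)
    residuals <- lapply(seq_len(m), function(i) residuals[[i]] - c_j[i] * basis)

    bases[[length(bases) + 1L]] <- factors
    coefs <- cbind(coefs, c_j)
    trace <- c(trace, norm_sum(residuals))
  }

  if (length(bases) == 0L) {
    coefs <- matrix(numeric(0), nrow = m, ncol = 0L)
  }
  dimnames(coefs) <- NULL

  structure(list(mean = mean_tensor, bases = bases, coefficients = coefs,
                 residual_trace = trace, threshold = threshold_r,
                 relative = relative, shape = d),
            class = "ltc")
}

n_bases <- function(model) length(model$bases)

basis_tensor <- function(model, j) rank_one_tensor(model$bases[[j]])

#' Encode a volume as coefficients over the learned bases
#'
#' Sequential greedy coding: subtract the model mean, then for each basis in
#' turn take the inner product of the current residual with the basis tensor
#' and deflate. Because the bases need not be mutually orthogonal, the
#' sequential order matters and matches the order used during fitting; for
#' a training sample the result reproduces its row of `model$coefficients`.
#'
#' @param model an `ltc` model.
#' @param sample numeric array with the model's shape.
#' @param n_use number of leading bases to use (default: all).
#' @return Numeric coefficient vector of length `n_use`.
#' @export
encode <- function(model, sample, n_use = NULL) {
  stopifnot(inherits(model, "ltc"))
  stop_if_not_tensor(sample)
  if (!identical(tensor_dim(sample), model$shape)) {
    stop("sample shape does not match the model", call. = FALSE)
  }
  j_max <- n_bases(model)
  if (is.null(n_use)) n_use <- j_max
  if (n_use < 1L || n_use > j_max) {
    stop(sprintf("`n_use` must be in 1..%d", j_max), call. = FALSE)
  }
  res <- sample - model$mean
  coefs <- numeric(n_use)
  for (j in seq_len(n_use)) {
    b <- basis_tensor(model, j)
    coefs[j] <- tensor_inner(res, b)
    res <- res - coefs[j] * b
  }
  coefs
}

#' Decode coefficients back into a volume
#'
#' Returns the mean texture plus the coefficient-weighted sum of basis
#' tensors.
#'
#' @param model an `ltc` model.
#' @param coefs numeric vector with at most as many entries as the model has
#'   bases; entry j weights basis j.
#' @return Numeric array with the model's shape.
#' @export
decode <- function(model, coefs) {
  stopifnot(inherits(model, "ltc"))
  if (length(coefs) > n_bases(model)) {
    stop(sprintf("%d coefficients supplied but the model has %d bases",
                 length(coefs), n_bases(model)), call. = FALSE)
  }
  out <- model$mean
  for (j in seq_along(coefs)) {
    if (coefs[j] != 0) out <- out + coefs[j] * basis_tensor(model, j)
  }
  out
}

#' Reconstruction fidelity versus number of bases
#'
#' For each basis count in `grid`, encodes every sample with that many
#' leading bases, reconstructs it, and reports the normalized correlation
#' `<orig, recon> / (||orig|| * ||recon||)` averaged over samples. On
#' training data the curve is non-decreasing in the basis count and
#' approaches 1 as the residual vanishes.
#'
#' @param model an `ltc` model.
#' @param samples list of same-shape arrays to evaluate on.
#' @param grid integer vector of basis counts (0 allowed: mean only).
#' @return A data.frame with columns `n_bases` and `correlation`.
#' @export
reconstruction_quality <- function(model, samples, grid) {
  stopifnot(inherits(model, "ltc"))
  check_samples(samples)
  grid <- as.integer(grid)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid < 0L) || any(grid > n_bases(model))) {
    stop(sprintf("grid entries must be in 0..%d", n_bases(model)),
         call. = FALSE)
  }
  n_max <- max(grid)
  corr <- matrix(NA_real_, length(samples), length(grid))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    coefs <- if (n_max > 0L) encode(model, s, n_max) else numeric(0)
    for (g in seq_along(grid)) {
      recon <- decode(model, coefs[seq_len(grid[g])])
      corr[i, g] <- tensor_inner(s, recon) /
        (tensor_norm(s) * tensor_norm(recon))
    }
  }
  data.frame(n_bases = grid, correlation = colMeans(corr))
}

#' @export
print.ltc <- function(x, ...) {
  tr <- x$residual_trace
  cat(sprintf("Linear tensor coding model: shape (%s), %d basis/bases\n",
              paste(x$shape, collapse = "x"), n_bases(x)))
  cat(sprintf("  residual norm sum: %.6g -> %.6g (%d sample(s))\n",
              tr[1L], utils::tail(tr, 1L), nrow(x$coefficients)))
  invisible(x)
}
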