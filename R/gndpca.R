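#' Generalized N-dimensional PCA (shared Tucker subspace model)
#'
#' Fits one orthonormal factor matrix per mode, shared across an ensemble of
#' same-shape tensors, so that each centered sample is approximated by a
#' small core tensor multiplied by the factors on every mode. The factors
#' are found by alternating per-mode eigendecompositions: with all other
#' modes fixed, the optimal mode-n factor consists of the leading
#' eigenvectors of the accumulated covariance of the partially projected
#' samples, so each update can only increase the captured energy.
#'
#' @param samples list of same-shape numeric arrays (one per subject).
#' @param core_ranks integer vector, one retained rank per mode
#'   (`1 <= J_n <= I_n`).
#' @param max_sweeps maximum number of full passes over the modes.
#' @param tol relative change in the captured-energy objective below which
#'   iteration stops.
#' @param subtract_mean subtract the ensemble mean before fitting (the model
#'   assumes zero-mean data; disable only for algebra-level checks).
#' @return An object of class `gndpca` with elements `factors` (list of
#'   per-mode orthonormal matrices), `core_ranks`, `mean`, `shape`,
#'   `converged`, `sweeps`, and `objective_trace` (captured energy after
#'   each sweep, non-decreasing).
#' @seealso [project_core()], [reconstruct()], [fit_ltc()]
#' @export
fit_gndpca <- function(samples, core_ranks, max_sweeps = 50L, tol = 1e-9,
                       subtract_mean = TRUE) {
  d <- check_samples(samples)
  n_modes <- length(d)
  core_ranks <- as.integer(core_ranks)
  if (length(core_ranks) != n_modes) {
    stop(sprintf("`core_ranks` must have %d entries (one per mode)",
                 n_modes), call. = FALSE)
  }
  if (any(core_ranks < 1L) || any(core_ranks > d)) {
    stop(sprintf("core ranks must satisfy 1 <= J_n <= I_n = (%s)",
                 paste(d, collapse = ", ")), call. = FALSE)
  }
  if (max_sweeps < 1L) stop("`max_sweeps` must be >= 1", call. = FALSE)

  mean_tensor <- if (subtract_mean) sample_mean(samples) else array(0, d)
  centered <- lapply(samples, function(s) s - mean_tensor)

  # HOSVD-style init: leading eigenvectors of each mode's raw covariance.
  factors <- vector("list", n_modes)
  for (n in seq_len(n_modes)) {
    cov_n <- matrix(0, d[n], d[n])
    for (s in centered) {
      u <- unfold(s, n)
      cov_n <- cov_n + tcrossprod(u)
    }
    factors[[n]] <- leading_eigvecs(cov_n, core_ranks[n])
  }

  objective <- function() {
    sum(vapply(centered, function(s) {
      core <- s
      for (n in seq_len(n_modes)) core <- ttm(core, t(factors[[n]]), n)
      sum(core^2)
    }, 0))
  }

  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(max_sweeps)) {
    for (n in seq_len(n_modes)) {
      cov_n <- matrix(0, d[n], d[n])
      for (s in centered) {
        proj <- s
        for (k in seq_len(n_modes)[-n]) proj <- ttm(proj, t(factors[[k]]), k)
        u <- unfold(proj, n)
        cov_n <- cov_n + tcrossprod(u)
      }
      factors[[n]] <- leading_eigvecs(cov_n, core_ranks[n])
    }
    sweeps <- sweep
    obj <- objective()
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(obj - prev) <= tol * max(abs(prev), 1e-300)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }

  structure(list(factors = factors, core_ranks = core_ranks,
                 mean = mean_tensor, shape = d, converged = converged,
                 sweeps = sweeps, objective_trace = trace),
            class = "gndpca")
}

# Top-k eigenvectors of a symmetric PSD matrix, each with a deterministic
# sign (largest-magnitude entry positive).
leading_eigvecs <- function(s, k) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  apply(v, 2L, fix_sign)
}

#' Project a sample onto a fitted multilinear subspace
#'
#' Subtracts the model mean and contracts the sample with the transposed
#' factor on every mode, yielding the sample's core tensor.
#'
#' @param model a `gndpca` model.
#' @param sample numeric array with the model's shape.
#' @return Core tensor of shape `core_ranks`.
#' @export
project_core <- function(model, sample) {
  stopifnot(inherits(model, "gndpca"))
  stop_if_not_tensor(sample)
  if (!identical(tensor_dim(sample), model$shape)) {
    stop("sample shape does not match the model", call. = FALSE)
  }
  core <- sample - model$mean
  for (n in seq_along(model$factors)) core <- ttm(core, t(model$factors[[n]]), n)
  core
}

#' Reconstruct a volume from a core tensor
#'
#' Multiplies the core by the factor on every mode and adds back the model
#' mean.
#'
#' @param model a `gndpca` model.
#' @param core array of shape `core_ranks` (e.g. from [project_core()]).
#' @return Numeric array with the model's shape.
#' @export
reconstruct <- function(model, core) {
  stopifnot(inherits(model, "gndpca"))
  if (!identical(tensor_dim(core), as.integer(model$core_ranks)) &&
      !identical(as.numeric(tensor_dim(core)), as.numeric(model$core_ranks))) {
    stop("core shape does not match the model's core ranks", call. = FALSE)
  }
  out <- core
  for (n in seq_along(model$factors)) out <- ttm(out, model$factors[[n]], n)
  out + model$mean
}

#' @export
print.gndpca <- function(x, ...) {
  cat(sprintf("GND-PCA model: shape (%s), core ranks (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(x$core_ranks, collapse = "x")))
  cat(sprintf("  %d sweep(s), converged: %s, captured energy %.6g\n",
              x$sweeps, x$converged, utils::tail(x$objective_trace, 1)))
  invisible(x)
}
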