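#' Coefficient statistics of a fitted coding model
#'
#' Treats the per-basis training coefficients as Gaussian and estimates, for
#' each basis k, the sample mean `m_k` and sample standard deviation
#' `lambda_k` (n-1 denominator) of the coefficient column. These drive the
#' texture-synthesis sweep in [synthesize_volume()].
#'
#' @param x an `ltc` model, or a plain coefficient matrix (samples in rows).
#' @return An object of class `coef_stats` with numeric vectors `mean` and
#'   `sd`, one entry per basis.
#' @export
coefficient_stats <- function(x) {
  coefs <- if (inherits(x, "ltc")) x$coefficients else as.matrix(x)
  if (!is.numeric(coefs) || ncol(coefs) < 1L) {
    stop("no coefficient columns to summarize", call. = FALSE)
  }
  if (nrow(coefs) < 2L) {
    stop(paste("at least two samples are needed to estimate a coefficient",
               "standard deviation; fit the model on more samples"),
         call. = FALSE)
  }
  structure(list(mean = colMeans(coefs), sd = apply(coefs, 2L, stats::sd)),
            class = "coef_stats")
}

#' Synthesize a novel volume by sweeping one basis coefficient
#'
#' Builds `mean + c_tilde * basis_k`: moving a single coefficient away from
#' its training mean changes intensity only on the (separable) support of
#' that basis, which is how the model renders localized texture variation.
#' The coefficient is expected to stay within two standard deviations of the
#' sweep center -- beyond that the output no longer resembles the training
#' population; by default out-of-range values are clamped with a warning.
#'
#' @param model an `ltc` model.
#' @param stats `coef_stats` from [coefficient_stats()].
#' @param basis_index which basis to sweep (1-based).
#' @param c_tilde the coefficient value.
#' @param center `"mean"` centers the admissible band at the training mean
#'   `m_k` (the default; after mean-centering the training coefficients, the
#'   two choices coincide in expectation); `"zero"` centers it at 0.
#' @param strict error instead of clamping when `c_tilde` leaves the
#'   `+/- 2 lambda_k` band.
#' @return Numeric array with the model's shape.
#' @export
synthesize_volume <- function(model, stats, basis_index, c_tilde,
                              center = c("mean", "zero"), strict = FALSE) {
  stopifnot(inherits(model, "ltc"), inherits(stats, "coef_stats"))
  center <- match.arg(center)
  j <- as.integer(basis_index)
  if (j < 1L || j > n_bases(model)) {
    stop(sprintf("`basis_index` must be in 1..%d", n_bases(model)),
         call. = FALSE)
  }
  mid <- if (center == "mean") stats$mean[j] else 0
  lam <- stats$sd[j]
  if (abs(c_tilde - mid) > 2 * lam) {
    if (strict) {
      stop(sprintf("c_tilde = %.4g lies outside the +/-2*lambda band [%.4g, %.4g]",
                   c_tilde, mid - 2 * lam, mid + 2 * lam), call. = FALSE)
    }
    warning("c_tilde outside +/-2*lambda band; clamped", call. = FALSE)
    c_tilde <- mid + sign(c_tilde - mid) * 2 * lam
  }
  model$mean + c_tilde * basis_tensor(model, j)
}

#' Sweep a basis coefficient across multiples of its standard deviation
#'
#' Convenience wrapper producing the family of volumes at
#' `c_tilde = m_k + multiple * lambda_k` (default multiples -1.5, 0, 1.5,
#' the range that makes the basis's local effect visible while staying well
#' inside the plausible band).
#'
#' @inheritParams synthesize_volume
#' @param multiples numeric vector of standard-deviation multiples.
#' @return Named list of volumes, one per multiple.
#' @export
synthesis_sweep <- function(model, stats, basis_index,
                            multiples = c(-1.5, 0, 1.5),
                            center = c("mean", "zero")) {
  center <- match.arg(center)
  j <- as.integer(basis_index)
  mid <- if (center == "mean") stats$mean[j] else 0
  out <- lapply(multiples, function(a) {
    synthesize_volume(model, stats, j, mid + a * stats$sd[j], center = center)
  })
  names(out) <- sprintf("%+.2flambda", multiples)
  out
}

#' Extract the middle frontal slice of a volume
#'
#' Fixes the last mode at its middle index; handy for inspecting synthesized
#' 3D textures as 2D images.
#'
#' @param volume 3rd-order numeric array.
#' @return A matrix.
#' @export
mid_slice <- function(volume) {
  d <- tensor_dim(volume)
  if (length(d) != 3L) stop("`volume` must be a 3rd-order array", call. = FALSE)
  volume[, , ceiling(d[3L] / 2)]
}
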