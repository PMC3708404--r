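# Brute-force oracles, kept deliberately naive (explicit loops over
# multi-indices) and independent of the package's aperm-based fast paths.

random_tensor <- function(shape) {
  array(stats::rnorm(prod(shape)), shape)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

random_unit_factors <- function(shape) {
  lapply(shape, function(s) unit_vec(stats::rnorm(s)))
}

# mode-n unfolding by enumerating fibers one entry at a time
oracle_unfold <- function(x, mode) {
  d <- dim(x)
  rest <- seq_along(d)[-mode]
  grid <- expand.grid(lapply(d[rest], seq_len))
  out <- matrix(0, d[mode], nrow(grid))
  for (j in seq_len(nrow(grid))) {
    for (i in seq_len(d[mode])) {
      idx <- integer(length(d))
      idx[mode] <- i
      idx[rest] <- as.integer(grid[j, ])
      out[i, j] <- x[matrix(idx, 1L)]
    }
  }
  out
}

# mode-n product by explicit summation at every output index
oracle_ttm <- function(x, m, mode) {
  d <- dim(x)
  nd <- d
  nd[mode] <- nrow(m)
  out <- array(0, nd)
  grid <- expand.grid(lapply(nd, seq_len))
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    acc <- 0
    for (t in seq_len(d[mode])) {
      src <- idx
      src[mode] <- t
      acc <- acc + m[idx[mode], t] * x[matrix(src, 1L)]
    }
    out[matrix(idx, 1L)] <- acc
  }
  out
}

# outer product by looping over every multi-index
oracle_rank_one <- function(factors) {
  d <- vapply(factors, length, 1L)
  out <- array(0, d)
  grid <- expand.grid(lapply(d, seq_len))
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    p <- 1
    for (n in seq_along(factors)) p <- p * factors[[n]][idx[n]]
    out[matrix(idx, 1L)] <- p
  }
  out
}

# sine of the largest principal angle between the column spaces of a and b
max_principal_angle_sin <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  resid <- qa - qb %*% crossprod(qb, qa)
  max(svd(resid, nu = 0, nv = 0)$d)
}

# samples drawn from a planted Tucker model: shared orthonormal factors,
# random cores
tucker_samples <- function(shape, ranks, m) {
  factors <- lapply(seq_along(shape), function(n) {
    qr.Q(qr(matrix(stats::rnorm(shape[n] * ranks[n]), shape[n], ranks[n])))
  })
  samples <- lapply(seq_len(m), function(i) {
    s <- array(stats::rnorm(prod(ranks)), ranks)
    for (n in seq_along(shape)) s <- ttm(s, factors[[n]], n)
    s
  })
  list(samples = samples, factors = factors)
}
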