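test_that("a single exact rank-one sample is coded with one basis", {
  set.seed(7)
  f <- random_unit_factors(c(6, 5, 4))
  k <- 4.2
  mod <- fit_ltc(list(k * rank_one_tensor(f)), max_bases = 5,
                 subtract_mean = FALSE)
  expect_equal(length(mod$bases), 1L)
  for (n in 1:3) {
    expect_equal(abs(sum(mod$bases[[1]][[n]] * f[[n]])), 1,
                 tolerance = 1e-10)
  }
  expect_equal(abs(mod$coefficients[1, 1]), k, tolerance = 1e-10)
  expect_lt(utils::tail(mod$residual_trace, 1), 1e-10)
})

test_that("planted orthogonal rank-one structure is recovered exactly", {
  spec <- synth_spec(shape = c(10, 9, 8), n_samples = 12,
                     n_shared_bases = 3, n_class_bases = 0,
                     noise_sigma = 0, seed = 11)
  gen <- generate_ensemble(spec)
  mod <- fit_ltc(gen$samples, max_bases = 6)
  expect_lte(length(mod$bases), 4L)  # noise-floor truncation after recovery
  expect_lt(mod$residual_trace[4] / mod$residual_trace[1], 1e-8)
  # every recovered basis matches some planted basis up to sign
  planted <- lapply(gen$truth$bases, rank_one_tensor)
  for (j in 1:3) {
    b <- rank_one_tensor(mod$bases[[j]])
    best <- max(vapply(planted, function(p) abs(tensor_inner(p, b)), 0))
    expect_gt(best, 1 - 1e-8)
  }
})

test_that("deflation obeys the per-step Pythagoras identity", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 6, n_shared_bases = 3,
                     n_class_bases = 0, noise_sigma = 0.5, seed = 13)
  gen <- generate_ensemble(spec)
  mod <- fit_ltc(gen$samples, max_bases = 4)
  for (i in seq_along(gen$samples)) {
    res <- gen$samples[[i]] - mod$mean
    for (j in seq_along(mod$bases)) {
      b <- rank_one_tensor(mod$bases[[j]])
      cij <- tensor_inner(res, b)
      # the stored coefficient is the residual/basis inner product
      expect_equal(cij, mod$coefficients[i, j], tolerance = 1e-10)
      # and equals the chain of unit-vector mode products
      chain <- res
      for (n in 1:3) chain <- ttm(chain, mod$bases[[j]][[n]], n)
      expect_equal(as.numeric(chain), cij, tolerance = 1e-10)
      nxt <- res - cij * b
      expect_equal(tensor_norm(res)^2, cij^2 + tensor_norm(nxt)^2,
                   tolerance = 1e-8)
      res <- nxt
    }
  }
  # summed residual norms never increase
  expect_true(all(diff(mod$residual_trace) <= 1e-10))
})

test_that("one-basis coding coincides with rank-(1,1,1) GND-PCA", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 10,
                     n_shared_bases = 4, seed = 17)
  gen <- generate_ensemble(spec)
  ltc1 <- fit_ltc(gen$samples, max_bases = 1)
  gnd1 <- fit_gndpca(gen$samples, c(1, 1, 1))
  for (i in seq_along(gen$samples)) {
    r_ltc <- decode(ltc1, ltc1$coefficients[i, ])
    r_gnd <- reconstruct(gnd1, project_core(gnd1, gen$samples[[i]]))
    expect_equal(r_ltc, r_gnd, tolerance = 1e-10)
  }
})

test_that("encoding reproduces training rows and handles new volumes", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 8, n_shared_bases = 4,
                     n_class_bases = 0, noise_sigma = 0.2, seed = 19)
  gen <- generate_ensemble(spec)
  mod <- fit_ltc(gen$samples, max_bases = 4)
  for (i in seq_along(gen$samples)) {
    expect_equal(encode(mod, gen$samples[[i]]), mod$coefficients[i, ],
                 tolerance = 1e-12)
  }
  # the mean itself encodes to zero
  expect_equal(encode(mod, mod$mean), numeric(length(mod$bases)),
               tolerance = 1e-12)
  # a volume displaced along one basis: sequential deflation oracle
  probe <- mod$mean + 2.5 * rank_one_tensor(mod$bases[[2]])
  got <- encode(mod, probe)
  res <- probe - mod$mean
  want <- numeric(length(mod$bases))
  for (j in seq_along(want)) {
    b <- rank_one_tensor(mod$bases[[j]])
    want[j] <- tensor_inner(res, b)
    res <- res - want[j] * b
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(encode(mod, random_tensor(c(8, 7, 5))), "shape")
})

test_that("decoding is linear in the coefficients", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 6,
                     n_shared_bases = 4, seed = 23)
  gen <- generate_ensemble(spec)
  mod <- fit_ltc(gen$samples, max_bases = 3)
  expect_equal(decode(mod, numeric(0)), mod$mean)
  expect_equal(decode(mod, c(1)),
               mod$mean + rank_one_tensor(mod$bases[[1]]), tolerance = 1e-12)
  # full-coefficient decode reproduces a training sample up to its residual
  i <- 2
  recon <- decode(mod, mod$coefficients[i, ])
  expect_lte(tensor_norm(gen$samples[[i]] - recon),
             utils::tail(mod$residual_trace, 1) + 1e-8)
  expect_error(decode(mod, rep(0, 10)), "bases")
})

test_that("reconstruction quality rises with the basis count", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 10, n_shared_bases = 4,
                     n_class_bases = 0, noise_sigma = 0.3, seed = 29)
  gen <- generate_ensemble(spec)
  mod <- fit_ltc(gen$samples, max_bases = 4)
  curve <- reconstruction_quality(mod, gen$samples, 0:4)
  expect_true(all(diff(curve$correlation) >= -1e-12))
  expect_true(all(curve$correlation >= -1 & curve$correlation <= 1))
  # zero bases means correlating each sample with the mean texture
  c0 <- mean(vapply(gen$samples, function(s) {
    tensor_inner(s, mod$mean) / (tensor_norm(s) * tensor_norm(mod$mean))
  }, 0))
  expect_equal(curve$correlation[1], c0, tolerance = 1e-12)
  expect_error(reconstruction_quality(mod, gen$samples, integer(0)),
               "non-empty")
})

test_that("the relative stopping threshold truncates extraction", {
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 10, n_shared_bases = 4,
                     n_class_bases = 0, noise_sigma = 0, seed = 31)
  gen <- generate_ensemble(spec)
  full <- fit_ltc(gen$samples, max_bases = 10)
  rel <- full$residual_trace / full$residual_trace[1]
  target <- rel[3] + 1e-9  # threshold met after exactly two bases
  mod <- fit_ltc(gen$samples, max_bases = 10, threshold_r = target,
                 relative = TRUE)
  expect_equal(length(mod$bases), 2L)
})
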