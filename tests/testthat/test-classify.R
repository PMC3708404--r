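test_that("leave-one-out on cleanly separated features is perfect", {
  labels <- rep(c(-1, 1), each = 10)
  feats <- matrix(ifelse(labels < 0, -10, 10) + rnorm(20, 0, 0.1), ncol = 1)
  set.seed(0)
  for (cl in c("svm", "knn")) {
    r <- loo_classify(feats, labels, cl, k = 1)
    expect_equal(r$accuracy, 1)
    expect_equal(r$n_correct, 20L)
    expect_equal(r$predictions, labels)
  }
})

test_that("one contaminated sample costs exactly one fold under 1-NN", {
  labels <- rep(c(-1, 1), each = 5)
  feats <- matrix(labels, ncol = 1)
  feats[3, 1] <- 1  # a negative sample sitting among the positives
  r <- loo_classify(feats, labels, "knn", k = 1)
  expect_equal(r$n_correct, 9L)
  expect_equal(r$accuracy, 9 / 10)
  expect_equal(which(r$predictions != labels), 3L)
})

test_that("pure-noise features classify at chance", {
  set.seed(3)
  labels <- rep(c(-1, 1), each = 10)
  acc <- replicate(15, {
    feats <- matrix(rnorm(20 * 4), 20, 4)
    loo_classify(feats, labels, "knn", k = 3)$accuracy
  })
  expect_gt(mean(acc), 0.3)
  expect_lt(mean(acc), 0.7)
})

test_that("accuracy is invariant to sample order", {
  set.seed(4)
  labels <- rep(c(-1, 1), each = 8)
  feats <- cbind(labels + rnorm(16, 0, 0.8), rnorm(16))
  perm <- sample(16)
  for (cl in c("svm", "knn")) {
    a <- loo_classify(feats, labels, cl)
    b <- loo_classify(feats[perm, , drop = FALSE], labels[perm], cl)
    expect_equal(a$accuracy, b$accuracy)
    expect_equal(a$predictions[perm], b$predictions)
  }
})

test_that("degenerate folds are skipped with a warning", {
  labels <- c(-1, rep(1, 4))
  feats <- matrix(labels, ncol = 1)
  expect_warning(r <- loo_classify(feats, labels, "knn", k = 1),
                 "single class")
  expect_true(is.na(r$predictions[1]))
  expect_equal(r$n_evaluated, 4L)
})

test_that("single-feature representations agree across models", {
  # a one-basis coding model and a rank-(1,1,1) multilinear subspace carry
  # the same single feature (up to sign), hence identical KNN accuracy
  spec <- synth_spec(shape = c(8, 7, 6), n_samples = 12,
                     n_shared_bases = 4, seed = 43)
  gen <- generate_ensemble(spec)
  rep_ltc <- classification_experiment(gen$samples, gen$labels,
                                       method = "ltc_all", n_ltc_bases = 1,
                                       fold_mode = "pooled",
                                       classifiers = "knn")
  rep_gnd <- classification_experiment(gen$samples, gen$labels,
                                       method = "gndpca",
                                       core_ranks = c(1, 1, 1),
                                       fold_mode = "pooled",
                                       classifiers = "knn")
  expect_equal(rep_ltc$accuracy, rep_gnd$accuracy)
})

test_that("selecting the discriminative bases lifts pooled accuracy", {
  spec <- synth_spec(shape = c(12, 12, 10), n_samples = 16,
                     n_shared_bases = 8, n_class_bases = 2,
                     spectrum_decay = 0.9, class_effect = 2,
                     noise_sigma = 0.1, seed = 47)
  gen <- generate_ensemble(spec)
  report <- classification_experiment(gen$samples, gen$labels,
                                      method = c("ltc_all", "ltc_selected"),
                                      n_ltc_bases = 10, select_k = 3,
                                      fold_mode = "pooled")
  sel <- report[report$method == "ltc_selected", ]
  expect_true(all(sel$accuracy >= 0.85))
})

test_that("per-fold refitting evaluates held-out volumes without leakage", {
  spec <- synth_spec(shape = c(8, 8, 6), n_samples = 12,
                     n_shared_bases = 4, n_class_bases = 2,
                     class_effect = 3, noise_sigma = 0.05, seed = 53)
  gen <- generate_ensemble(spec)
  report <- classification_experiment(gen$samples, gen$labels,
                                      method = "ltc_selected",
                                      n_ltc_bases = 6, select_k = 2,
                                      fold_mode = "refit",
                                      classifiers = "knn")
  expect_equal(report$n_evaluated, 12L)
  expect_gt(report$accuracy, 0.8)
})
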