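#' Correlation between a basis's coefficients and binary class labels
#'
#' For labels in {-1, +1} this is the point-biserial (Pearson) correlation
#' between one coefficient column and the label vector: bases whose
#' coefficients separate the classes get correlations of large magnitude,
#' regardless of sign. A `literal` variant replaces the usual denominator
#' `sqrt(sum((c-cbar)^2) * sum((l-lbar)^2))` by
#' `sqrt(sum((c-cbar)^2 * (l-lbar)^2))`; it is provided for comparison only
#' and is not a correlation coefficient (it is not bounded by 1).
#'
#' @param coefficients samples-by-bases numeric matrix.
#' @param labels integer/numeric vector of -1/+1 class labels, one per row.
#' @param basis_index which coefficient column to correlate.
#' @param literal use the alternative denominator described above.
#' @return Scalar in `[-1, 1]` (Pearson form).
#' @export
basis_label_correlation <- function(coefficients, labels, basis_index,
                                    literal = FALSE) {
  lc <- check_labeled(coefficients, labels)
  j <- as.integer(basis_index)
  if (j < 1L || j > ncol(lc$coefficients)) {
    stop(sprintf("`basis_index` must be in 1..%d", ncol(lc$coefficients)),
         call. = FALSE)
  }
  cj <- lc$coefficients[, j]
  if (stats::sd(cj) == 0) {
    stop("coefficient column is constant; correlation undefined",
         call. = FALSE)
  }
  dc <- cj - mean(cj)
  dl <- lc$labels - mean(lc$labels)
  if (literal) {
    sum(dc * dl) / sqrt(sum(dc^2 * dl^2))
  } else {
    sum(dc * dl) / sqrt(sum(dc^2) * sum(dl^2))
  }
}

check_labeled <- function(coefficients, labels) {
  coefficients <- as.matrix(coefficients)
  if (!is.numeric(coefficients)) {
    stop("`coefficients` must be a numeric matrix", call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (length(labels) != nrow(coefficients)) {
    stop("one label per coefficient row is required", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1))) {
    stop("labels must be -1 or +1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  list(coefficients = coefficients, labels = labels)
}

#' Rank bases by discriminative power and select the top k
#'
#' Computes the label correlation of every basis, ranks by absolute
#' correlation (an anti-correlated basis separates the classes just as
#' well), breaking ties by lower basis index, and returns the first `k`.
#' Constant coefficient columns get correlation 0 and sort last.
#'
#' @inheritParams basis_label_correlation
#' @param k number of bases to select.
#' @return A list of class `basis_selection`: `correlations` (length-J),
#'   `ranking` (permutation of 1..J by decreasing `|correlation|`),
#'   `selected` (first `k` of the ranking).
#' @export
select_bases <- function(coefficients, labels, k) {
  lc <- check_labeled(coefficients, labels)
  j_total <- ncol(lc$coefficients)
  k <- as.integer(k)
  if (k < 1L || k > j_total) {
    stop(sprintf("`k` must be in 1..%d", j_total), call. = FALSE)
  }
  corrs <- vapply(seq_len(j_total), function(j) {
    if (stats::sd(lc$coefficients[, j]) == 0) return(0)
    basis_label_correlation(lc$coefficients, lc$labels, j)
  }, 0)
  ranking <- order(-abs(corrs), seq_len(j_total))
  structure(list(correlations = corrs, ranking = ranking,
                 selected = ranking[seq_len(k)]),
            class = "basis_selection")
}

#' Leave-one-out classification of labeled feature rows
#'
#' For each sample, trains the classifier on the remaining samples and
#' predicts the held-out one. Features are z-scored inside each fold using
#' training-fold statistics (constant features get unit scale), since both
#' the linear SVM and k-nearest-neighbour distances are sensitive to the
#' widely differing scales of leading versus trailing coefficients.
#'
#' @param features samples-by-features numeric matrix.
#' @param labels -1/+1 vector, one per row.
#' @param classifier `"svm"` (linear kernel) or `"knn"`.
#' @param cost SVM cost parameter.
#' @param k number of neighbours for KNN.
#' @param standardize z-score per fold (default TRUE).
#' @return List: `accuracy` (fraction correct over evaluated folds),
#'   `predictions` (-1/+1, NA for skipped folds), `n_correct`, `n_evaluated`.
#' @export
loo_classify <- function(features, labels, classifier = c("svm", "knn"),
                         cost = 1, k = 3L, standardize = TRUE) {
  classifier <- match.arg(classifier)
  lc <- check_labeled(features, labels)
  x <- lc$coefficients
  y <- lc$labels
  m <- nrow(x)
  if (m < 2L) stop("at least two samples are required", call. = FALSE)

  preds <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %d skipped: training set has a single class", i),
              call. = FALSE)
      next
    }
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
    }
    preds[i] <- switch(classifier,
      svm = {
        fit <- e1071::svm(xtr, factor(ytr, levels = c(-1, 1)),
                          kernel = "linear", cost = cost, scale = FALSE)
        as.numeric(as.character(stats::predict(fit, xte)))
      },
      knn = {
        kk <- min(as.integer(k), nrow(xtr))
        as.numeric(as.character(
          class::knn(xtr, xte, factor(ytr, levels = c(-1, 1)), k = kk)))
      })
  }
  ok <- !is.na(preds)
  list(accuracy = sum(preds[ok] == y[ok]) / sum(ok),
       predictions = preds,
       n_correct = sum(preds[ok] == y[ok]),
       n_evaluated = sum(ok))
}

# flattened core tensors as feature rows
core_feature_matrix <- function(model, samples) {
  do.call(rbind, lapply(samples, function(s) {
    as.numeric(project_core(model, s))
  }))
}

#' End-to-end classification experiment on a labeled volume ensemble
#'
#' Fits the requested representation, builds coefficient features, and
#' evaluates leave-one-out accuracy with both a linear SVM and KNN:
#' \describe{
#'   \item{ltc_all}{all coding coefficients as features}
#'   \item{ltc_selected}{only the `select_k` most label-correlated bases}
#'   \item{gndpca}{the flattened per-sample core tensor}
#' }
#' `fold_mode = "refit"` refits the representation (and the basis selection)
#' inside every leave-one-out fold, encoding the held-out volume with the
#' fold's model, so no information about the held-out label leaks into the
#' features. `"pooled"` fits once on all volumes and cross-validates only
#' the classifier -- cheaper, and the usual protocol when the representation
#' is treated as a fixed preprocessing step; both arms of any comparison
#' should then use the same mode.
#'
#' @param samples list of same-shape numeric arrays.
#' @param labels -1/+1 vector, one per sample.
#' @param method representation(s) to evaluate.
#' @param n_ltc_bases number of coding bases to fit.
#' @param select_k number of bases kept by `ltc_selected`.
#' @param core_ranks GND-PCA core size (clipped to the mode sizes).
#' @param fold_mode `"pooled"` or `"refit"` (see Details).
#' @param classifiers subset of `c("svm", "knn")`.
#' @param cost,k classifier hyperparameters.
#' @return data.frame: method, classifier, n_correct, n_evaluated, accuracy.
#' @export
classification_experiment <- function(samples, labels,
                                      method = c("ltc_all", "ltc_selected",
                                                 "gndpca"),
                                      n_ltc_bases = 50L, select_k = 5L,
                                      core_ranks = NULL,
                                      fold_mode = c("refit", "pooled"),
                                      classifiers = c("svm", "knn"),
                                      cost = 1, k = 3L) {
  method <- match.arg(method, several.ok = TRUE)
  fold_mode <- match.arg(fold_mode)
  classifiers <- match.arg(classifiers, c("svm", "knn"), several.ok = TRUE)
  d <- check_samples(samples)
  lab <- check_labeled(matrix(0, length(samples), 1L), labels)$labels
  m <- length(samples)
  if (is.null(core_ranks)) core_ranks <- pmin(d, c(20L, 20L, 3L)[seq_along(d)])
  core_ranks <- pmin(as.integer(core_ranks), d)

  need_ltc <- any(method %in% c("ltc_all", "ltc_selected"))
  need_gnd <- "gndpca" %in% method

  feature_sets <- list()
  if (fold_mode == "pooled") {
    if (need_ltc) {
      fit <- fit_ltc(samples, max_bases = n_ltc_bases)
      if ("ltc_all" %in% method) feature_sets$ltc_all <- fit$coefficients
      if ("ltc_selected" %in% method) {
        sel <- select_bases(fit$coefficients, lab,
                            min(select_k, ncol(fit$coefficients)))
        feature_sets$ltc_selected <- fit$coefficients[, sel$selected,
                                                      drop = FALSE]
      }
    }
    if (need_gnd) {
      fit_g <- fit_gndpca(samples, core_ranks)
      feature_sets$gndpca <- core_feature_matrix(fit_g, samples)
    }
    rows <- list()
    for (meth in method) {
      for (cl in classifiers) {
        r <- loo_classify(feature_sets[[meth]], lab, cl, cost = cost, k = k)
        rows[[length(rows) + 1L]] <-
          data.frame(method = meth, classifier = cl,
                     n_correct = r$n_correct, n_evaluated = r$n_evaluated,
                     accuracy = r$accuracy)
      }
    }
    return(do.call(rbind, rows))
  }

  # refit mode: representation and selection are refit per fold
  preds <- lapply(method, function(x) {
    sapply(classifiers, function(cl) rep(NA_real_, m), simplify = FALSE)
  })
  names(preds) <- method
  for (i in seq_len(m)) {
    tr_idx <- setdiff(seq_len(m), i)
    if (length(unique(lab[tr_idx])) < 2L) {
      warning(sprintf("fold %d skipped: training set has a single class", i),
              call. = FALSE)
      next
    }
    fold_feats <- list()
    if (need_ltc) {
      fit <- fit_ltc(samples[tr_idx], max_bases = n_ltc_bases)
      co_tr <- fit$coefficients
      co_te <- matrix(encode(fit, samples[[i]]), nrow = 1L)
      if ("ltc_all" %in% method) {
        fold_feats$ltc_all <- list(tr = co_tr, te = co_te)
      }
      if ("ltc_selected" %in% method) {
        sel <- select_bases(co_tr, lab[tr_idx], min(select_k, ncol(co_tr)))
        fold_feats$ltc_selected <- list(
          tr = co_tr[, sel$selected, drop = FALSE],
          te = co_te[, sel$selected, drop = FALSE])
      }
    }
    if (need_gnd) {
      fit_g <- fit_gndpca(samples[tr_idx], core_ranks)
      fold_feats$gndpca <- list(
        tr = core_feature_matrix(fit_g, samples[tr_idx]),
        te = matrix(as.numeric(project_core(fit_g, samples[[i]])), nrow = 1L))
    }
    for (meth in method) {
      ff <- fold_feats[[meth]]
      xtr <- ff$tr; xte <- ff$te
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
      for (cl in classifiers) {
        preds[[meth]][[cl]][i] <- switch(cl,
          svm = {
            fit_c <- e1071::svm(xtr, factor(lab[tr_idx], levels = c(-1, 1)),
                                kernel = "linear", cost = cost, scale = FALSE)
            as.numeric(as.character(stats::predict(fit_c, xte)))
          },
          knn = {
            kk <- min(as.integer(k), nrow(xtr))
            as.numeric(as.character(
              class::knn(xtr, xte, factor(lab[tr_idx], levels = c(-1, 1)),
                         k = kk)))
          })
      }
    }
  }
  rows <- list()
  for (meth in method) {
    for (cl in classifiers) {
      p <- preds[[meth]][[cl]]
      ok <- !is.na(p)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, classifier = cl,
                   n_correct = sum(p[ok] == lab[ok]),
                   n_evaluated = sum(ok),
                   accuracy = sum(p[ok] == lab[ok]) / sum(ok))
    }
  }
  do.call(rbind, rows)
}
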