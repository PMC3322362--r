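# Classifier families: kernel identities, training determinism,
# vote-fraction probabilities, calibration monotonicity, importance,
# forward selection, persistence.

test_that("normalized polynomial kernel satisfies its identities", {
  set.seed(101)
  for (i in 1:10) {
    x <- runif(20)
    y <- runif(20)
    expect_equal(normalized_poly_kernel(x, x), 1.0)
    expect_equal(normalized_poly_kernel(x, y),
                 normalized_poly_kernel(y, x))
    expect_gt(normalized_poly_kernel(x, y), 0)
    expect_lte(normalized_poly_kernel(x, y), 1)
  }
  # orthonormal x, y at degree 2: (0+1)^2 / sqrt((1+1)^2 (1+1)^2) = 1/4
  expect_equal(normalized_poly_kernel(c(1, 0), c(0, 1), degree = 2), 0.25)
  expect_error(normalized_poly_kernel(1:3, 1:4), "length")
})

test_that("kernel Gram matrices are symmetric positive semi-definite", {
  set.seed(102)
  for (n in c(5, 15, 30)) {
    x <- matrix(runif(n * 10), nrow = n) # non-negative features
    gram <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j) {
                    normalized_poly_kernel(x[i, ], x[j, ])
                  }))
    expect_equal(gram, t(gram))
    expect_gte(min(eigen(gram, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("both families separate the toy dataset and are seed-deterministic", {
  f <- encode_dataset(toy_separable_dataset(10))
  probe <- encode_dataset(toy_separable_dataset(4))
  for (family in c("random_forest", "svm")) {
    cfg <- model_config(family, seed = 77)
    m <- train_model(f, cfg)
    acc <- mean(classify(predict_proba(m, f)) == f$label)
    expect_equal(acc, 1.0)
    # identical call, identical seed -> identical held-out predictions
    m2 <- train_model(f, cfg)
    expect_equal(predict_proba(m2, probe), predict_proba(m, probe))
  }
})

test_that("training rejects single-class data and schema mismatches", {
  f <- encode_dataset(toy_separable_dataset(5))
  pos_only <- f[f$label == "positive", ]
  expect_error(train_model(pos_only, model_config()), "both classes")

  m <- train_model(f, model_config(seed = 1))
  expect_error(predict_proba(m, f[, -ncol(f)]), "schema")
})

test_that("RF probability equals the brute-force vote fraction", {
  f <- toy_planted_features(n_per_class = 15, delta = 0.4, seed = 8)
  m <- train_model(f, model_config("random_forest", seed = 3))
  x <- as.matrix(f[, -(1:3)])
  p <- predict_proba(m, f)
  per_tree <- predict(m$fit, x, predict.all = TRUE)$individual
  expect_equal(p, rowMeans(per_tree == "positive"), ignore_attr = TRUE)
  expect_true(all(p >= 0 & p <= 1))

  # single tree: vote fractions can only be 0 or 1
  m1 <- train_model(f, model_config("random_forest", rf_trees = 1,
                                    rf_features_per_split = 10, seed = 3))
  expect_true(all(predict_proba(m1, f) %in% c(0, 1)))
})

test_that("classify thresholds inclusively", {
  expect_equal(classify(c(0.50, 0.49, 0.51), 0.50),
               c("positive", "negative", "positive"))
  expect_equal(classify(c(0, 1), threshold = 1e-9),
               c("negative", "positive"))
  expect_error(classify(c(-0.1, 0.5)), "probabilities")
})

test_that("calibrated SVM probabilities are monotone in the raw margin", {
  f <- toy_planted_features(n_per_class = 20, delta = 0.5, seed = 13)
  m <- train_model(f, model_config("svm", seed = 5))
  x <- as.matrix(f[, -(1:3)])
  gram_new <- rpinet:::normalized_poly_gram(x, m$fit$x_train)
  margin <- rpinet:::svm_margin(m$fit, gram_new)
  prob <- predict_proba(m, f)
  ord <- order(margin)
  expect_true(all(diff(prob[ord]) >= -1e-12))
  expect_true(all(prob >= 0 & prob <= 1))
  # calibration slope is positive: larger margin, larger probability
  expect_gt(cor(margin, prob, method = "spearman"), 0.99)
})

test_that("feature importance ranks all features and flags constant ones", {
  f <- toy_planted_features(n_per_class = 20, delta = 0.5, seed = 21)
  m <- train_model(f, model_config("random_forest", seed = 21))
  imp <- feature_importance(m)
  expect_equal(nrow(imp), 599)
  expect_equal(imp$rank, 1:599)
  expect_true(all(diff(imp$importance) <= 0))
  # features never seen in the data have zero importance
  zero_feats <- names(which(colSums(as.matrix(f[, -(1:3)])) == 0))
  expect_true(length(zero_feats) > 0)
  expect_true(all(imp$importance[imp$feature %in% zero_feats] == 0))

  msvm <- train_model(f, model_config("svm", seed = 1))
  expect_error(feature_importance(msvm), "random_forest")
})

test_that("greedy forward selection finds a perfectly separating feature", {
  f <- encode_dataset(toy_separable_dataset(10))
  # P111 (pure-A protein triad) separates classes on its own
  cands <- c("P111", "P123", "P456", "R_ACGU", "R_GGCC", "P217")
  sel <- greedy_forward_select(f, model_config("random_forest", seed = 2),
                               max_features = 4, candidates = cands)
  expect_equal(sel$selected[1], "P111")
  expect_equal(sel$trace$cv_accuracy[1], 1.0)
  expect_equal(nrow(sel$trace), 1) # search stops at a perfect score
  expect_true(all(diff(sel$trace$cv_accuracy) >= 0))
  expect_error(greedy_forward_select(f, max_features = 0), "max_features")
})

test_that("forward selection picks up two complementary informative features", {
  # neither informative feature separates the classes alone (each one
  # covers half the positives), so a greedy search needs both; the other
  # columns are pure noise
  set.seed(31)
  n <- 40
  y <- rep(c("positive", "negative"), each = n / 2)
  f1 <- ifelse(y == "positive" & seq_len(n) %% 2 == 0, 1, 0)
  f2 <- ifelse(y == "positive" & seq_len(n) %% 2 == 1, 1, 0)
  noise <- matrix(runif(n * 8), nrow = n,
                  dimnames = list(NULL, sprintf("noise%d", 1:8)))
  feats <- dplyr::bind_cols(tibble::tibble(label = y, inf1 = f1,
                                           inf2 = f2),
                            tibble::as_tibble(noise))
  sel <- greedy_forward_select(feats,
                               model_config("random_forest", seed = 31),
                               max_features = 5)
  expect_true(all(c("inf1", "inf2") %in% sel$selected))
  expect_lte(match("inf1", sel$selected), 5)
  expect_lte(match("inf2", sel$selected), 5)
  expect_true(all(diff(sel$trace$cv_accuracy) >= 0))
})

test_that("model persistence round-trips predictions; corrupt files fail", {
  f <- toy_planted_features(n_per_class = 15, delta = 0.5, seed = 41)
  probe <- f[sample.int(nrow(f), 10), ]
  for (family in c("random_forest", "svm")) {
    m <- train_model(f, model_config(family, seed = 11))
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(m, path)
    back <- load_model(path)
    expect_equal(predict_proba(back, probe), predict_proba(m, probe))
  }
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "model")
  notmodel <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notmodel)
  expect_error(load_model(notmodel), "compatible")
})

test_that("growing the forest does not degrade held-out AUC", {
  f <- toy_planted_features(n_per_class = 60, delta = 0.3, seed = 51)
  set.seed(51)
  idx <- sample.int(nrow(f))
  train_idx <- idx[1:80]
  test_idx <- idx[81:120]
  auc_for <- function(trees) {
    m <- train_model(f[train_idx, ],
                     model_config("random_forest", rf_trees = trees,
                                  seed = 7))
    roc_auc(predict_proba(m, f[test_idx, ]), f$label[test_idx])$auc
  }
  expect_gte(auc_for(200), auc_for(20) - 0.05)
})

test_that("tidy and glance methods summarize models", {
  f <- encode_dataset(toy_separable_dataset(5))
  m <- train_model(f, model_config("random_forest", seed = 1))
  expect_equal(nrow(tidy(m)), 599)
  g <- glance(m)
  expect_equal(g$family, "random_forest")
  expect_equal(g$rf_trees, 20L)

  msvm <- train_model(f, model_config("svm", seed = 1))
  expect_equal(tidy(msvm)$term, c("intercept", "margin"))
  expect_true(glance(msvm)$calibrated)
})
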