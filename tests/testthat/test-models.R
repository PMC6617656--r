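test_that("model configs carry the study defaults per family", {
  expect_identical(model_config("naive_bayes")$n_features, 200L)
  rf <- model_config("random_forest")
  expect_identical(rf$n_features, 414L)
  expect_identical(rf$trees, 26L)
  expect_identical(model_config("svm_ovr_linear")$n_features, 378L)
  nn <- model_config("ffnn")
  expect_identical(nn$n_features, 398L)
  expect_identical(nn$hidden, 297L)
  expect_error(model_config("naive_bayes", n_features = 0), "n_features")
})

test_that("every family separates a linearly separable toy problem", {
  toy <- separable_toy()
  for (fam in va_families()) {
    cfg <- if (fam == "ffnn")
      model_config(fam, n_features = 2, seed = 5, hidden = 16)
    else
      model_config(fam, n_features = 2, seed = 5)
    model <- train_classifier(cfg, toy$X, toy$y)
    pred <- predict_with_confidence(model, toy$X)
    expect_identical(pred$top, toy$y)
  }
})

test_that("naive Bayes posteriors match the hand-computed Bayes rule", {
  # class A emits word counts (w1 = 9, w2 = 1), class B (1, 9); with
  # add-one smoothing over the 5 columns (2 words + 3 age indicators,
  # both records adult so the age terms cancel):
  #   theta_A(w1) = (9+1)/(11+5) = 10/16,  theta_B(w1) = (1+1)/(11+5)
  # and equal priors, a test record containing w1 once has posterior
  #   P(A | w1) = 10 / (10 + 2) = 10/12
  toks <- list(c(rep("w1", 9), "w2"), c("w1", rep("w2", 9)))
  v <- build_vocabulary(toks)
  X <- count_features(toks, v, c("adult", "adult"))
  model <- train_classifier(model_config("naive_bayes", n_features = 2),
                            X, c("A", "B"))
  Xte <- count_features(list("w1"), v, "adult")
  pred <- predict_with_confidence(model, Xte)
  expect_equal(unname(pred$prob[1, "A"]), 10 / 12, tolerance = 1e-12)
  expect_equal(unname(pred$prob[1, "B"]), 2 / 12, tolerance = 1e-12)
})

test_that("a zero-column matrix yields a prior-only naive Bayes model", {
  X <- Matrix::Matrix(0, nrow = 4, ncol = 0, sparse = TRUE)
  model <- train_classifier(model_config("naive_bayes"), X,
                            c("A", "A", "A", "B"))
  pred <- predict_with_confidence(
    model, Matrix::Matrix(0, nrow = 2, ncol = 0, sparse = TRUE))
  expect_equal(unname(pred$prob[1, ]), c(0.75, 0.25), ignore_attr = TRUE)
})

test_that("confidences are normalized and the top is the argmax", {
  toy <- separable_toy()
  for (fam in c("naive_bayes", "random_forest", "svm_ovr_linear")) {
    model <- train_classifier(model_config(fam, n_features = 2), toy$X,
                              toy$y)
    pred <- predict_with_confidence(model, toy$X)
    expect_true(all(abs(Matrix::rowSums(pred$prob) - 1) < 1e-9))
    expect_true(all(pred$prob >= 0))
    idx <- max.col(pred$prob, ties.method = "first")
    expect_identical(pred$top, colnames(pred$prob)[idx])
    expect_equal(pred$confidence,
                 pred$prob[cbind(seq_len(nrow(pred$prob)), idx)],
                 ignore_attr = TRUE)
    expect_identical(unname(pred$ranked[, 1]), pred$top)
  }
})

test_that("training twice with one seed reproduces predictions exactly", {
  toy <- separable_toy()
  for (fam in va_families()) {
    cfg <- if (fam == "ffnn")
      model_config(fam, n_features = 2, seed = 11, hidden = 8, epochs = 5)
    else
      model_config(fam, n_features = 2, seed = 11)
    p1 <- predict_with_confidence(train_classifier(cfg, toy$X, toy$y),
                                  toy$X)
    p2 <- predict_with_confidence(train_classifier(cfg, toy$X, toy$y),
                                  toy$X)
    expect_identical(p1$prob, p2$prob)
  }
})

test_that("training does not disturb the caller's RNG stream", {
  toy <- separable_toy()
  set.seed(123)
  before <- .Random.seed
  invisible(train_classifier(model_config("naive_bayes", n_features = 2),
                             toy$X, toy$y))
  expect_identical(.Random.seed, before)
})

test_that("NaN features and single-category labels are fatal", {
  toy <- separable_toy()
  expect_error(train_classifier(model_config("naive_bayes", n_features = 2),
                                toy$X, rep("A", nrow(toy$X))),
               "single category")
  Xbad <- as.matrix(toy$X)
  Xbad[1, 1] <- NaN
  attr(Xbad, "age_cols") <- attr(toy$X, "age_cols")
  expect_error(train_classifier(model_config("naive_bayes", n_features = 2),
                                Xbad, toy$y), "NaN")
})

test_that("prediction refuses a matrix missing model features, by name", {
  toy <- separable_toy()
  model <- train_classifier(model_config("naive_bayes", n_features = 2),
                            toy$X, toy$y)
  Xm <- toy$X[, setdiff(colnames(toy$X), "cough"), drop = FALSE]
  expect_error(predict_with_confidence(model, Xm), "cough")
})

test_that("extra columns at prediction time are ignored", {
  toy <- separable_toy()
  model <- train_classifier(model_config("naive_bayes", n_features = 2),
                            toy$X, toy$y)
  Xe <- cbind(toy$X, extra = 1)
  p0 <- predict_with_confidence(model, toy$X)
  p1 <- predict_with_confidence(model, Xe)
  expect_identical(p0$prob, p1$prob)
})

test_that("model bundles round-trip through save/load", {
  toy <- separable_toy()
  for (fam in c("naive_bayes", "svm_ovr_linear")) {
    model <- train_classifier(model_config(fam, n_features = 2, seed = 3),
                              toy$X, toy$y)
    dir <- file.path(tempdir(), paste0("bundle-", fam))
    save_classifier(model, dir)
    expect_true(all(file.exists(file.path(dir, c("config.json",
                                                 "features.json",
                                                 "fit.rds")))))
    back <- load_classifier(dir)
    expect_identical(predict_with_confidence(back, toy$X)$prob,
                     predict_with_confidence(model, toy$X)$prob)
    unlink(dir, recursive = TRUE)
  }
})

test_that("restrict_predictions renormalizes over the kept categories", {
  prob <- rbind(c(A = 0.5, B = 0.3, C = 0.2),
                c(A = 0.1, B = 0.2, C = 0.7))
  rownames(prob) <- c("r1", "r2")
  pred <- structure(list(prob = prob,
                         top = c("A", "C"),
                         confidence = c(0.5, 0.7),
                         ranked = rank_predictions(prob)),
                    class = "va_predictions")
  res <- restrict_predictions(pred, c("A", "B"))
  expect_identical(colnames(res$prob), c("A", "B"))
  expect_equal(unname(res$prob[1, ]), c(0.5, 0.3) / 0.8, ignore_attr = TRUE)
  expect_identical(res$top, c("A", "B"))
  expect_true(all(abs(rowSums(res$prob) - 1) < 1e-9))
  expect_error(restrict_predictions(pred, "Z"), "overlap")
})

test_that("rank_predictions orders categories by decreasing confidence", {
  prob <- rbind(c(A = 0.2, B = 0.5, C = 0.3))
  expect_identical(rank_predictions(prob)[1, ], c("B", "C", "A"))
})

test_that("optimize_config evaluates exactly the budget, reproducibly", {
  toy <- separable_toy()
  idx <- seq_len(nrow(toy$X))
  train_idx <- idx[idx %% 2 == 1]
  valid_idx <- idx[idx %% 2 == 0]
  o1 <- optimize_config("naive_bayes", toy$X, toy$y, train_idx, valid_idx,
                        budget = 5, seed = 21)
  o2 <- optimize_config("naive_bayes", toy$X, toy$y, train_idx, valid_idx,
                        budget = 5, seed = 21)
  expect_identical(nrow(o1$trials), 5L)
  expect_identical(o1$trials, o2$trials)
  expect_identical(o1$best_score, max(o1$trials$score))
  expect_s3_class(o1$best_config, "va_model_config")
})

test_that("optimize_config's best score is attainable by retraining", {
  toy <- separable_toy()
  idx <- seq_len(nrow(toy$X))
  train_idx <- idx[idx %% 2 == 1]
  valid_idx <- idx[idx %% 2 == 0]
  o <- optimize_config("naive_bayes", toy$X, toy$y, train_idx, valid_idx,
                       budget = 4, seed = 8)
  Xtr <- toy$X[train_idx, , drop = FALSE]
  attr(Xtr, "age_cols") <- attr(toy$X, "age_cols")
  m <- train_classifier(o$best_config, Xtr, toy$y[train_idx])
  pred <- predict_with_confidence(m, toy$X[valid_idx, , drop = FALSE])
  acc <- mean(pred$top == toy$y[valid_idx])
  expect_equal(acc, o$best_score, tolerance = 1e-9)
})

test_that("overlapping optimization splits are rejected", {
  toy <- separable_toy()
  expect_error(optimize_config("naive_bayes", toy$X, toy$y, 1:10, 10:20,
                               budget = 1))
})

test_that("a model fit on shuffled labels generalizes at chance only", {
  set.seed(77)
  n <- 120
  toks <- lapply(seq_len(n), function(i)
    sample(paste0("w", 1:12), 8, replace = TRUE))
  y <- sample(c("A", "B"), n, replace = TRUE)
  v <- build_vocabulary(toks[1:60])
  Xtr <- count_features(toks[1:60], v, rep("adult", 60))
  Xte <- count_features(toks[61:n], v, rep("adult", 60))
  model <- train_classifier(model_config("naive_bayes", n_features = 12),
                            Xtr, y[1:60])
  acc <- mean(predict_with_confidence(model, Xte)$top == y[61:n])
  # labels are independent of the text: out-of-sample accuracy must sit
  # near 0.5 (0.75 is ~4 binomial SDs above chance on 60 records)
  expect_lt(acc, 0.75)
})
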