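# a small synthetic labeled corpus shared by the harness tests
harness_corpus <- function(n = c(adult = 60, child = 40, neonate = 30),
                           seed = 4, lambda = 0, rho = 0) {
  csmf <- default_synth_csmf()
  cfg <- generator_config(n = n, csmf = csmf, lambda = lambda, rho = rho,
                          seed = seed)
  generate_corpus(cfg)
}

test_that("fold plans partition each age group into near-equal test sets", {
  corp <- harness_corpus()$records
  plan <- make_folds(corp, k = 5, seed = 9)
  expect_s3_class(plan, "va_fold_plan")
  for (g in c("adult", "child", "neonate")) {
    folds <- plan$folds[[g]]
    expect_length(folds, 5)
    ids <- unlist(folds)
    group_ids <- corp$record_id[corp$age_group == g]
    expect_setequal(ids, group_ids)           # covers the group
    expect_identical(anyDuplicated(ids), 0L)  # disjoint
    expect_lte(diff(range(lengths(folds))), 1)
  }
})

test_that("fold plans are reproducible from the seed", {
  corp <- harness_corpus()$records
  expect_identical(make_folds(corp, k = 5, seed = 9),
                   make_folds(corp, k = 5, seed = 9))
  p2 <- make_folds(corp, k = 5, seed = 10)
  expect_false(identical(make_folds(corp, k = 5, seed = 9)$folds, p2$folds))
})

test_that("groups smaller than k are rejected", {
  corp <- harness_corpus(n = c(adult = 20, child = 20, neonate = 9))$records
  expect_error(make_folds(corp, k = 10, seed = 1), "neonate")
})

test_that("adult and child folds train with cross-age-group augmentation", {
  corp <- harness_corpus()$records
  plan <- make_folds(corp, k = 5, seed = 9)
  for (g in c("adult", "child")) {
    train <- assemble_training(plan, 1, g, corp)
    test_ids <- plan$folds[[g]][[1]]
    # disjoint from the test fold
    expect_length(intersect(train$record_id, test_ids), 0)
    # contains every record of the other two age groups
    others <- corp$record_id[corp$age_group != g]
    expect_true(all(others %in% train$record_id))
    # and all own-group records outside the test fold
    own <- corp$record_id[corp$age_group == g]
    expect_setequal(setdiff(own, test_ids),
                    intersect(train$record_id, own))
  }
})

test_that("neonatal folds train on neonatal records only", {
  corp <- harness_corpus()$records
  plan <- make_folds(corp, k = 5, seed = 9)
  train <- assemble_training(plan, 2, "neonate", corp)
  expect_true(all(train$age_group == "neonate"))
  expect_length(intersect(train$record_id, plan$folds$neonate[[2]]), 0)
})

test_that("flag_low_confidence returns sub-threshold rows sorted ascending", {
  prob <- rbind(r1 = c(A = 0.9, B = 0.1),
                r2 = c(A = 0.55, B = 0.45),
                r3 = c(A = 0.4, B = 0.6))
  pred <- structure(list(prob = prob, top = c("A", "A", "B"),
                         confidence = c(0.9, 0.55, 0.6),
                         ranked = rank_predictions(prob)),
                    class = "va_predictions")
  out <- flag_low_confidence(pred, 0.7)
  expect_identical(out$record_id, c("r2", "r3"))
  expect_identical(out$predicted_category, c("A", "B"))
  expect_length(flag_low_confidence(pred, 0.1)$record_id, 0)
  expect_error(flag_low_confidence(pred, 0), "threshold")
  expect_error(flag_low_confidence(pred, 1.5), "threshold")
})

test_that("run_experiment produces a complete, reproducible report", {
  synth <- harness_corpus()
  lex <- va_lexicon(base = generator_vocabulary(synth$manifest$config))
  r1 <- run_experiment(synth$records, families = "naive_bayes", k = 3,
                       seed = 5, lexicon = lex, chance_iterations = 200)
  expect_s3_class(r1, "va_eval_report")
  expect_identical(sort(unique(r1$folds$age_group)),
                   c("adult", "child", "neonate"))
  expect_identical(nrow(r1$folds), 3L * 3L)     # 3 groups x 3 folds
  expect_true(all(table(r1$summary$age_group) == 6))  # 6 metrics
  grid <- report_grid(r1)
  expect_identical(nrow(grid), 3L)
  expect_true(all(c("sensitivity", "cccsmfa") %in% names(grid)))
  r2 <- run_experiment(synth$records, families = "naive_bayes", k = 3,
                       seed = 5, lexicon = lex, chance_iterations = 200)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$chance, r2$chance)
})

test_that("run_experiment demands a fully labeled corpus", {
  corp <- harness_corpus()$records
  corp$category[1] <- NA
  expect_error(run_experiment(corp, families = "naive_bayes", k = 3),
               "labeled")
})

test_that("per-fold vocabularies never see test-fold tokens (leakage guard)", {
  synth <- harness_corpus()
  corp <- synth$records
  lex <- va_lexicon(base = generator_vocabulary(synth$manifest$config))
  sw <- default_stopwords()
  tokens <- preprocess_corpus(corp, lex, sw)
  plan <- make_folds(corp, k = 3, seed = 13)
  g <- "neonate"; fold <- 1
  train <- assemble_training(plan, fold, g, corp)
  tok_of <- function(ids) tokens$tokens[match(ids, corp$record_id)]
  vocab_full <- build_vocabulary(tok_of(train$record_id))
  # delete the test fold from the corpus entirely and rebuild: the
  # training resources and fitted model must be bit-identical
  gone <- plan$folds[[g]][[fold]]
  corp2 <- corp[!corp$record_id %in% gone, , drop = FALSE]
  class(corp2) <- c("va_corpus", "data.frame")
  tokens2 <- preprocess_corpus(corp2, lex, sw)
  tok_of2 <- function(ids) tokens2$tokens[match(ids, corp2$record_id)]
  vocab_del <- build_vocabulary(tok_of2(train$record_id))
  expect_identical(vocab_full, vocab_del)
  Xa <- count_features(tok_of(train$record_id), vocab_full,
                       train$age_group)
  Xb <- count_features(tok_of2(train$record_id), vocab_del,
                       train$age_group)
  cfg <- model_config("naive_bayes", n_features = 20, seed = 31)
  ma <- train_classifier(cfg, Xa, train$category)
  mb <- train_classifier(cfg, Xb, train$category)
  expect_identical(ma$fit, mb$fit)
  expect_identical(ma$features, mb$features)
})

test_that("fold metrics are internally consistent with the raw metrics", {
  true <- c("A", "A", "B", "B")
  prob <- rbind(c(A = 0.8, B = 0.2), c(A = 0.6, B = 0.4),
                c(A = 0.3, B = 0.7), c(A = 0.9, B = 0.1))
  pred <- structure(list(prob = prob,
                         top = c("A", "A", "B", "A"),
                         confidence = c(0.8, 0.6, 0.7, 0.9),
                         ranked = rank_predictions(prob)),
                    class = "va_predictions")
  m <- vacoder:::fold_metrics(true, pred, c("A", "B"), chance_c = 0.5,
                              averaging = "weighted")
  cm <- confusion_table(true, pred$top, c("A", "B"))
  expect_equal(m$sensitivity, prf(cm)$sensitivity)
  expect_equal(m$pccc, pccc(concordance(true, pred$ranked), 2))
  csmfa <- csmf_accuracy(csmf(true, c("A", "B")),
                         csmf(pred$top, c("A", "B")))
  expect_equal(m$csmfa, csmfa)
  expect_equal(m$cccsmfa, cccsmfa(csmfa, 0.5))
})

test_that("evaluation reports serialize to JSON", {
  synth <- harness_corpus(n = c(adult = 30, child = 0, neonate = 0))
  lex <- va_lexicon(base = generator_vocabulary(synth$manifest$config))
  r <- run_experiment(synth$records, families = "naive_bayes", k = 3,
                      seed = 5, lexicon = lex, chance_iterations = 100)
  f <- tempfile(fileext = ".json")
  write_eval_report(r, f)
  back <- jsonlite::fromJSON(f)
  expect_identical(back$schema, "vacoder-eval-report/1")
  expect_equal(back$summary$mean, r$summary$mean)
})
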