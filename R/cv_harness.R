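#' Make a cross-validation fold plan
#'
#' Partitions the record ids of each age group into `k` disjoint test
#' sets of near-equal size (differing by at most one record) by simple
#' random assignment. Folds are not stratified by cause: test
#' distributions are left to mirror the data, re-sampling to uniform
#' cause distributions being deliberately avoided in this design.
#'
#' @param corpus A labeled `va_corpus`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the plan is reproducible from it.
#' @param stratify_by_category If `TRUE`, additionally balance folds
#'   within each cause (off by default, see above).
#' @return An object of class `va_fold_plan`: `k`, `seed`, and `folds`, a
#'   list per age group of `k` character vectors of test record ids.
#' @export
make_folds <- function(corpus, k = 10, seed = 1,
                       stratify_by_category = FALSE) {
  validate_corpus(corpus)
  stopifnot(k >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- split_by_age_group(corpus)
  folds <- lapply(groups, function(g) {
    n <- nrow(g)
    if (n < k)
      stop("age group '", g$age_group[1], "' has only ", n,
           " records; use k <= ", n, call. = FALSE)
    assign_fold <- function(ids) {
      n_i <- length(ids)
      sizes <- rep(n_i %/% k, k) + (seq_len(k) <= n_i %% k)
      split(sample(ids), rep(seq_len(k), times = sizes))
    }
    if (stratify_by_category && !anyNA(g$category)) {
      per_cat <- lapply(split(g$record_id, g$category), assign_fold)
      lapply(seq_len(k), function(f)
        unlist(lapply(per_cat, `[[`, f), use.names = FALSE))
    } else {
      unname(assign_fold(g$record_id))
    }
  })
  structure(list(k = k, seed = seed, folds = folds),
            class = "va_fold_plan")
}

#' @export
print.va_fold_plan <- function(x, ...) {
  cat("Fold plan: k = ", x$k, ", seed = ", x$seed, "\n", sep = "")
  for (g in names(x$folds))
    cat("  ", g, ": ", sum(lengths(x$folds[[g]])), " records in ",
        length(x$folds[[g]]), " folds\n", sep = "")
  invisible(x)
}

#' Assemble the training set for one fold of one age group
#'
#' Adult and child folds train on their own group's non-test records
#' *plus every record of the other two age groups* (cross-age-group
#' augmentation: the extra narratives share vocabulary and the age
#' indicator lets the model separate strata). Neonatal folds train on
#' neonatal non-test records only, because neonates use a different
#' category scheme. Training and test sets are always disjoint.
#'
#' @param plan A [make_folds()] plan.
#' @param fold Fold number in `1..k`.
#' @param age_group Age group being evaluated.
#' @param corpus The full corpus the plan was built from.
#' @return The training `va_corpus` subset.
#' @export
assemble_training <- function(plan, fold, age_group, corpus) {
  stopifnot(inherits(plan, "va_fold_plan"), fold >= 1, fold <= plan$k)
  age_group <- match.arg(age_group, va_age_groups())
  test_ids <- plan$folds[[age_group]][[fold]]
  own <- corpus$age_group == age_group & !(corpus$record_id %in% test_ids)
  keep <- if (age_group == "neonate") own
          else own | corpus$age_group != age_group
  out <- corpus[keep, , drop = FALSE]
  class(out) <- c("va_corpus", "data.frame")
  out
}

#' Flag low-confidence predictions for human review
#'
#' @param predictions A [predict_with_confidence()] result.
#' @param threshold Records with top-1 confidence strictly below this are
#'   flagged; must lie in (0, 1].
#' @return Data frame `record_id`, `predicted_category`, `confidence`,
#'   sorted by ascending confidence.
#' @export
flag_low_confidence <- function(predictions, threshold) {
  stopifnot(inherits(predictions, "va_predictions"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  ids <- rownames(predictions$prob) %||%
    as.character(seq_along(predictions$top))
  flagged <- which(predictions$confidence < threshold)
  out <- data.frame(record_id = ids[flagged],
                    predicted_category = predictions$top[flagged],
                    confidence = predictions$confidence[flagged],
                    stringsAsFactors = FALSE)
  out[order(out$confidence), , drop = FALSE]
}

fold_metrics <- function(true, pred, categories, chance_c, averaging) {
  cm <- confusion_table(true, pred$top, categories)
  agg <- suppressWarnings(prf(cm, averaging))
  C1 <- concordance(true, pred$ranked, k = 1)
  csmfa <- csmf_accuracy(csmf(true, categories), csmf(pred$top, categories))
  data.frame(precision = agg$precision, sensitivity = agg$sensitivity,
             f1 = agg$f1,
             pccc = pccc(C1, length(categories), k = 1),
             csmfa = csmfa,
             cccsmfa = cccsmfa(csmfa, chance_c))
}

#' Run a cross-validated coding experiment
#'
#' The full evaluation loop: preprocess every narrative once with the
#' global resources, plan folds per age group, and for each fold fit the
#' vocabulary and ANOVA feature selection on the training records only,
#' train each requested classifier family, score the held-out records,
#' and aggregate per-age-group fold means and standard deviations of
#' precision, sensitivity, F1, PCCC, CSMF accuracy and chance-corrected
#' CSMF accuracy. The chance baseline is recomputed per age group from
#' the evaluated records (`dataset_null`), or taken from
#' [preset_chance_means()] with `chance = "preset"`.
#'
#' @param corpus A fully labeled `va_corpus` (every `category` set).
#' @param scheme The active [cod_scheme()].
#' @param families Classifier families to evaluate.
#' @param k Number of folds (default 10).
#' @param seed Master seed for folds, chance baselines and training.
#' @param configs Optional named list of [model_config()] overrides per
#'   family.
#' @param lexicon,stopwords Preprocessing resources (global constants,
#'   not fold-fit).
#' @param tokens Optional precomputed [preprocess_corpus()] result for
#'   `corpus` (skips preprocessing).
#' @param chance `"dataset_null"` (default) or `"preset"`.
#' @param chance_iterations Monte-Carlo iterations for the baseline.
#' @param min_df Vocabulary document-frequency floor.
#' @param averaging Aggregation for precision/sensitivity/F1.
#' @return An object of class `va_eval_report`: `summary` (one row per
#'   age group x family x metric with fold mean and sd), `folds` (full
#'   per-fold detail), `chance` (per-group baseline), `notes` (folds
#'   where a category was absent from training), and a `config` echo
#'   with seeds and the resource hash.
#' @export
run_experiment <- function(corpus, scheme = default_scheme(),
                           families = va_families(), k = 10, seed = 1,
                           configs = NULL,
                           lexicon = va_lexicon(),
                           stopwords = default_stopwords(),
                           tokens = NULL,
                           chance = c("dataset_null", "preset"),
                           chance_iterations = 1000,
                           min_df = 1,
                           averaging = "weighted") {
  chance <- match.arg(chance)
  validate_corpus(corpus, scheme)
  if (anyNA(corpus$category))
    stop("run_experiment requires a fully labeled corpus")
  families <- match.arg(families, va_families(), several.ok = TRUE)
  if (is.null(tokens))
    tokens <- preprocess_corpus(corpus, lexicon, stopwords)
  stopifnot(identical(tokens$record_id, corpus$record_id))
  plan <- make_folds(corpus, k = k, seed = seed)
  tok_of <- function(ids) tokens$tokens[match(ids, corpus$record_id)]

  groups <- intersect(va_age_groups(), unique(corpus$age_group))
  chance_c <- vapply(groups, function(g) {
    cats <- scheme_categories(scheme, g)
    if (chance == "preset") return(preset_chance_means()[[g]])
    as.numeric(chance_csmfa("dataset_null", iterations = chance_iterations,
                            seed = seed + match(g, va_age_groups()),
                            true_labels = corpus$category[corpus$age_group == g],
                            categories = cats))
  }, numeric(1))
  names(chance_c) <- groups

  fold_rows <- list()
  notes <- character(0)
  for (g in groups) {
    cats <- scheme_categories(scheme, g)
    for (f in seq_len(k)) {
      test_ids <- plan$folds[[g]][[f]]
      train <- assemble_training(plan, f, g, corpus)
      vocab <- build_vocabulary(tok_of(train$record_id), min_df = min_df)
      Xtr <- count_features(tok_of(train$record_id), vocab, train$age_group)
      rownames(Xtr) <- train$record_id
      test <- corpus[match(test_ids, corpus$record_id), , drop = FALSE]
      Xte <- count_features(tok_of(test_ids), vocab, test$age_group)
      rownames(Xte) <- test_ids
      # augmentation can bring other-scheme categories into training:
      # fit over the union label space, score over the group's scheme
      y <- factor(train$category,
                  levels = union(cats, unique(train$category)))
      absent <- cats[!cats %in% train$category]
      if (length(absent))
        notes <- c(notes, paste0(g, " fold ", f,
                                 ": categories absent from training: ",
                                 paste(absent, collapse = ", ")))
      for (fam in families) {
        cfg <- configs[[fam]] %||%
          model_config(fam, seed = seed + 97L * f + match(fam, families))
        model <- suppressWarnings(train_classifier(cfg, Xtr, y))
        pred <- restrict_predictions(predict_with_confidence(model, Xte),
                                     cats)
        m <- fold_metrics(test$category, pred, cats, chance_c[[g]],
                          averaging)
        fold_rows[[length(fold_rows) + 1L]] <-
          cbind(data.frame(age_group = g, family = fam, fold = f,
                           n_test = length(test_ids),
                           stringsAsFactors = FALSE), m)
      }
    }
  }
  folds <- do.call(rbind, fold_rows)
  metrics <- c("precision", "sensitivity", "f1", "pccc", "csmfa", "cccsmfa")
  summary <- do.call(rbind, lapply(split(
    folds, list(folds$age_group, folds$family), drop = TRUE),
    function(d) {
      data.frame(age_group = d$age_group[1], family = d$family[1],
                 metric = metrics,
                 mean = vapply(metrics, function(m) mean(d[[m]]), 0),
                 sd = vapply(metrics, function(m) stats::sd(d[[m]]), 0),
                 n_folds = nrow(d), row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  structure(list(summary = summary, folds = folds, chance = chance_c,
                 notes = notes,
                 config = list(k = k, seed = seed, families = families,
                               scheme = scheme$name, min_df = min_df,
                               averaging = averaging, chance = chance,
                               chance_iterations = chance_iterations,
                               resource_hash = tokens$resource_hash)),
            class = "va_eval_report")
}

#' @export
print.va_eval_report <- function(x, digits = 3, ...) {
  cat("VA coding evaluation (", x$config$k, "-fold CV, scheme '",
      x$config$scheme, "', seed ", x$config$seed, ")\n", sep = "")
  wide <- report_grid(x)
  print(format(wide, digits = digits), row.names = FALSE)
  if (length(x$notes))
    cat(length(x$notes), "fold note(s); see $notes\n")
  invisible(x)
}

#' Flatten an evaluation report to a score grid
#'
#' One row per age group and classifier family, columns = metric fold
#' means, shaped like the familiar results tables of VA coding studies.
#'
#' @param report A `va_eval_report`.
#' @return Data frame of fold-mean scores.
#' @export
report_grid <- function(report) {
  stopifnot(inherits(report, "va_eval_report"))
  s <- report$summary
  out <- stats::reshape(s[c("age_group", "family", "metric", "mean")],
                        direction = "wide",
                        idvar = c("age_group", "family"),
                        timevar = "metric")
  names(out) <- sub("^mean\\.", "", names(out))
  ord <- order(match(out$age_group, va_age_groups()),
               match(out$family, va_families()))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as JSON
#'
#' @param report A `va_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "va_eval_report"))
  jsonlite::write_json(
    list(schema = "vacoder-eval-report/1",
         config = report$config,
         chance = as.list(report$chance),
         summary = report$summary,
         folds = report$folds,
         notes = report$notes),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
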