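#' The four supported classifier families
#' @return Character vector of family names.
#' @export
va_families <- function()
  c("naive_bayes", "random_forest", "svm_ovr_linear", "ffnn")

#' Classifier configuration
#'
#' Creates a configuration for one of the four classifier families, with
#' the optimized defaults of the narrative-coding study design: naive
#' Bayes uses the best 200 ANOVA-ranked features; random forest 414
#' features and 26 trees; one-vs-rest linear SVM 378 features; the
#' feed-forward network 398 features, one hidden layer of 297 ReLU units.
#'
#' @param family One of `"naive_bayes"`, `"random_forest"`,
#'   `"svm_ovr_linear"`, `"ffnn"`.
#' @param n_features Number of ANOVA-selected word features (family
#'   default if `NULL`).
#' @param seed Integer seed controlling every random element of training.
#' @param ... Family parameters overriding the defaults: `alpha`
#'   (naive Bayes add-alpha smoothing, default 1), `trees` and `mtry`
#'   (random forest), `cost` (SVM), `hidden`, `epochs`, `batch`, `lr`,
#'   `patience`, `val_frac` (network).
#' @return An object of class `va_model_config`.
#' @export
model_config <- function(family = va_families(), n_features = NULL,
                         seed = 1L, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    naive_bayes = list(n_features = 200L, alpha = 1),
    random_forest = list(n_features = 414L, trees = 26L, mtry = NULL),
    svm_ovr_linear = list(n_features = 378L, cost = 1),
    ffnn = list(n_features = 398L, hidden = 297L, epochs = 30L,
                batch = 32L, lr = 1e-3, patience = 5L, val_frac = 0.1))
  cfg <- modifyList(defaults, list(...))
  if (!is.null(n_features)) cfg$n_features <- as.integer(n_features)
  if (cfg$n_features < 1) stop("n_features must be >= 1")
  structure(c(list(family = family, seed = as.integer(seed)), cfg),
            class = "va_model_config")
}

#' @export
print.va_model_config <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "seed"))]
  cat("Model config [", x$family, "] ",
      paste(names(pars), vapply(pars, function(v)
        if (is.null(v)) "auto" else paste(v, collapse = ","), character(1)),
        sep = "=", collapse = ", "),
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

model_categories <- function(y) {
  if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
}

#' Train a classifier on a feature matrix
#'
#' Performs ANOVA top-k feature selection (`config$n_features` word
#' features, age indicator always kept) on the supplied matrix, then fits
#' the configured family. Training is deterministic given `config$seed`.
#' The fitted object records the exact selected column names so that
#' prediction can align any compatible matrix.
#'
#' @param config A [model_config()].
#' @param X Feature matrix from [count_features()] (training records
#'   only). A matrix with zero columns is allowed for naive Bayes and
#'   yields a prior-only model.
#' @param y Category label per training record; at least two distinct
#'   categories. If a factor, its level order defines the category index
#'   used for tie-breaking.
#' @return An object of class `va_classifier`.
#' @export
train_classifier <- function(config, X, y) {
  stopifnot(inherits(config, "va_model_config"))
  categories <- model_categories(y)
  y <- factor(as.character(y), levels = categories)
  if (length(categories) < 2) stop("training labels contain a single category")
  xv <- if (methods::is(X, "sparseMatrix")) X@x else as.vector(as.matrix(X))
  if (anyNA(xv)) stop("NaN/NA values in the feature matrix")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (ncol(X) == 0 || is.null(attr(X, "age_cols"))) {
    sel <- NULL
    Xs <- X
  } else {
    sel <- select_top_k(X, y, config$n_features)
    Xs <- sel$matrix
  }
  fit <- switch(config$family,
    naive_bayes = nb_fit(Xs, y, alpha = config$alpha),
    random_forest = {
      p <- ncol(Xs)
      mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
      ranger::ranger(x = as.matrix(Xs), y = y,
                     num.trees = config$trees, mtry = min(mtry, p),
                     probability = TRUE, seed = config$seed,
                     num.threads = 1)
    },
    svm_ovr_linear = svm_ovr_fit(Xs, y, cost = config$cost),
    ffnn = ffnn_fit(Xs, as.integer(y), hidden = config$hidden,
                    epochs = config$epochs, batch = config$batch,
                    lr = config$lr, val_frac = config$val_frac,
                    patience = config$patience, seed = config$seed))
  structure(
    list(family = config$family, config = config, fit = fit,
         categories = categories,
         features = colnames(Xs),
         selected = if (is.null(sel)) integer(0) else sel$selected,
         ranking = if (is.null(sel)) NULL else sel$ranking,
         age_cols = attr(Xs, "age_cols")),
    class = "va_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.va_classifier <- function(x, ...) {
  cat("VA classifier [", x$family, "]: ", length(x$categories),
      " categories, ", length(x$features), " features\n", sep = "")
  invisible(x)
}

# ---- multinomial naive Bayes with add-alpha smoothing ----
nb_fit <- function(X, y, alpha = 1) {
  C <- nlevels(y)
  prior <- as.numeric(table(y)) / length(y)
  if (ncol(X) == 0)
    return(list(log_prior = log(prior), log_theta = NULL, alpha = alpha))
  ind <- Matrix::sparseMatrix(i = as.integer(y), j = seq_along(y), x = 1,
                              dims = c(C, length(y)))
  counts <- as.matrix(ind %*% X)               # C x V word totals per class
  theta <- (counts + alpha) / (rowSums(counts) + alpha * ncol(X))
  list(log_prior = log(prior), log_theta = log(theta), alpha = alpha)
}

nb_predict_prob <- function(fit, X) {
  n <- if (is.null(dim(X))) 1L else nrow(X)
  if (is.null(fit$log_theta)) {
    scores <- matrix(fit$log_prior, n, length(fit$log_prior), byrow = TRUE)
  } else {
    scores <- as.matrix(X %*% t(fit$log_theta))
    scores <- sweep(scores, 2, fit$log_prior, "+")
  }
  .softmax_rows(scores)
}

# ---- one-vs-rest linear SVMs, softmax over decision values ----
svm_ovr_fit <- function(X, y, cost = 1) {
  Xd <- as.matrix(X)
  machines <- lapply(levels(y), function(cat) {
    pos <- y == cat
    if (!any(pos) || all(pos)) return(NULL)   # degenerate: no margin to fit
    yb <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x = Xd, y = yb, kernel = "linear", cost = cost,
                    scale = FALSE)
    # libsvm signs decision values toward the label it saw first in the
    # data, so calibrate the sign against the training split
    dv <- attr(predict(m, Xd, decision.values = TRUE),
               "decision.values")[, 1]
    m$ovr_sign <- if (mean(dv[pos]) >= mean(dv[!pos])) 1 else -1
    m
  })
  names(machines) <- levels(y)
  list(machines = machines, cost = cost)
}

svm_ovr_decision <- function(fit, X) {
  Xd <- as.matrix(X)
  dec <- vapply(fit$machines, function(m) {
    if (is.null(m)) return(rep(-Inf, nrow(Xd)))
    pr <- predict(m, Xd, decision.values = TRUE)
    m$ovr_sign * as.numeric(attr(pr, "decision.values")[, 1])
  }, numeric(nrow(Xd)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(Xd))
  dec
}

#' Per-category confidence predictions
#'
#' Produces, for every record, a confidence for each category the model
#' was trained on. Confidences are non-negative and sum to 1 per record;
#' the top-1 category is the argmax (ties resolved toward the lower
#' category index). Naive Bayes and the network emit posteriors directly;
#' the random forest emits vote fractions; the SVM softmaxes its
#' one-vs-rest decision values.
#'
#' @param model A [train_classifier()] result.
#' @param X Feature matrix whose columns include all of the model's
#'   selected features (extra columns are ignored); missing columns are an
#'   error naming the absent stems.
#' @return An object of class `va_predictions`: `prob` (records x
#'   categories), `top` (predicted category), `confidence` (top-1
#'   confidence) and `ranked` (categories ordered best-first per record).
#' @export
predict_with_confidence <- function(model, X) {
  stopifnot(inherits(model, "va_classifier"))
  if (length(model$features)) {
    missing <- setdiff(model$features, colnames(X))
    if (length(missing))
      stop("feature matrix lacks columns used by the model: ",
           paste(head(missing, 10), collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  }
  prob <- switch(model$family,
    naive_bayes = nb_predict_prob(model$fit, X),
    random_forest = {
      p <- predict(model$fit, data = as.matrix(X),
                   num.threads = 1)$predictions
      p[, model$categories, drop = FALSE]
    },
    svm_ovr_linear = .softmax_rows(svm_ovr_decision(model$fit, X)),
    ffnn = ffnn_predict_prob(model$fit, X))
  colnames(prob) <- model$categories
  rownames(prob) <- rownames(X)
  prob <- prob / rowSums(prob)
  top_idx <- max.col(prob, ties.method = "first")
  ranked <- t(apply(prob, 1, function(p)
    model$categories[order(-p, seq_along(p))]))
  structure(list(prob = prob,
                 top = model$categories[top_idx],
                 confidence = prob[cbind(seq_len(nrow(prob)), top_idx)],
                 ranked = ranked),
            class = "va_predictions")
}

#' @export
print.va_predictions <- function(x, ...) {
  cat("Predictions for ", nrow(x$prob), " records over ", ncol(x$prob),
      " categories; mean top-1 confidence ",
      sprintf("%.3f", mean(x$confidence)), "\n", sep = "")
  invisible(x)
}

#' Restrict predictions to a category subset
#'
#' Drops confidence columns outside `categories` and renormalizes each
#' row, recomputing the top-1 category and ranking. Used when a model was
#' trained over a wider label space than the one being scored (e.g. a
#' model trained with cross-age-group augmentation, evaluated on one
#' stratum's scheme).
#'
#' @param predictions A [predict_with_confidence()] result.
#' @param categories Categories to keep (order defines the tie-break
#'   index).
#' @return A new `va_predictions` object over `categories`.
#' @export
restrict_predictions <- function(predictions, categories) {
  stopifnot(inherits(predictions, "va_predictions"))
  keep <- intersect(categories, colnames(predictions$prob))
  if (!length(keep))
    stop("no overlap between prediction columns and requested categories")
  prob <- predictions$prob[, keep, drop = FALSE]
  tot <- rowSums(prob)
  prob[tot == 0, ] <- 1 / length(keep)     # no mass left: fall back to flat
  prob <- prob / rowSums(prob)
  top_idx <- max.col(prob, ties.method = "first")
  structure(list(prob = prob,
                 top = keep[top_idx],
                 confidence = prob[cbind(seq_len(nrow(prob)), top_idx)],
                 ranked = rank_predictions(prob)),
            class = "va_predictions")
}

#' Rank categories per record from a confidence matrix
#'
#' @param prob Records x categories confidence matrix.
#' @return Character matrix, one row per record, categories ordered by
#'   decreasing confidence (ties toward the lower column index).
#' @export
rank_predictions <- function(prob) {
  t(apply(prob, 1, function(p) colnames(prob)[order(-p, seq_along(p))]))
}

#' Save / load a trained classifier
#'
#' A model bundle is a directory holding `config.json` (family, seed and
#' parameters), `features.json` (categories and selected feature names)
#' and `fit.rds` (fitted parameters). Reloading reproduces predictions
#' exactly.
#'
#' @param model A `va_classifier`.
#' @param dir Bundle directory (created if needed).
#' @return `save_classifier()` returns `dir` invisibly;
#'   `load_classifier()` the restored `va_classifier`.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "va_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(categories = model$categories, features = model$features,
         selected = model$selected, age_cols = model$age_cols),
    file.path(dir, "features.json"), auto_unbox = FALSE, pretty = TRUE)
  saveRDS(model, file.path(dir, "fit.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  f <- file.path(dir, "fit.rds")
  stopifnot(file.exists(f))
  model <- readRDS(f)
  stopifnot(inherits(model, "va_classifier"))
  model
}

#' Random-search hyperparameter optimization
#'
#' Evaluates exactly `budget` seeded random candidates from the family's
#' search space (always including `n_features`), scoring each by
#' support-weighted sensitivity on the validation rows. Failed trials
#' score `-Inf` and are kept in the log.
#'
#' @param family Classifier family.
#' @param X Full feature matrix.
#' @param y Labels aligned to `X` rows.
#' @param train_idx,valid_idx Row indices of the optimization split.
#' @param budget Number of candidate evaluations (default 100).
#' @param seed Seed controlling the candidate sequence.
#' @param space Optional named list of samplers `function(n)` overriding
#'   the default ranges; entries may also be vectors of discrete values to
#'   sample from.
#' @return List with `best_config` (a [model_config()]), `best_score`,
#'   and `trials` (data frame log of every candidate and score).
#' @export
optimize_config <- function(family, X, y, train_idx, valid_idx,
                            budget = 100, seed = 1, space = NULL) {
  stopifnot(budget >= 1, length(intersect(train_idx, valid_idx)) == 0)
  family <- match.arg(family, va_families())
  n_word <- length(setdiff(seq_len(ncol(X)), attr(X, "age_cols")))
  default_space <- switch(family,
    naive_bayes = list(
      n_features = function(n) sample(seq_len(n_word), n, replace = TRUE),
      alpha = function(n) runif(n, 0.1, 2)),
    random_forest = list(
      n_features = function(n) sample(seq_len(n_word), n, replace = TRUE),
      trees = function(n) sample(5:100, n, replace = TRUE)),
    svm_ovr_linear = list(
      n_features = function(n) sample(seq_len(n_word), n, replace = TRUE),
      cost = function(n) 10^runif(n, -2, 1)),
    ffnn = list(
      n_features = function(n) sample(seq_len(n_word), n, replace = TRUE),
      hidden = function(n) sample(25:400, n, replace = TRUE),
      lr = function(n) 10^runif(n, -4, -2)))
  space <- modifyList(default_space, as.list(space %||% list()))
  space <- lapply(space, function(s)
    if (is.function(s)) s else {
      vals <- s
      function(n) sample(vals, n, replace = TRUE)
    })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cand <- as.data.frame(lapply(space, function(s) s(budget)))
  ytr <- y[train_idx]; yva <- y[valid_idx]
  Xtr <- X[train_idx, , drop = FALSE]
  attr(Xtr, "age_cols") <- attr(X, "age_cols")
  Xva <- X[valid_idx, , drop = FALSE]
  scores <- numeric(budget)
  errors <- character(budget)
  for (b in seq_len(budget)) {
    pars <- as.list(cand[b, , drop = FALSE])
    scores[b] <- tryCatch({
      cfg <- do.call(model_config,
                     c(list(family = family, seed = seed), pars))
      m <- suppressWarnings(train_classifier(cfg, Xtr, ytr))
      pred <- predict_with_confidence(m, Xva)
      cm <- confusion_table(as.character(yva), pred$top,
                            union(model_categories(y), pred$top))
      suppressWarnings(prf(cm, "weighted")$sensitivity)
    }, error = function(e) {
      errors[b] <<- conditionMessage(e)
      -Inf
    })
  }
  trials <- cbind(trial = seq_len(budget), cand,
                  score = scores, error = errors)
  best <- which.max(scores)
  best_config <- do.call(model_config,
                         c(list(family = family, seed = seed),
                           as.list(cand[best, , drop = FALSE])))
  list(best_config = best_config, best_score = scores[best],
       trials = trials)
}
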