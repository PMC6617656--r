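#' Confusion table over a fixed category list
#'
#' @param true,pred Character vectors of true and predicted categories.
#' @param categories Ordered category list of the active scheme; labels
#'   outside it are an error.
#' @return N x N integer matrix, rows = true, columns = predicted.
#' @export
confusion_table <- function(true, pred, categories) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  bad <- setdiff(unique(c(true, pred)), categories)
  if (length(bad))
    stop("labels outside the category list: ", paste(bad, collapse = ", "))
  t_f <- factor(true, levels = categories)
  p_f <- factor(pred, levels = categories)
  unclass(table(true = t_f, predicted = p_f))
}

#' Precision, sensitivity and F1 from a confusion table
#'
#' Per-category precision TP/(TP+FP), sensitivity TP/(TP+FN) and
#' F1 = 2PR/(P+R), aggregated by support-weighted (default), macro, or
#' micro averaging. Categories with zero support contribute 0 to macro
#' averages, with a warning.
#'
#' @param confusion Square matrix from [confusion_table()].
#' @param averaging `"weighted"`, `"macro"` or `"micro"`.
#' @return List with scalar `precision`, `sensitivity`, `f1`, and a
#'   `per_category` data frame.
#' @export
prf <- function(confusion, averaging = c("weighted", "macro", "micro")) {
  averaging <- match.arg(averaging)
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  if (total == 0) stop("empty confusion table")
  tp <- diag(confusion)
  support <- rowSums(confusion)     # true counts
  predicted <- colSums(confusion)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  sens <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  if (any(support == 0))
    warning(sum(support == 0), " categor(ies) with zero support ",
            "contribute 0 to the aggregate", call. = FALSE)
  per_category <- data.frame(
    category = rownames(confusion), support = as.integer(support),
    precision = prec, sensitivity = sens, f1 = f1,
    row.names = NULL, stringsAsFactors = FALSE)
  agg <- switch(averaging,
    weighted = {
      w <- support / total
      c(precision = sum(w * prec), sensitivity = sum(w * sens),
        f1 = sum(w * f1))
    },
    macro = c(precision = mean(prec), sensitivity = mean(sens),
              f1 = mean(f1)),
    micro = {
      p <- sum(tp) / total
      c(precision = p, sensitivity = p, f1 = p)
    })
  list(precision = unname(agg["precision"]),
       sensitivity = unname(agg["sensitivity"]),
       f1 = unname(agg["f1"]),
       averaging = averaging, per_category = per_category)
}

#' Top-k concordance of ranked predictions
#'
#' Fraction of records whose true category appears among the `k`
#' highest-confidence predicted categories.
#'
#' @param true Character vector of true categories.
#' @param ranked Matrix of predicted categories, one row per record,
#'   columns ordered best-first (as from [rank_predictions()]); or a list
#'   of ranked character vectors.
#' @param k Rank cutoff (default 1).
#' @return Concordance in \[0, 1\].
#' @export
concordance <- function(true, ranked, k = 1) {
  if (k < 1) stop("k must be >= 1")
  if (is.list(ranked)) ranked <- do.call(rbind, lapply(ranked, rbind))
  if (is.null(dim(ranked))) ranked <- matrix(ranked, ncol = 1)
  stopifnot(nrow(ranked) == length(true), ncol(ranked) >= k)
  hit <- vapply(seq_along(true),
                function(i) true[i] %in% ranked[i, seq_len(k)], logical(1))
  mean(hit)
}

#' Partial chance-corrected concordance
#'
#' Rescales a top-k concordance so that random guessing over `n_categories`
#' scores 0: `(C - k/N) / (1 - k/N)`. Negative values mean worse than
#' chance.
#'
#' @param C Concordance in \[0, 1\].
#' @param n_categories Number of possible categories N.
#' @param k Rank cutoff used for `C` (default 1; must be < N).
#' @return PCCC value, at most 1.
#' @export
pccc <- function(C, n_categories, k = 1) {
  stopifnot(C >= 0, C <= 1, k >= 1)
  if (n_categories <= k)
    stop("n_categories must exceed k for chance correction")
  (C - k / n_categories) / (1 - k / n_categories)
}

#' Cause-specific mortality fractions
#'
#' Category counts divided by the total, over the full ordered category
#' list (absent categories get 0).
#'
#' @param labels Character vector of category labels.
#' @param categories Ordered category list.
#' @return Named numeric vector summing to 1.
#' @export
csmf <- function(labels, categories) {
  stopifnot(length(labels) > 0)
  bad <- setdiff(unique(labels), categories)
  if (length(bad))
    stop("labels outside the category list: ", paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = categories))
  stats::setNames(as.numeric(counts) / length(labels), categories)
}

#' CSMF accuracy between two cause distributions
#'
#' `1 - sum(|pred - true|) / (2 * (1 - min(true)))`: total absolute CSMF
#' error normalized by its maximum possible value, so 1 means the
#' predicted population distribution equals the true one and 0 is the
#' worst attainable error.
#'
#' @param true,pred Numeric CSMF vectors over the same ordered category
#'   list (same length and, if named, same names).
#' @return CSMF accuracy in \[0, 1\].
#' @export
csmf_accuracy <- function(true, pred) {
  if (length(true) != length(pred))
    stop("CSMF vectors are over different category lists")
  if (!is.null(names(true)) && !is.null(names(pred)) &&
      !identical(names(true), names(pred)))
    stop("CSMF vectors are over different category lists")
  stopifnot(length(true) >= 2, all(true >= 0), all(pred >= 0),
            abs(sum(true) - 1) < 1e-9, abs(sum(pred) - 1) < 1e-9)
  denom <- 2 * (1 - min(true))
  if (denom == 0) {  # single observed category: defined only at equality
    if (max(abs(pred - true)) < 1e-12) return(1)
    stop("CSMF accuracy undefined: true distribution is a point mass ",
         "and pred differs")
  }
  1 - sum(abs(pred - true)) / denom
}

#' Monte-Carlo mean CSMF accuracy of a chance predictor
#'
#' Two null models are provided, because "chance" has two common readings:
#'
#' * `dataset_null`: per iteration, assign every record a category
#'   uniformly at random and score the resulting CSMF against the fixed
#'   true distribution of `true_labels`. This mirrors randomly assigning
#'   CoD categories to the evaluation set and is the default baseline for
#'   chance-correcting real scoring runs.
#' * `dirichlet_null`: per iteration, draw the true CSMF uniformly from
#'   the probability simplex (flat Dirichlet) over `n_categories` causes
#'   and score the uniform prediction `1/N` against it. As `N` grows the
#'   mean approaches `1 - 1/e ~= 0.632`, the published asymptotic chance
#'   value.
#'
#' @param mode `"dataset_null"` or `"dirichlet_null"`.
#' @param iterations Number of Monte-Carlo iterations (default 10000).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @param true_labels Required for `dataset_null`: the evaluation set's
#'   true category labels.
#' @param categories For `dataset_null`: the ordered category list
#'   (defaults to the distinct labels).
#' @param n_categories Required for `dirichlet_null`: number of causes N
#'   (>= 2).
#' @return The estimated mean chance CSMF accuracy, with attribute
#'   `"se"` (Monte-Carlo standard error).
#' @export
chance_csmfa <- function(mode = c("dataset_null", "dirichlet_null"),
                         iterations = 10000, seed = 1,
                         true_labels = NULL, categories = NULL,
                         n_categories = NULL) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- if (mode == "dataset_null") {
    if (is.null(true_labels)) stop("dataset_null requires true_labels")
    if (is.null(categories)) categories <- sort(unique(true_labels))
    N <- length(categories)
    if (N < 2) stop("need at least 2 categories")
    n <- length(true_labels)
    p_true <- csmf(true_labels, categories)
    denom <- 2 * (1 - min(p_true))
    vapply(seq_len(iterations), function(it) {
      counts <- tabulate(sample.int(N, n, replace = TRUE), nbins = N)
      1 - sum(abs(counts / n - p_true)) / denom
    }, numeric(1))
  } else {
    if (is.null(n_categories) || n_categories < 2)
      stop("dirichlet_null requires n_categories >= 2")
    N <- n_categories
    vapply(seq_len(iterations), function(it) {
      p <- rexp(N)
      p <- p / sum(p)                 # flat Dirichlet via normalized Exp(1)
      1 - sum(abs(1 / N - p)) / (2 * (1 - min(p)))
    }, numeric(1))
  }
  est <- mean(vals)
  if (est <= 0 || est >= 1)
    warning("estimated chance CSMF accuracy outside (0,1)", call. = FALSE)
  structure(est, se = stats::sd(vals) / sqrt(iterations))
}

# save/restore the global RNG state so metric helpers do not disturb
# caller-level reproducibility
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Chance-corrected CSMF accuracy
#'
#' `(csmfa - c) / (1 - c)` where `c` is the mean CSMF accuracy of a chance
#' predictor (see [chance_csmfa()]). Scores 0 at chance performance and
#' negative below chance; 1 remains perfect.
#'
#' @param csmfa CSMF accuracy of the evaluated predictor.
#' @param c Mean chance CSMF accuracy, in (0, 1).
#' @return CCCSMFA value, at most 1.
#' @export
cccsmfa <- function(csmfa, c) {
  if (any(c >= 1) || any(c <= 0)) stop("chance mean c must lie in (0, 1)")
  (csmfa - c) / (1 - c)
}

#' Per-age-group chance means used with the default scheme
#'
#' Preset mean chance CSMF accuracies for the three strata of the default
#' 15/15/5-category scheme (adult .643, child .641, neonate .646),
#' available for table-consistency checks; fresh evaluations normally
#' recompute the baseline from their own records via [chance_csmfa()].
#'
#' @return Named numeric vector over `adult`, `child`, `neonate`.
#' @export
preset_chance_means <- function() {
  c(adult = 0.643, child = 0.641, neonate = 0.646)
}
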