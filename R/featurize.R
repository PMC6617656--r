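age_col_names <- function() paste0(".age_", va_age_groups())

#' Build a vocabulary from a preprocessed corpus
#'
#' The vocabulary fixes the meaning of feature-matrix columns: one column
#' per unique stem, ordered by document frequency (descending) then
#' lexicographically, so rebuilding on the same corpus gives the same
#' ordering. Stems appearing in fewer than `min_df` documents are
#' excluded. Build vocabularies from *training* data only: the
#' cross-validation harness enforces this to avoid leakage.
#'
#' @param tokens A `va_tokens` object from [preprocess_corpus()], or a
#'   plain list of token vectors.
#' @param min_df Minimum document frequency (default 1).
#' @return An object of class `va_vocabulary`: data frame with columns
#'   `stem`, `df` and `index` (dense, 1..V).
#' @export
build_vocabulary <- function(tokens, min_df = 1) {
  if (inherits(tokens, "va_tokens")) tokens <- tokens$tokens
  stopifnot(is.list(tokens), min_df >= 1)
  if (!length(tokens) || !any(lengths(tokens) > 0))
    stop("cannot build a vocabulary from an empty corpus")
  df <- table(unlist(lapply(tokens, unique), use.names = FALSE))
  df <- df[df >= min_df]
  if (!length(df)) stop("no stem reaches min_df = ", min_df)
  ord <- order(-as.integer(df), names(df), method = "radix")
  vocab <- data.frame(stem = names(df)[ord],
                      df = as.integer(df)[ord],
                      index = seq_along(ord),
                      stringsAsFactors = FALSE)
  class(vocab) <- c("va_vocabulary", "data.frame")
  vocab
}

#' Word-count feature matrix with age-group indicator
#'
#' One row per record: integer counts of each vocabulary stem in the
#' record's token stream (out-of-vocabulary stems are ignored), plus three
#' one-hot columns encoding the age group. The three age columns are
#' treated as a single logical "age" feature downstream: they are always
#' retained by feature selection.
#'
#' @param tokens A `va_tokens` object or list of token vectors.
#' @param vocab A [build_vocabulary()] result.
#' @param age_group Character vector of age groups, one per record.
#' @return A sparse `dgCMatrix` (rows = records, in corpus order) with
#'   attribute `"age_cols"` marking the indicator columns.
#' @export
count_features <- function(tokens, vocab, age_group) {
  ids <- NULL
  if (inherits(tokens, "va_tokens")) {
    ids <- tokens$record_id
    tokens <- tokens$tokens
  }
  stopifnot(inherits(vocab, "va_vocabulary"),
            length(age_group) == length(tokens),
            all(age_group %in% va_age_groups()))
  n <- length(tokens)
  V <- nrow(vocab)
  tok_i <- rep.int(seq_len(n), lengths(tokens))
  tok_j <- match(unlist(tokens, use.names = FALSE), vocab$stem)
  keep <- !is.na(tok_j)
  counts <- Matrix::sparseMatrix(i = tok_i[keep], j = tok_j[keep],
                                 x = 1, dims = c(n, V))
  age <- Matrix::sparseMatrix(
    i = seq_len(n), j = match(age_group, va_age_groups()),
    x = 1, dims = c(n, 3L))
  X <- cbind(counts, age)
  dimnames(X) <- list(ids, c(vocab$stem, age_col_names()))
  attr(X, "age_cols") <- V + seq_len(3L)
  X
}

#' One-way ANOVA F-value of one feature across categories
#'
#' The ratio of between-category variance of the feature means to the
#' pooled within-category variance:
#' \deqn{F = \frac{\sum_g n_g(\bar x_g - \bar x)^2 / (G-1)}
#'             {\sum_g \sum_i (x_{gi} - \bar x_g)^2 / (n-G)}}
#' Degenerate cases: zero within-class variance with differing class means
#' gives `Inf` (such a feature separates classes perfectly and ranks
#' first); an all-constant feature gives 0 (ranks last).
#'
#' @param x Numeric feature values, one per record.
#' @param labels Category label per record (at least two distinct).
#' @return Non-negative F value (possibly `Inf`).
#' @export
anova_f <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  as.numeric(anova_f_all(matrix(as.numeric(x), ncol = 1), labels))
}

#' ANOVA F-values for every column of a feature matrix
#'
#' Vectorized form of [anova_f()] over the columns of a (sparse or dense)
#' matrix.
#'
#' @param X Numeric matrix, rows = records.
#' @param labels Category label per record.
#' @return Numeric vector of F values, one per column.
#' @export
anova_f_all <- function(X, labels) {
  labels <- as.factor(labels)
  g <- droplevels(labels)
  G <- nlevels(g)
  if (G < 2) stop("anova_f requires at least two categories")
  n <- length(g)
  ind <- Matrix::sparseMatrix(i = as.integer(g), j = seq_len(n), x = 1,
                              dims = c(G, n))
  S <- as.matrix(ind %*% X)            # per-group sums, G x V
  Q <- as.matrix(ind %*% (X * X))      # per-group sums of squares
  ng <- as.numeric(table(g))
  tot <- colSums(S)
  between <- colSums(S^2 / ng) - tot^2 / n
  within <- colSums(Q) - colSums(S^2 / ng)
  # guard FP noise around exact zeros of integer-count data
  scale <- pmax(colSums(Q), 1)
  between[between < scale * 1e-12] <- 0
  within[within < scale * 1e-12] <- 0
  f <- ifelse(within == 0,
              ifelse(between == 0, 0, Inf),
              (between / (G - 1)) / (within / (n - G)))
  stats::setNames(as.numeric(f), colnames(X))
}

#' Select the top-k features by ANOVA F-value
#'
#' Ranks the word-count columns by F-value (ties broken by lower column
#' index) and keeps the best `k`; the three age-indicator columns are
#' always retained in addition, since they encode a single logical feature
#' that selection never drops. Selection is a pure column subset: values
#' are never altered.
#'
#' @param X Feature matrix from [count_features()].
#' @param labels Category label per record.
#' @param k Number of word features to keep (capped at the number of word
#'   columns, with a warning).
#' @return A list of class `va_selection`: `ranking` (data frame `column`,
#'   `stem`, `f_value`, `selected`), `selected` (kept column indices into
#'   `X`, ascending) and `matrix` (the reduced matrix, with its own
#'   `"age_cols"` attribute).
#' @export
select_top_k <- function(X, labels, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer")
  k <- as.integer(k)
  age_cols <- attr(X, "age_cols")
  word_cols <- setdiff(seq_len(ncol(X)), age_cols)
  if (k > length(word_cols)) {
    warning("k = ", k, " exceeds the ", length(word_cols),
            " available word features; keeping all", call. = FALSE)
    k <- length(word_cols)
  }
  f <- anova_f_all(X[, word_cols, drop = FALSE], labels)
  ord <- order(-f, seq_along(f))          # ties: lower column index first
  top <- sort(word_cols[ord[seq_len(k)]])
  keep <- c(top, age_cols)
  reduced <- X[, keep, drop = FALSE]
  attr(reduced, "age_cols") <- match(age_cols, keep)
  ranking <- data.frame(column = word_cols,
                        stem = colnames(X)[word_cols],
                        f_value = as.numeric(f),
                        selected = word_cols %in% top,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, selected = keep, matrix = reduced),
            class = "va_selection")
}

#' @export
print.va_selection <- function(x, ...) {
  cat("Feature selection: kept ", sum(x$ranking$selected), " of ",
      nrow(x$ranking), " word features (+ age indicator)\n", sep = "")
  top <- x$ranking[x$ranking$selected, ]
  top <- top[order(-top$f_value), ]
  cat("top stems:", paste(head(top$stem, 10), collapse = ", "), "\n")
  invisible(x)
}
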