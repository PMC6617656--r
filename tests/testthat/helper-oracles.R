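# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force one-way variance-ratio: two-pass loops over groups.
brute_force_f <- function(x, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  G <- length(groups)
  n <- length(x)
  grand <- mean(x)
  between <- 0
  within <- 0
  for (g in groups) {
    xg <- x[labels == g]
    between <- between + length(xg) * (mean(xg) - grand)^2
    within <- within + sum((xg - mean(xg))^2)
  }
  if (within == 0) {
    if (between == 0) return(0)
    return(Inf)
  }
  (between / (G - 1)) / (within / (n - G))
}

# All strings at Levenshtein distance exactly 1 from a word (lowercase
# alphabet): exhaustive enumeration of substitutions, deletions and
# insertions.
edit1_neighbourhood <- function(word) {
  ch <- strsplit(word, "")[[1]]
  n <- length(ch)
  out <- character(0)
  for (i in seq_len(n)) {
    for (l in letters[letters != ch[i]]) {
      s <- ch; s[i] <- l
      out <- c(out, paste(s, collapse = ""))
    }
    out <- c(out, paste(ch[-i], collapse = ""))
  }
  for (i in 0:n) {
    for (l in letters) {
      out <- c(out, paste(c(ch[seq_len(i)], l, ch[seq_len(n - i) + i]),
                          collapse = ""))
    }
  }
  setdiff(unique(out), word)
}

# 40-record linearly separable toy: category A narratives use only
# "cough", category B only "fever".
separable_toy <- function(n_per_class = 20, reps = 3) {
  toks <- c(replicate(n_per_class, list(rep("cough", reps))),
            replicate(n_per_class, list(rep("fever", reps))))
  y <- rep(c("A", "B"), each = n_per_class)
  vocab <- build_vocabulary(toks)
  X <- count_features(toks, vocab, rep("adult", 2 * n_per_class))
  rownames(X) <- sprintf("R%02d", seq_len(2 * n_per_class))
  list(X = X, y = y, vocab = vocab)
}

# small labeled corpus written to a temp CSV
tmp_corpus_csv <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("records-", as.integer(runif(1, 1, 1e6)),
                                ".csv"))
  df <- data.frame(
    record_id = c("r1", "r2", "r3"),
    age_group = c("adult", "child", "neonate"),
    narrative = c("fever and cough for three days",
                  "loose motions and vomiting",
                  "born premature and weak"),
    icd10 = c("I50.9", "A09", "P07"),
    category = NA_character_,
    source_tag = "unit-test",
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}
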