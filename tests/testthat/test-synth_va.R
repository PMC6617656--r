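test_that("default CSMFs are valid simplex vectors with the study skew", {
  csmf <- default_synth_csmf()
  for (g in names(csmf)) {
    expect_equal(sum(csmf[[g]]), 1, tolerance = 1e-12)
    expect_true(all(csmf[[g]] > 0))
  }
  expect_equal(max(csmf$adult), csmf$adult[[1]], tolerance = 1e-12)
  expect_gt(max(csmf$adult), 0.25)   # dominant cause ~0.3
  expect_lt(max(csmf$adult), 0.35)
  expect_length(csmf$adult, 15)
  expect_length(csmf$neonate, 5)
})

test_that("every default generator word is covered by the shipped resources", {
  cfg <- generator_config()
  vocab <- generator_vocabulary(cfg)
  known <- c(va_lexicon()$words, default_stopwords())
  expect_length(setdiff(vocab, known), 0)
})

test_that("generator configs validate their inputs", {
  expect_error(generator_config(lambda = 1.5))
  expect_error(generator_config(rho = 1))
  bad_csmf <- default_synth_csmf()
  bad_csmf$adult <- bad_csmf$adult * 2
  expect_error(generator_config(csmf = bad_csmf), "summing to 1")
  lex <- default_cause_lexicons()
  lex[["Diarrhea"]] <- NULL
  expect_error(generator_config(cause_lexicons = lex), "Diarrhea")
})

test_that("generated corpora hit the configured sizes and label space", {
  cfg <- generator_config(n = c(adult = 100, child = 50, neonate = 30),
                          seed = 17)
  synth <- generate_corpus(cfg)
  corp <- synth$records
  expect_s3_class(corp, "va_corpus")
  expect_identical(sum(corp$age_group == "adult"), 100L)
  expect_identical(sum(corp$age_group == "child"), 50L)
  expect_identical(sum(corp$age_group == "neonate"), 30L)
  validate_corpus(corp, default_scheme())
  expect_false(anyNA(corp$category))
  expect_true(all(corp$source_tag == "synthetic"))
})

test_that("realized label fractions track the configured CSMF at n = 1000", {
  cfg <- generator_config(n = c(adult = 1000, child = 0, neonate = 0),
                          seed = 23)
  synth <- generate_corpus(cfg)
  realized <- csmf(synth$records$category,
                   scheme_categories(default_scheme(), "adult"))
  expect_true(all(abs(realized - cfg$csmf$adult) < 0.05))
  expect_equal(unname(realized),
               unname(synth$manifest$realized_csmf$adult))
})

test_that("generation is byte-identical under one seed", {
  cfg <- generator_config(n = c(adult = 40, child = 20, neonate = 10),
                          seed = 31)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$manifest$body, s2$manifest$body)
  expect_identical(s1$manifest$corruption_log, s2$manifest$corruption_log)
  cfg2 <- generator_config(n = c(adult = 40, child = 20, neonate = 10),
                           seed = 32)
  expect_false(identical(generate_corpus(cfg2)$records$narrative,
                         s1$records$narrative))
})

test_that("with rho = 0 and lambda = 0 every body token is cause-specific", {
  cfg <- generator_config(n = c(adult = 50, child = 0, neonate = 20),
                          lambda = 0, rho = 0, seed = 7)
  synth <- generate_corpus(cfg)
  expect_identical(nrow(synth$manifest$corruption_log), 0L)
  for (i in seq_len(nrow(synth$records))) {
    id <- synth$records$record_id[i]
    lex <- cfg$cause_lexicons[[synth$records$category[i]]]
    expect_length(setdiff(synth$manifest$body[[id]], lex), 0)
    expect_identical(synth$manifest$body[[id]],
                     synth$manifest$body_corrupted[[id]])
  }
})

test_that("body lengths respect the configured range", {
  cfg <- generator_config(n = c(adult = 200, child = 0, neonate = 0),
                          length_range = c(min = 6, mean = 14, max = 40),
                          seed = 3)
  synth <- generate_corpus(cfg)
  lens <- lengths(synth$manifest$body)
  expect_gte(min(lens), 6)
  expect_lte(max(lens), 40)
  expect_gt(mean(lens), 8)   # centred near the configured mean
  expect_lt(mean(lens), 20)
})

test_that("inject_misspellings at rho = 0 is the identity", {
  toks <- c("fever", "cough", "pain")
  out <- inject_misspellings(toks, 0, seed = 1)
  expect_identical(as.character(out), toks)
  expect_identical(nrow(attr(out, "log")), 0L)
})

test_that("injected corruptions are single edits and fully logged", {
  set.seed(12)
  toks <- rep(c("fever", "breathless", "jaundice", "pain"), 50)
  out <- inject_misspellings(toks, 0.5, seed = 41)
  log <- attr(out, "log")
  expect_gt(nrow(log), 20)
  # the log names exactly the positions that changed
  changed <- which(as.character(out) != toks)
  expect_identical(log$index, changed)
  expect_identical(log$original, toks[changed])
  expect_identical(log$corrupted, as.character(out)[changed])
  # every corruption is one substitution, deletion, insertion or
  # transposition: generalized edit distance 1 (adist counts a
  # transposition as distance 2 without the flag, so check both)
  d <- mapply(function(a, b) as.integer(utils::adist(a, b)),
              log$original, log$corrupted)
  swap_like <- mapply(function(a, b)
    nchar(a) == nchar(b) &&
      identical(sort(strsplit(a, "")[[1]]), sort(strsplit(b, "")[[1]])),
    log$original, log$corrupted)
  expect_true(all(d == 1 | (d == 2 & swap_like)))
})

test_that("misspelling injection is seed-reproducible", {
  toks <- rep(c("fever", "cough"), 25)
  expect_identical(as.character(inject_misspellings(toks, 0.3, seed = 6)),
                   as.character(inject_misspellings(toks, 0.3, seed = 6)))
})

test_that("preprocessing restores >= 90% of corruptions at rho = 0.1", {
  cfg <- generator_config(n = c(adult = 300, child = 0, neonate = 0),
                          rho = 0.1, seed = 19)
  synth <- generate_corpus(cfg)
  log <- synth$manifest$corruption_log
  expect_gt(nrow(log), 100)
  lex <- va_lexicon(base = generator_vocabulary(cfg))
  fixed <- correct_spelling(log$corrupted, lex,
                            extra_known = default_stopwords())
  restorable <- is_alpha_token(log$corrupted) & nchar(log$corrupted) >= 3
  restored <- as.character(fixed) == log$original
  expect_gte(mean(restored[restorable]), 0.9)
})

test_that("disjoint cause lexicons are pairwise disjoint, also by stem", {
  lex <- disjoint_cause_lexicons()
  words <- unlist(lex, use.names = FALSE)
  expect_identical(anyDuplicated(words), 0L)
  stems <- porter_stem(words)
  expect_identical(anyDuplicated(stems), 0L)
  expect_setequal(names(lex),
                  unique(unlist(default_scheme()$categories_by_age_group)))
  expect_true(all(lengths(lex) == 8))
  # deterministic
  expect_identical(lex, disjoint_cause_lexicons())
})

test_that("top ANOVA-ranked stems come from the cause lexicons when noise-free", {
  cfg <- generator_config(n = c(adult = 150, child = 0, neonate = 0),
                          cause_lexicons = disjoint_cause_lexicons(),
                          lambda = 0, rho = 0, seed = 29)
  synth <- generate_corpus(cfg)
  lex <- va_lexicon(base = generator_vocabulary(cfg))
  tokens <- preprocess_corpus(synth$records, lex, default_stopwords())
  vocab <- build_vocabulary(tokens)
  X <- count_features(tokens, vocab, synth$records$age_group)
  sel <- select_top_k(X, synth$records$category, 20)
  top <- sel$ranking$stem[sel$ranking$selected]
  cause_stems <- unique(porter_stem(
    unlist(cfg$cause_lexicons, use.names = FALSE)))
  expect_length(setdiff(top, cause_stems), 0)
})

test_that("realized CSMF distance to the target shrinks with corpus size", {
  dist_for <- function(n, seed) {
    cfg <- generator_config(n = c(adult = n, child = 0, neonate = 0),
                            seed = seed)
    synth <- generate_corpus(cfg)
    realized <- csmf(synth$records$category,
                     scheme_categories(default_scheme(), "adult"))
    sum(abs(realized - cfg$csmf$adult))
  }
  small <- mean(vapply(1:5, function(s) dist_for(100, s), 0))
  large <- mean(vapply(1:5, function(s) dist_for(5000, s), 0))
  expect_lt(large, small)
})

test_that("sensitivity degrades monotonically as lambda dilutes the signal", {
  cfg <- generator_config(n = c(adult = 150, child = 0, neonate = 0),
                          cause_lexicons = disjoint_cause_lexicons(),
                          rho = 0, seed = 43)
  sweep <- signal_sweep(cfg, lambdas = c(0, 0.7, 1), k = 3, seed = 2,
                        chance_iterations = 100)
  sens <- sweep$sensitivity[order(sweep$lambda)]
  expect_identical(nrow(sweep), 3L)
  expect_gte(sens[1], 0.9)            # full signal: near-perfect
  expect_true(all(diff(sens) <= 0.05))  # non-increasing up to fold noise
  expect_lt(sens[3], 0.5)             # no-information limit
})

test_that("synthetic corpora and manifests write to disk", {
  cfg <- generator_config(n = c(adult = 20, child = 0, neonate = 10),
                          seed = 2)
  synth <- generate_corpus(cfg)
  rec <- tempfile(fileext = ".csv")
  man <- tempfile(fileext = ".json")
  write_synth_corpus(synth, rec, man)
  back <- suppressMessages(read_va_records(rec))
  expect_identical(back$narrative, synth$records$narrative)
  m <- jsonlite::fromJSON(man)
  expect_identical(m$seed, 2L)
  expect_equal(m$lambda, cfg$lambda)
  expect_named(m$realized_csmf, c("adult", "neonate"))
})
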