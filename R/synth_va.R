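#' Default skewed cause distributions for synthetic corpora
#'
#' Adult and child strata use a geometric-decay 15-category CSMF whose
#' largest category holds roughly 30% of deaths, matching the qualitative
#' shape of real VA category distributions (a few dominant causes, a long
#' tail). Neonates use an explicit 5-category skew.
#'
#' @return Named list of CSMF vectors per age group over the default
#'   scheme's categories.
#' @export
default_synth_csmf <- function() {
  scheme <- default_scheme()
  w15 <- 0.7^(0:14)
  adult <- stats::setNames(w15 / sum(w15), scheme_categories(scheme, "adult"))
  neo <- stats::setNames(c(0.35, 0.25, 0.18, 0.12, 0.10),
                         scheme_categories(scheme, "neonate"))
  list(adult = adult, child = adult, neonate = neo)
}

#' Default cause-specific symptom lexicons
#'
#' Each category of the default scheme maps to a small vocabulary of
#' symptom and circumstance words a narrative for that cause would use
#' (e.g. jaundice/yellow/abdomen for liver disease, fever/cough/chest for
#' respiratory infection). All words appear in the shipped spelling
#' lexicon, so preprocessing never "corrects" them away. Real narratives
#' overlap more across causes than these defaults do; widen or blend the
#' lists to make the task harder.
#'
#' @return Named list: category -> character vector of words.
#' @export
default_cause_lexicons <- function() {
  list(
    "Acute respiratory infections" =
      c("fever", "cough", "chest", "pain", "breathless", "phlegm",
        "pneumonia", "breathing", "sputum", "cold"),
    "Diarrhea" =
      c("diarrhea", "loose", "motions", "vomiting", "dehydration",
        "stomach", "stool", "water", "weakness"),
    "Pulmonary tuberculosis" =
      c("tuberculosis", "cough", "blood", "sputum", "weight", "loss",
        "night", "sweating", "thin"),
    "Other and unspecified infections" =
      c("fever", "typhoid", "malaria", "chills", "infection",
        "shivering", "headache", "dengue"),
    "Neoplasms" =
      c("cancer", "tumor", "lump", "growth", "chemotherapy", "pain",
        "swelling", "operation"),
    "Nutrition" =
      c("weak", "thin", "appetite", "anemia", "malnutrition", "pale",
        "weakness", "iron"),
    "Cardiovascular disease" =
      c("heart", "chest", "pain", "pressure", "attack",
        "breathlessness", "cardiac", "failure"),
    "Chronic respiratory disease" =
      c("asthma", "wheezing", "breathless", "cough", "chronic",
        "bronchitis", "oxygen"),
    "Liver cirrhosis" =
      c("liver", "alcohol", "jaundice", "yellow", "abdomen", "swelling",
        "cirrhosis", "vomit"),
    "Other non-communicable diseases" =
      c("diabetes", "kidney", "dialysis", "sugar", "urine", "thyroid",
        "ulcer", "gastric"),
    "Road and transport injuries" =
      c("road", "accident", "truck", "bus", "hit", "injury", "fracture",
        "bleeding"),
    "Other injuries" =
      c("fell", "fall", "burn", "burns", "snake", "bite", "drowned",
        "wound"),
    "Ill-defined" =
      c("sudden", "unknown", "old", "age", "unwell", "unconscious",
        "collapsed"),
    "Suicide" =
      c("hanged", "hanging", "poison", "rope", "consumed", "suicide"),
    "Maternal" =
      c("pregnancy", "delivery", "pregnant", "labor", "placenta",
        "eclampsia", "postpartum", "miscarriage"),
    "Prematurity/low birth weight" =
      c("premature", "prematurity", "weight", "low", "small", "born",
        "early"),
    "Neonatal infections" =
      c("fever", "sepsis", "infection", "umbilical", "feeding",
        "septic"),
    "Birth asphyxia/trauma" =
      c("asphyxia", "birth", "cry", "breathe", "delivery", "blue",
        "oxygen"),
    "Ill-defined or cause unknown" =
      c("sudden", "unknown", "unwell", "weak"),
    "Other" =
      c("jaundice", "yellow", "convulsions", "vomiting", "diarrhea"))
}

#' Cause-independent background vocabulary
#' @return Character vector of words mixed into every narrative.
#' @export
default_background_lexicon <- function() {
  c("hospital", "doctor", "village", "home", "treatment", "medicine",
    "morning", "evening", "condition", "family", "days", "week",
    "month", "relatives", "admitted", "taken", "local", "visited",
    "checked", "advised")
}

synth_templates <- function() {
  list(intro = c("the patient suffered from",
                 "the deceased had",
                 "he complained of",
                 "she complained of",
                 "the person was suffering from"),
       outro = c("and passed away",
                 "and died at home",
                 "before death",
                 "and could not recover"))
}

#' Configure the synthetic VA corpus generator
#'
#' The generator emulates the observable features of physician-coded VA
#' narrative corpora: short noisy English narratives built from
#' cause-specific symptom vocabulary diluted by cause-independent
#' background words, per-token misspellings, three age strata, and skewed
#' cause distributions. Templates are cause-independent, so the gold label
#' leaks into the text only through the symptom lexicon.
#'
#' @param scheme Active [cod_scheme()].
#' @param n Named integer vector: records per age group (default
#'   `c(adult = 1200, child = 500, neonate = 300)`, echoing the dominance
#'   of adult records in real VA corpora).
#' @param csmf Named list of per-age-group CSMF vectors over the scheme's
#'   categories (default [default_synth_csmf()]).
#' @param cause_lexicons Named list category -> word vector.
#' @param background Background word vector.
#' @param lambda Mixing weight in \[0, 1\]: probability a body token is
#'   background rather than cause-specific (default 0.3; `lambda = 1` is
#'   the no-information limit).
#' @param length_range `c(min, mean, max)` body tokens per narrative.
#' @param rho Per-token misspelling probability in \[0, 1) (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `va_generator_config`.
#' @export
generator_config <- function(scheme = default_scheme(),
                             n = c(adult = 1200, child = 500, neonate = 300),
                             csmf = default_synth_csmf(),
                             cause_lexicons = default_cause_lexicons(),
                             background = default_background_lexicon(),
                             lambda = 0.3,
                             length_range = c(min = 6, mean = 14, max = 40),
                             rho = 0.05,
                             seed = 1L) {
  stopifnot(inherits(scheme, "cod_scheme"),
            lambda >= 0, lambda <= 1, rho >= 0, rho < 1,
            length_range[1] >= 1,
            length_range[1] <= length_range[2],
            length_range[2] <= length_range[3])
  n <- n[va_age_groups()[va_age_groups() %in% names(n)]]
  for (g in names(n)) {
    if (n[[g]] == 0) next
    cats <- scheme_categories(scheme, g)
    p <- csmf[[g]]
    if (is.null(p) || length(p) != length(cats) ||
        abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("csmf for '", g, "' must be a non-negative vector over the ",
           length(cats), " scheme categories summing to 1")
    missing_lex <- cats[p > 0 & !(cats %in% names(cause_lexicons))]
    missing_lex <- c(missing_lex,
                     cats[vapply(cats, function(cc)
                       !is.null(cause_lexicons[[cc]]) &&
                         length(cause_lexicons[[cc]]) == 0, logical(1))])
    if (length(missing_lex))
      stop("no cause lexicon for categor(ies): ",
           paste(unique(missing_lex), collapse = ", "))
  }
  structure(list(scheme = scheme, n = n, csmf = csmf,
                 cause_lexicons = cause_lexicons, background = background,
                 lambda = lambda, length_range = length_range, rho = rho,
                 seed = as.integer(seed)),
            class = "va_generator_config")
}

#' All words a generator configuration can emit
#'
#' Useful as the spelling-correction lexicon when preprocessing a
#' synthetic corpus.
#'
#' @param config A [generator_config()].
#' @return Sorted character vector of cause, background and template
#'   words.
#' @export
generator_vocabulary <- function(config) {
  stopifnot(inherits(config, "va_generator_config"))
  tpl <- unlist(strsplit(unlist(synth_templates()), " "), use.names = FALSE)
  sort(unique(c(unlist(config$cause_lexicons, use.names = FALSE),
                config$background, tpl)))
}

#' Corrupt tokens with random single-edit misspellings
#'
#' Each alphabetic token is independently corrupted with probability
#' `rho` by one random edit: substitute, delete, insert, or transpose
#' (uniform over the four types; the rate applies per token, not per
#' character). Corruptions are logged so downstream spelling-correction
#' efficacy can be measured.
#'
#' @param tokens Character vector.
#' @param rho Corruption probability per token, in \[0, 1).
#' @param seed Optional seed (the caller's RNG stream is used when
#'   `NULL`).
#' @return Tokens with attribute `"log"`: data frame `index`, `original`,
#'   `corrupted` for every token that actually changed.
#' @export
inject_misspellings <- function(tokens, rho, seed = NULL) {
  stopifnot(rho >= 0, rho < 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  out <- tokens
  hits <- which(is_alpha_token(tokens) & runif(length(tokens)) < rho)
  for (i in hits) {
    w <- tokens[i]
    n <- nchar(w)
    type <- sample(c("sub", "del", "ins", "swap"), 1)
    if (n < 2 && type %in% c("del", "swap")) type <- "sub"
    out[i] <- switch(type,
      sub = {
        p <- sample.int(n, 1)
        repl <- sample(setdiff(letters, substr(w, p, p)), 1)
        paste0(substr(w, 1, p - 1), repl, substr(w, p + 1, n))
      },
      del = {
        p <- sample.int(n, 1)
        paste0(substr(w, 1, p - 1), substr(w, p + 1, n))
      },
      ins = {
        p <- sample.int(n + 1, 1) - 1L
        paste0(substr(w, 1, p), sample(letters, 1), substr(w, p + 1, n))
      },
      swap = {
        p <- sample.int(n - 1, 1)
        paste0(substr(w, 1, p - 1), substr(w, p + 1, p + 1),
               substr(w, p, p), substr(w, p + 2, n))
      })
  }
  changed <- hits[out[hits] != tokens[hits]]
  structure(out, log = data.frame(index = changed,
                                  original = tokens[changed],
                                  corrupted = out[changed],
                                  stringsAsFactors = FALSE))
}

#' Generate a synthetic VA corpus
#'
#' For each record: draw the cause from the configured CSMF, draw a body
#' length, fill the body with a `lambda`-weighted mixture of background
#' and cause-lexicon words, corrupt tokens at rate `rho`, and wrap the
#' body in a cause-independent narrative template. Byte-identical
#' regeneration is guaranteed by the seed recorded in the manifest.
#'
#' @param config A [generator_config()].
#' @return A list of class `va_synth_corpus`: `records` (a labeled
#'   `va_corpus`) and `manifest` (config echo, seed, realized CSMF per
#'   group, clean and corrupted body tokens per record, and the combined
#'   corruption log).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "va_generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tpl <- synth_templates()
  rows <- list(); body_clean <- list(); body_noisy <- list()
  corruption <- list()
  realized <- list()
  lr <- config$length_range
  for (g in names(config$n)) {
    n_g <- config$n[[g]]
    if (n_g == 0) next
    cats <- scheme_categories(config$scheme, g)
    labels <- sample(cats, n_g, replace = TRUE, prob = config$csmf[[g]])
    realized[[g]] <- csmf(labels, cats)
    for (i in seq_len(n_g)) {
      L <- min(max(lr[[1]] + rpois(1, lr[[2]] - lr[[1]]), lr[[1]]), lr[[3]])
      from_bg <- runif(L) < config$lambda
      lex <- config$cause_lexicons[[labels[i]]]
      body <- character(L)
      if (any(from_bg))
        body[from_bg] <- sample(config$background, sum(from_bg),
                                replace = TRUE)
      if (any(!from_bg))
        body[!from_bg] <- sample(lex, sum(!from_bg), replace = TRUE)
      noisy <- inject_misspellings(body, config$rho)
      id <- sprintf("SYN-%s-%05d", toupper(substr(g, 1, 1)), i)
      log_i <- attr(noisy, "log")
      if (nrow(log_i))
        corruption[[length(corruption) + 1L]] <-
          cbind(record_id = id, log_i)
      narrative <- paste(c(sample(tpl$intro, 1), as.character(noisy),
                           sample(tpl$outro, 1)), collapse = " ")
      narrative <- paste0(narrative, ".")
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = id, age_group = g, narrative = narrative,
        category = labels[i], stringsAsFactors = FALSE)
      body_clean[[id]] <- body
      body_noisy[[id]] <- as.character(noisy)
    }
  }
  records <- do.call(rbind, rows)
  records <- va_corpus(records$record_id, records$age_group,
                       records$narrative, category = records$category,
                       source_tag = "synthetic", scheme = config$scheme)
  corruption <- if (length(corruption)) do.call(rbind, corruption) else
    data.frame(record_id = character(0), index = integer(0),
               original = character(0), corrupted = character(0),
               stringsAsFactors = FALSE)
  structure(list(records = records,
                 manifest = list(config = config, seed = config$seed,
                                 realized_csmf = realized,
                                 body = body_clean,
                                 body_corrupted = body_noisy,
                                 corruption_log = corruption)),
            class = "va_synth_corpus")
}

#' @export
print.va_synth_corpus <- function(x, ...) {
  cat("Synthetic VA corpus: ", nrow(x$records), " records (",
      paste(names(table(x$records$age_group)),
            table(x$records$age_group), sep = "=", collapse = ", "),
      "), ", nrow(x$manifest$corruption_log), " injected misspellings\n",
      sep = "")
  invisible(x)
}

#' Disjoint cause lexicons for identifiability experiments
#'
#' Partitions a pool of real words (drawn from the shipped base lexicon,
#' excluding stopwords, background and template words, and any words
#' whose Porter stems collide) into non-overlapping per-category
#' vocabularies. With these lexicons, zero noise and `lambda = 0`, the
#' corpus is separable by construction.
#'
#' @param scheme Active [cod_scheme()].
#' @param words_per_category Lexicon size per category (default 8).
#' @return Named list category -> word vector, categories of all age
#'   groups covered, pairwise disjoint (also at the stem level).
#' @export
disjoint_cause_lexicons <- function(scheme = default_scheme(),
                                    words_per_category = 8) {
  cats <- unique(unlist(scheme$categories_by_age_group))
  pool <- va_lexicon()$words
  avoid <- c(default_stopwords(), default_background_lexicon(),
             unlist(strsplit(unlist(synth_templates()), " ")))
  pool <- setdiff(pool, avoid)
  pool <- pool[nchar(pool) >= 4]
  stems <- porter_stem(pool)
  pool <- pool[!duplicated(stems) & !(stems %in% avoid)]
  pool <- sort(pool)
  need <- length(cats) * words_per_category
  if (length(pool) < need)
    stop("lexicon pool too small: need ", need, " words, have ",
         length(pool))
  # deterministic partition: every words_per_category-th slice
  idx <- matrix(seq_len(need), nrow = words_per_category)
  out <- lapply(seq_along(cats), function(j) pool[idx[, j]])
  names(out) <- cats
  out
}

#' Sensitivity/CCCSMFA response to the signal-dilution level
#'
#' Reruns the cross-validated experiment at each background-mixing level
#' `lambda`: at `lambda = 0` every body token is cause-specific, at
#' `lambda = 1` the narratives carry no cause signal. Sensitivity is
#' non-increasing in `lambda` in expectation.
#'
#' @param config Base [generator_config()] (its `lambda` is overridden).
#' @param lambdas Numeric vector of mixing levels in \[0, 1\].
#' @param families Classifier families to evaluate.
#' @param k Folds per experiment.
#' @param seed Seed for corpus generation and evaluation.
#' @param ... Passed on to [run_experiment()].
#' @return Data frame: one row per `lambda` x age group x family with
#'   fold-mean `sensitivity` and `cccsmfa`.
#' @export
signal_sweep <- function(config, lambdas, families = "naive_bayes",
                         k = 5, seed = 1, ...) {
  stopifnot(all(lambdas >= 0), all(lambdas <= 1))
  out <- list()
  for (lam in lambdas) {
    cfg <- config
    cfg$lambda <- lam
    corpus <- generate_corpus(cfg)
    lex <- va_lexicon(base = generator_vocabulary(cfg))
    rep <- run_experiment(corpus$records, scheme = cfg$scheme,
                          families = families, k = k, seed = seed,
                          lexicon = lex, ...)
    grid <- report_grid(rep)
    out[[length(out) + 1L]] <-
      cbind(lambda = lam,
            grid[c("age_group", "family", "sensitivity", "cccsmfa")])
  }
  do.call(rbind, out)
}

#' Write a synthetic corpus and its regeneration manifest
#'
#' @param synth A [generate_corpus()] result.
#' @param records_path CSV (or JSONL) path for the records.
#' @param manifest_path JSON path for the manifest (seed, config echo and
#'   realized CSMF; sufficient to regenerate the corpus exactly).
#' @return Invisibly, `records_path`.
#' @export
write_synth_corpus <- function(synth, records_path, manifest_path) {
  stopifnot(inherits(synth, "va_synth_corpus"))
  write_va_records(synth$records, records_path)
  cfg <- synth$manifest$config
  jsonlite::write_json(
    list(seed = cfg$seed,
         scheme = cfg$scheme$name,
         n = as.list(cfg$n),
         csmf = lapply(cfg$csmf, as.list),
         lambda = cfg$lambda, rho = cfg$rho,
         length_range = as.list(cfg$length_range),
         cause_lexicons = cfg$cause_lexicons,
         background = cfg$background,
         realized_csmf = lapply(synth$manifest$realized_csmf, as.list),
         n_corruptions = nrow(synth$manifest$corruption_log)),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(records_path)
}
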