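#' Read a one-term-per-line wordlist resource
#'
#' Blank lines and `#` comment lines are dropped; terms are lowercased.
#'
#' @param path File path.
#' @return Character vector of unique lowercase terms.
#' @export
read_wordlist <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(tolower(x))
}

#' Spelling lexicon: English base plus custom medical terms
#'
#' The lexicon drives spelling correction: tokens found in it pass
#' through unchanged, unknown tokens are replaced by their nearest lexicon
#' entry. Custom terms (domain vocabulary that a general English dictionary
#' lacks) are protected: they are part of the lexicon so they are never
#' "corrected" away. Lookup is case-insensitive (all terms are stored
#' lowercase).
#'
#' @param base Character vector of English word forms, or a path to a
#'   wordlist file. Defaults to the shipped base lexicon.
#' @param custom Character vector or wordlist path of domain terms.
#'   Defaults to the shipped medical term list.
#' @return An object of class `va_lexicon` with elements `words`
#'   (the full lookup set), `base` and `custom`.
#' @export
va_lexicon <- function(base = NULL, custom = NULL) {
  as_words <- function(x, default_file) {
    if (is.null(x)) {
      x <- read_wordlist(system.file("extdata", default_file,
                                     package = "vacoder", mustWork = TRUE))
    } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
      x <- read_wordlist(x)
    }
    unique(tolower(as.character(x)))
  }
  base <- as_words(base, "lexicon_base.txt")
  custom <- as_words(custom, "lexicon_medical.txt")
  structure(list(words = sort(unique(c(base, custom))),
                 base = base, custom = custom),
            class = "va_lexicon")
}

#' @export
print.va_lexicon <- function(x, ...) {
  cat("VA spelling lexicon: ", length(x$words), " terms (",
      length(x$custom), " custom)\n", sep = "")
  invisible(x)
}

#' The default stopword list
#'
#' A fixed list of 160 common English function words (including *and*,
#' *because*, *for*) removed from narratives before stemming. It is a
#' replaceable resource: pass your own file to override.
#'
#' @param path Optional path to a one-word-per-line stopword file.
#' @param quiet Suppress the size message.
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function(path = NULL, quiet = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords_en.txt",
                        package = "vacoder", mustWork = TRUE)
  sw <- read_wordlist(path)
  if (!quiet) message("loaded ", length(sw), " stopwords from ", path)
  sw
}

#' Lowercase and tokenize a narrative, detaching punctuation
#'
#' Splits on whitespace, lowercases, and separates punctuation from words
#' so that e.g. `"Heart failure."` becomes `c("heart", "failure", ".")`.
#' Tokens containing digits (dates such as `13/03/01`, dosages) are kept
#' intact: their internal punctuation is structural, not orthographic.
#'
#' @param text Character vector of narratives.
#' @return For a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
normalize_text <- function(text) {
  one <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    s <- tolower(s)
    parts <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    out <- lapply(parts, function(tok) {
      if (grepl("[0-9]", tok)) return(tok)
      tok <- gsub("([[:punct:]])", " \\1 ", tok)
      strsplit(trimws(tok), "[[:space:]]+")[[1]]
    })
    unlist(out, use.names = FALSE)
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

is_alpha_token <- function(tokens) grepl("^[a-z]+$", tokens)

#' Correct spelling against a lexicon
#'
#' Each alphabetic token not found in the lexicon is replaced by the
#' nearest lexicon entry by Levenshtein edit distance: candidates at
#' distance 1 are preferred over distance 2; ties break by higher corpus
#' frequency (when `freq` is given) then lexicographic order. Punctuation
#' tokens, tokens containing digits, tokens shorter than `min_len`
#' characters, and tokens with no candidate within `max_dist` pass through
#' unchanged. All substitutions are recorded in the `"corrections"`
#' attribute of the result.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param lexicon A [va_lexicon()].
#' @param max_dist Maximum edit distance considered (default 2).
#' @param min_len Tokens shorter than this are never corrected (default 3).
#' @param freq Optional named numeric vector of corpus frequencies for
#'   lexicon words, used as the first tie-break.
#' @param extra_known Additional tokens to treat as correctly spelled
#'   without being replacement candidates (e.g. the stopword list, since
#'   correction runs before stopword removal).
#' @param cache Optional environment used to memoize corrections of
#'   repeated tokens across calls.
#' @return Corrected tokens with attributes `"corrections"` (data frame
#'   `original`, `corrected`, `distance`) and `"unresolved"` (tokens with
#'   no in-range candidate).
#' @export
correct_spelling <- function(tokens, lexicon, max_dist = 2, min_len = 3,
                             freq = NULL, extra_known = character(0),
                             cache = NULL) {
  stopifnot(inherits(lexicon, "va_lexicon"))
  words <- lexicon$words
  wlen <- nchar(words)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lookup <- function(tok) {
    if (!is.null(cache[[tok]])) return(cache[[tok]])
    cand <- words[abs(wlen - nchar(tok)) <= max_dist]
    res <- tok
    if (length(cand)) {
      d <- as.integer(adist(tok, cand))
      dmin <- min(d)
      if (dmin <= max_dist) {
        best <- cand[d == dmin]
        if (length(best) > 1L && !is.null(freq)) {
          f <- freq[best]
          f[is.na(f)] <- 0
          best <- best[f == max(f)]
        }
        res <- sort(best)[1L]
        attr(res, "distance") <- dmin
      }
    }
    cache[[tok]] <- res
    res
  }
  out <- tokens
  fixable <- is_alpha_token(tokens) & nchar(tokens) >= min_len &
    !(tokens %in% words) & !(tokens %in% extra_known)
  log <- list()
  unresolved <- character(0)
  for (i in which(fixable)) {
    res <- lookup(tokens[i])
    if (!identical(as.character(res), tokens[i])) {
      log[[length(log) + 1L]] <- data.frame(
        original = tokens[i], corrected = as.character(res),
        distance = attr(res, "distance"), stringsAsFactors = FALSE)
      out[i] <- as.character(res)
    } else {
      unresolved <- c(unresolved, tokens[i])
    }
  }
  corrections <- if (length(log)) do.call(rbind, log) else
    data.frame(original = character(0), corrected = character(0),
               distance = integer(0), stringsAsFactors = FALSE)
  structure(out, corrections = corrections, unresolved = unique(unresolved))
}

#' Remove stopwords from a token stream
#'
#' Order-preserving filter; the number of removed tokens is recorded in
#' the `"removed"` attribute.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param stopwords Character vector of stopwords.
#' @return Filtered tokens.
#' @export
remove_stopwords <- function(tokens, stopwords = default_stopwords()) {
  keep <- !(tokens %in% stopwords)
  structure(tokens[keep], removed = sum(!keep))
}

#' Stem a token stream
#'
#' Applies the Porter stemmer ([porter_stem()]) to alphabetic tokens;
#' punctuation and digit-bearing tokens pass through. Idempotent.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Stemmed tokens.
#' @export
stem_tokens <- function(tokens) porter_stem(tokens)

#' Preprocess one narrative into stems
#'
#' The full chain: tokenize/lowercase/detach punctuation, correct spelling
#' against the lexicon, drop stopwords, then stem. Punctuation-only tokens
#' are dropped at the end (they carry no bag-of-words signal).
#' Deterministic for fixed resources.
#'
#' @param text A narrative string.
#' @param lexicon A [va_lexicon()].
#' @param stopwords Stopword vector.
#' @param ... Passed on to [correct_spelling()].
#' @return Character vector of stems, with the `"corrections"` attribute
#'   of the spelling step.
#' @export
preprocess_narrative <- function(text, lexicon = va_lexicon(),
                                 stopwords = default_stopwords(), ...) {
  toks <- normalize_text(text)
  toks <- correct_spelling(toks, lexicon, extra_known = stopwords, ...)
  corrections <- attr(toks, "corrections")
  toks <- remove_stopwords(as.character(toks), stopwords)
  toks <- stem_tokens(as.character(toks))
  toks <- toks[is_alpha_token(toks) | grepl("[0-9]", toks)]
  structure(toks, corrections = corrections)
}

#' Preprocess a whole corpus
#'
#' Runs [preprocess_narrative()] over every record, sharing a correction
#' cache so repeated misspellings are resolved once. Records whose
#' narrative reduces to zero tokens are flagged.
#'
#' @param corpus A `va_corpus` data frame.
#' @param lexicon A [va_lexicon()].
#' @param stopwords Stopword vector.
#' @param ... Passed on to [correct_spelling()].
#' @return A list of class `va_tokens`: `record_id`, `tokens` (list of
#'   stem vectors aligned to `record_id`), `corrections` (combined log),
#'   `empty` (ids of records with no usable tokens) and `resource_hash`
#'   (fingerprint of the lexicon + stopword resources).
#' @export
preprocess_corpus <- function(corpus, lexicon = va_lexicon(),
                              stopwords = default_stopwords(), ...) {
  validate_corpus(corpus)
  cache <- new.env(parent = emptyenv())
  logs <- vector("list", nrow(corpus))
  toks <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    t_i <- preprocess_narrative(corpus$narrative[i], lexicon, stopwords,
                                cache = cache, ...)
    logs[[i]] <- attr(t_i, "corrections")
    toks[[i]] <- as.character(t_i)
  }
  corrections <- do.call(rbind, logs)
  empty <- corpus$record_id[lengths(toks) == 0L]
  if (length(empty))
    warning(length(empty), " record(s) reduced to an empty token list",
            call. = FALSE)
  structure(list(record_id = corpus$record_id, tokens = toks,
                 corrections = corrections, empty = empty,
                 resource_hash = resource_hash(lexicon, stopwords)),
            class = "va_tokens")
}

#' @export
print.va_tokens <- function(x, ...) {
  cat("Preprocessed VA corpus: ", length(x$record_id), " records, ",
      nrow(x$corrections), " spelling corrections, resources ",
      x$resource_hash, "\n", sep = "")
  invisible(x)
}

#' Fingerprint of the preprocessing resources
#'
#' MD5 of the concatenated lexicon and stopword lists; any change to the
#' resources changes the hash, which is recorded alongside preprocessed
#' corpora and trained models.
#'
#' @param lexicon A [va_lexicon()].
#' @param stopwords Stopword vector.
#' @return Character MD5 hash.
#' @export
resource_hash <- function(lexicon, stopwords) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c("lexicon", lexicon$words, "stopwords", sort(stopwords)), f)
  unname(tools::md5sum(f))
}
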