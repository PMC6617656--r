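# Porter (1980) suffix-stripping stemmer.
#
# Implemented here because no stemming package is available to this
# package's dependency set; the algorithm is small, fully specified, and
# idempotent on its own output for the token stream produced by
# normalize_text() (lowercase alphabetic words).

# Consonant/vowel profile: TRUE = consonant. 'y' is a consonant only at the
# start of the word or after a vowel.
.porter_cons <- function(ch) {
  n <- length(ch)
  cons <- !(ch %in% c("a", "e", "i", "o", "u"))
  if (n > 1) {
    for (i in 2:n) {
      if (ch[i] == "y") cons[i] <- !cons[i - 1]
    }
  }
  cons
}

# Measure m: the number of vowel->consonant transitions in the stem.
.porter_m <- function(word) {
  if (!nchar(word)) return(0L)
  cons <- .porter_cons(strsplit(word, "", fixed = TRUE)[[1]])
  sum(diff(cons) == 1L)
}

.porter_has_vowel <- function(word) {
  if (!nchar(word)) return(FALSE)
  any(!.porter_cons(strsplit(word, "", fixed = TRUE)[[1]]))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  if (ch[n] != ch[n - 1]) return(FALSE)
  all(.porter_cons(ch)[c(n - 1, n)])
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not
# w, x or y.
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  cons <- .porter_cons(ch)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(ch[n] %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Apply the first matching (suffix, replacement, min_m) rule of a step.
.porter_rules <- function(word, rules) {
  for (r in rules) {
    suf <- r[[1]]
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (.porter_m(stem) > r[[3]]) word <- paste0(stem, r[[2]])
      return(word)
    }
  }
  word
}

.porter_step1 <- function(w) {
  # 1a
  if (endsWith(w, "sses")) w <- .chop(w, 2)
  else if (endsWith(w, "ies")) w <- .chop(w, 2)
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- .chop(w, 1)
  # 1b
  fixup <- FALSE
  if (endsWith(w, "eed")) {
    if (.porter_m(.chop(w, 3)) > 0) w <- .chop(w, 1)
  } else if (endsWith(w, "ed") && .porter_has_vowel(.chop(w, 2))) {
    w <- .chop(w, 2); fixup <- TRUE
  } else if (endsWith(w, "ing") && .porter_has_vowel(.chop(w, 3))) {
    w <- .chop(w, 3); fixup <- TRUE
  }
  if (fixup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !endsWith(w, "l") && !endsWith(w, "s") && !endsWith(w, "z")) {
      w <- .chop(w, 1)
    } else if (.porter_m(w) == 1 && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  # 1c
  if (endsWith(w, "y") && .porter_has_vowel(.chop(w, 1)))
    w <- paste0(.chop(w, 1), "i")
  w
}

.porter_step2_rules <- list(
  list("ational", "ate", 0L), list("tional", "tion", 0L),
  list("enci", "ence", 0L), list("anci", "ance", 0L),
  list("izer", "ize", 0L), list("abli", "able", 0L),
  list("alli", "al", 0L), list("entli", "ent", 0L), list("eli", "e", 0L),
  list("ousli", "ous", 0L), list("ization", "ize", 0L),
  list("ation", "ate", 0L), list("ator", "ate", 0L), list("alism", "al", 0L),
  list("iveness", "ive", 0L), list("fulness", "ful", 0L),
  list("ousness", "ous", 0L), list("aliti", "al", 0L),
  list("iviti", "ive", 0L), list("biliti", "ble", 0L))

.porter_step3_rules <- list(
  list("icate", "ic", 0L), list("ative", "", 0L), list("alize", "al", 0L),
  list("iciti", "ic", 0L), list("ical", "ic", 0L), list("ful", "", 0L),
  list("ness", "", 0L))

.porter_step4 <- function(w) {
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  # longest matching suffix is tried first
  for (suf in sufs[order(nchar(sufs), decreasing = TRUE)]) {
    if (endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.porter_m(stem) > 1) {
        if (suf == "ion" && !(endsWith(stem, "s") || endsWith(stem, "t")))
          return(w)
        return(stem)
      }
      return(w)
    }
  }
  w
}

.porter_step5 <- function(w) {
  if (endsWith(w, "e")) {
    stem <- .chop(w, 1)
    m <- .porter_m(stem)
    if (m > 1 || (m == 1 && !.porter_cvc(stem))) w <- stem
  }
  if (.porter_m(w) > 1 && .porter_double_cons(w) && endsWith(w, "l"))
    w <- .chop(w, 1)
  w
}

#' Porter stem of a single lowercase word
#'
#' Suffix-stripping per the classic five-step Porter algorithm
#' (e.g. `crying` → `cry`, `injuries` → `injuri`). Words shorter than three
#' characters, and tokens containing non-alphabetic characters, are
#' returned unchanged. A single Porter pass is not idempotent (the stem of
#' `advise` is `advis`, whose own stem is `advi`), so passes are iterated
#' to a fixed point: stems are stable identifiers and
#' `porter_stem(porter_stem(x))` equals `porter_stem(x)`.
#'
#' @param word Character vector of tokens.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("crying", "injuries", "failure"))
#' @export
porter_stem <- function(word) {
  one_pass <- function(w) {
    w <- .porter_step1(w)
    w <- .porter_rules(w, .porter_step2_rules)
    w <- .porter_rules(w, .porter_step3_rules)
    w <- .porter_step4(w)
    .porter_step5(w)
  }
  vapply(word, function(w) {
    for (i in 1:10) {
      if (nchar(w) < 3 || !grepl("^[a-z]+$", w)) return(w)
      nxt <- one_pass(w)
      if (identical(nxt, w)) return(w)
      w <- nxt
    }
    w
  }, character(1), USE.NAMES = FALSE)
}
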