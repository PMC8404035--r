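# Porter (1980) stemming algorithm.
#
# The reduction rules operate on a consonant/vowel skeleton: 'y' is a vowel
# when preceded by a consonant, a consonant otherwise; m counts VC runs in
# the [C](VC)^m[V] decomposition of a stem. Each step tries its suffixes
# longest-first and applies at most one rule (longest-match-wins, even when
# the rule's condition then fails). Words of length <= 2 are returned as-is.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!porter_is_cons(chars, i - 1))
  }
  TRUE
}

porter_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return(0L)
  cv <- vapply(seq_along(chars), function(i) porter_is_cons(chars, i), logical(1))
  # count v->c transitions
  m <- 0L
  for (i in seq_along(cv)[-1]) if (!cv[i - 1] && cv[i]) m <- m + 1L
  m
}

porter_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return(FALSE)
  any(!vapply(seq_along(chars), function(i) porter_is_cons(chars, i), logical(1)))
}

porter_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  chars[n] == chars[n - 1] && porter_is_cons(chars, n)
}

# *o: stem ends consonant-vowel-consonant and the final consonant is not w/x/y
porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!porter_is_cons(chars, n) || porter_is_cons(chars, n - 1) ||
      !porter_is_cons(chars, n - 2)) return(FALSE)
  !(chars[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1, n) == suffix
}

porter_stem1 <- function(word) {
  if (nchar(word) <= 2) return(word)

  # Step 1a
  if (endsWith(word, "sses")) {
    word <- sub("sses$", "ss", word)
  } else if (endsWith(word, "ies")) {
    word <- sub("ies$", "i", word)
  } else if (!endsWith(word, "ss") && endsWith(word, "s")) {
    word <- sub("s$", "", word)
  }

  # Step 1b
  step1b_cleanup <- FALSE
  if (endsWith(word, "eed")) {
    stem <- sub("eed$", "", word)
    if (porter_measure(stem) > 0) word <- paste0(stem, "ee")
  } else if (endsWith(word, "ed")) {
    stem <- sub("ed$", "", word)
    if (porter_has_vowel(stem)) { word <- stem; step1b_cleanup <- TRUE }
  } else if (endsWith(word, "ing")) {
    stem <- sub("ing$", "", word)
    if (porter_has_vowel(stem)) { word <- stem; step1b_cleanup <- TRUE }
  }
  if (step1b_cleanup) {
    if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_double_cons(word) &&
               !endsWith(word, "l") && !endsWith(word, "s") && !endsWith(word, "z")) {
      word <- substr(word, 1, nchar(word) - 1)
    } else if (porter_measure(word) == 1 && porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (endsWith(word, "y")) {
    stem <- substr(word, 1, nchar(word) - 1)
    if (porter_has_vowel(stem)) word <- paste0(stem, "i")
  }

  # Step 2 (m > 0)
  step2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
    c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
    c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
    c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
  )
  word <- porter_rule_table(word, step2, min_m = 1L)

  # Step 3 (m > 0)
  step3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  word <- porter_rule_table(word, step3, min_m = 1L)

  # Step 4 (m > 1): bare deletions; "ion" only after s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
             "ic", "ou")
  for (suf in step4[order(-nchar(step4))]) {
    if (porter_ends(word, suf)) {
      stem <- substr(word, 1, nchar(word) - nchar(suf))
      ok <- porter_measure(stem) > 1
      if (suf == "ion") ok <- ok && (endsWith(stem, "s") || endsWith(stem, "t"))
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (endsWith(word, "e")) {
    stem <- substr(word, 1, nchar(word) - 1)
    m <- porter_measure(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) word <- stem
  }
  # Step 5b
  if (porter_measure(word) > 1 && porter_double_cons(word) && endsWith(word, "l")) {
    word <- substr(word, 1, nchar(word) - 1)
  }
  word
}

porter_rule_table <- function(word, rules, min_m) {
  sufs <- vapply(rules, `[`, character(1), 1)
  for (j in order(-nchar(sufs))) {
    suf <- rules[[j]][1]
    if (porter_ends(word, suf)) {
      stem <- substr(word, 1, nchar(word) - nchar(suf))
      if (porter_measure(stem) >= min_m) word <- paste0(stem, rules[[j]][2])
      break
    }
  }
  word
}

#' Porter stemmer
#'
#' Stems lowercase word tokens with the classic Porter algorithm, so that
#' e.g. "pained", "painful" and "pains" all reduce to "pain". Tokens
#' containing characters outside `[a-z]` (digits, punctuation) are returned
#' unchanged: numerals such as grading terms are meaningful as-is.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems, same length.
#' @examples
#' porter_stem(c("pained", "painful", "pains"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0) return(character())
  uniq <- unique(words)
  stems <- vapply(uniq, function(w) {
    if (grepl("[^a-z]", w)) w else porter_stem1(w)
  }, character(1), USE.NAMES = FALSE)
  stems[match(words, uniq)]
}
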