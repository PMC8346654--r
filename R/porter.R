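# Porter's suffix-stripping algorithm (the original 1980 rule set).
# Words are assumed lowercase; words of length <= 2 or containing
# non-letter characters are returned unchanged.

pstem_chop <- function(w, n) substr(w, 1L, nchar(w) - n)

# TRUE = consonant, per position; 'y' is a consonant at word start or after
# a vowel, a vowel after a consonant.
pstem_cv <- function(w) {
  chs <- strsplit(w, "", fixed = TRUE)[[1L]]
  out <- logical(length(chs))
  for (i in seq_along(chs)) {
    ch <- chs[i]
    out[i] <-
      if (ch %in% c("a", "e", "i", "o", "u")) FALSE
      else if (ch == "y") { if (i == 1L) TRUE else !out[i - 1L] }
      else TRUE
  }
  out
}

# m in the [C](VC)^m[V] decomposition
pstem_measure <- function(w) {
  if (!nchar(w)) return(0L)
  r <- rle(pstem_cv(w))$values
  if (length(r) < 2L) return(0L)
  sum(!r[-length(r)] & r[-1L])
}

pstem_has_vowel <- function(w) nchar(w) > 0L && any(!pstem_cv(w))

pstem_ends_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) &&
    pstem_cv(w)[n]
}

# *o condition: ends consonant-vowel-consonant, final consonant not w/x/y
pstem_ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  p <- pstem_cv(w)
  p[n - 2L] && !p[n - 1L] && p[n] && !(substr(w, n, n) %in% c("w", "x", "y"))
}

# Rule tables: suffix -> replacement; within a step only the longest
# matching suffix is considered (so tables are ordered by suffix length).
pstem_order_rules <- function(rules) {
  rules[order(-nchar(names(rules)))]
}

pstem_step2_rules <- pstem_order_rules(c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
))

pstem_step3_rules <- pstem_order_rules(c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = ""
))

pstem_step4_suffixes <- names(pstem_order_rules(stats::setNames(
  rep("", 19L),
  c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
    "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
)))

# Apply the longest matching rule of a table if cond holds on the stem;
# a matching suffix whose condition fails still terminates the step.
pstem_apply_rules <- function(w, rules, min_m) {
  for (i in seq_along(rules)) {
    suf <- names(rules)[i]
    if (endsWith(w, suf)) {
      stem <- pstem_chop(w, nchar(suf))
      if (pstem_measure(stem) > min_m) w <- paste0(stem, rules[[i]])
      return(w)
    }
  }
  w
}

pstem_word <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) w <- pstem_chop(w, 2L)
  else if (endsWith(w, "ies")) w <- pstem_chop(w, 2L)
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- pstem_chop(w, 1L)

  # step 1b: -eed / -ed / -ing
  cleanup <- FALSE
  if (endsWith(w, "eed")) {
    if (pstem_measure(pstem_chop(w, 3L)) > 0L) w <- pstem_chop(w, 1L)
  } else if (endsWith(w, "ed")) {
    stem <- pstem_chop(w, 2L)
    if (pstem_has_vowel(stem)) { w <- stem; cleanup <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- pstem_chop(w, 3L)
    if (pstem_has_vowel(stem)) { w <- stem; cleanup <- TRUE }
  }
  if (cleanup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz"))
      w <- paste0(w, "e")
    else if (pstem_ends_double_cons(w) &&
             !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))
      w <- pstem_chop(w, 1L)
    else if (pstem_measure(w) == 1L && pstem_ends_cvc(w))
      w <- paste0(w, "e")
  }

  # step 1c: terminal y -> i when the stem has a vowel
  if (endsWith(w, "y") && pstem_has_vowel(pstem_chop(w, 1L)))
    w <- paste0(pstem_chop(w, 1L), "i")

  # steps 2-3: double/standard suffixes, condition m > 0
  w <- pstem_apply_rules(w, pstem_step2_rules, min_m = 0L)
  w <- pstem_apply_rules(w, pstem_step3_rules, min_m = 0L)

  # step 4: residual suffixes, condition m > 1 (-ion also needs s/t stem)
  for (suf in pstem_step4_suffixes) {
    if (endsWith(w, suf)) {
      stem <- pstem_chop(w, nchar(suf))
      ok <- pstem_measure(stem) > 1L
      if (suf == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop terminal e
  if (endsWith(w, "e")) {
    stem <- pstem_chop(w, 1L)
    m <- pstem_measure(stem)
    if (m > 1L || (m == 1L && !pstem_ends_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l for m > 1
  if (pstem_measure(w) > 1L && pstem_ends_double_cons(w) && endsWith(w, "l"))
    w <- pstem_chop(w, 1L)

  w
}

#' Porter stemmer
#'
#' Reduces English words to stems with Porter's suffix-stripping algorithm
#' (the original rule set, e.g. `expression -> express`,
#' `embryos -> embryo`, `hopping -> hop`). Input is expected lowercase;
#' words shorter than three characters or containing non-letter characters
#' pass through unchanged. The stemmer is idempotent:
#' `porter_stem(porter_stem(w))` equals `porter_stem(w)`.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("expression", "mouse", "embryos"))
porter_stem <- function(words) {
  if (!length(words)) return(character(0))
  u <- unique(words)
  s <- vapply(u, pstem_word, character(1L), USE.NAMES = FALSE)
  s[match(words, u)]
}
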