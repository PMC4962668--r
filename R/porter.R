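# Porter (1980) stemming algorithm, used by the stemming sieve and by the
# token-level features of the relation classifier. Input is expected to be a
# single lowercase ASCII word; anything else is returned unchanged.

.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of the stem: [C](VC)^m[V]
.p_measure <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .p_is_cons(chars, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  if (length(runs) && runs[1]) runs <- runs[-1]          # leading C
  if (length(runs) && !runs[length(runs)]) runs <- runs[-length(runs)]  # trailing V
  sum(!runs) # number of V runs remaining == number of VC pairs
}

.p_has_vowel <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(FALSE)
  any(vapply(seq_len(n), function(i) !.p_is_cons(chars, i), logical(1)))
}

.p_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && .p_is_cons(chars, n)
}

# *o condition: stem ends cvc where the final c is not w, x or y
.p_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  .p_is_cons(chars, n) && !.p_is_cons(chars, n - 1L) && .p_is_cons(chars, n - 2L) &&
    !(chars[n] %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) &&
    substring(word, nchar(word) - nchar(suffix) + 1L) == suffix
}

.p_stem_part <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

.p_chars <- function(word) strsplit(word, "", fixed = TRUE)[[1]]

# apply first matching rule of a (suffix -> replacement) table, guarded by
# a measure condition on the stem
.p_rule_table <- function(word, table, mcond) {
  for (suf in names(table)) {
    if (.p_ends(word, suf)) {
      stem <- .p_stem_part(word, suf)
      if (mcond(.p_measure(.p_chars(stem)))) {
        return(paste0(stem, table[[suf]]))
      }
      return(word) # longest matching suffix decides, even if condition fails
    }
  }
  word
}

#' Porter stem of a word
#'
#' @param word lowercase ASCII word (character scalar).
#' @return the stemmed word.
#' @examples
#' porter_stem("abortions") # same as porter_stem("abortion")
#' @export
porter_stem <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)

  # Step 1a
  if (.p_ends(word, "sses")) {
    word <- paste0(.p_stem_part(word, "sses"), "ss")
  } else if (.p_ends(word, "ies")) {
    word <- paste0(.p_stem_part(word, "ies"), "i")
  } else if (!.p_ends(word, "ss") && .p_ends(word, "s")) {
    word <- .p_stem_part(word, "s")
  }

  # Step 1b
  did_1b <- FALSE
  if (.p_ends(word, "eed")) {
    stem <- .p_stem_part(word, "eed")
    if (.p_measure(.p_chars(stem)) > 0L) word <- paste0(stem, "ee")
  } else if (.p_ends(word, "ed") && .p_has_vowel(.p_chars(.p_stem_part(word, "ed")))) {
    word <- .p_stem_part(word, "ed"); did_1b <- TRUE
  } else if (.p_ends(word, "ing") && .p_has_vowel(.p_chars(.p_stem_part(word, "ing")))) {
    word <- .p_stem_part(word, "ing"); did_1b <- TRUE
  }
  if (did_1b) {
    if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else {
      ch <- .p_chars(word)
      if (.p_double_cons(ch) && !(ch[length(ch)] %in% c("l", "s", "z"))) {
        word <- substr(word, 1L, nchar(word) - 1L)
      } else if (.p_measure(ch) == 1L && .p_cvc(ch)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (.p_ends(word, "y") && .p_has_vowel(.p_chars(.p_stem_part(word, "y")))) {
    word <- paste0(.p_stem_part(word, "y"), "i")
  }

  # Step 2 (m > 0)
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
             ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
             alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
             aliti = "al", iviti = "ive", biliti = "ble")
  # order by suffix length so the longest suffix matches first
  step2 <- step2[order(-nchar(names(step2)))]
  word <- .p_rule_table(word, as.list(step2), function(m) m > 0L)

  # Step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  step3 <- step3[order(-nchar(names(step3)))]
  word <- .p_rule_table(word, as.list(step3), function(m) m > 0L)

  # Step 4 (m > 1); "ion" additionally needs the stem to end in s or t
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
             "ic", "ou")
  for (suf in step4[order(-nchar(step4))]) {
    if (.p_ends(word, suf)) {
      stem <- .p_stem_part(word, suf)
      ok <- .p_measure(.p_chars(stem)) > 1L
      if (suf == "ion") ok <- ok && grepl("[st]$", stem)
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (.p_ends(word, "e")) {
    stem <- .p_stem_part(word, "e")
    m <- .p_measure(.p_chars(stem))
    if (m > 1L || (m == 1L && !.p_cvc(.p_chars(stem)))) word <- stem
  }
  # Step 5b
  ch <- .p_chars(word)
  if (.p_measure(ch) > 1L && .p_double_cons(ch) && ch[length(ch)] == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  word
}
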