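# Nine-pass sieve coreference resolution over the pool of entity mentions
# and noun phrases of one abstract. Pairs kept by a sieve are coreferent and
# are removed from later sieves; clusters are the connected components of
# the kept pairs. Cluster labels (entity type + concept id) are then
# propagated to noun phrases, which is what turns an inter-sentence relation
# into an intra-sentence candidate.

#' Default hyponym dictionaries for sieve 9
#'
#' Short noun lists that commonly refer back to a chemical ("drug", "dose",
#' ...) or a disease ("disease", "case", "infection", "side effect", ...),
#' resolved against the nearest typed mention within a window of sentences.
#'
#' @param chemical_terms,disease_terms character vectors of hyponym nouns.
#' @param window_sentences sentence window (default 2).
#' @return list of class `hyponym_dictionaries`.
#' @export
hyponym_dictionaries <- function(
    chemical_terms = c("drug", "drugs", "dose", "doses", "agent", "agents",
                       "compound", "medication", "treatment"),
    disease_terms = c("disease", "diseases", "case", "cases", "infection",
                      "side effect", "side effects", "syndrome", "disorder",
                      "condition", "symptom", "symptoms", "complication"),
    window_sentences = 2L) {
  stopifnot(window_sentences >= 0L)
  structure(list(chemical_terms = tolower(chemical_terms),
                 disease_terms = tolower(disease_terms),
                 window_sentences = as.integer(window_sentences)),
            class = "hyponym_dictionaries")
}

.NP_ADJ <- c("JJ", "JJR", "JJS", "ADJ")
.NP_NOUN <- c("NN", "NNS", "NNP", "NNPS", "NOUN", "PROPN")
.NP_NUM <- c("CD", "NUM")
.NP_DET <- c("DT", "DET")

#' Chunk noun phrases in a sentence
#'
#' Greedy left-to-right maximal matches of the POS pattern
#' `determiner? (adjective|noun|number)* noun`; determiners are excluded
#' from the returned span.
#'
#' @param sentence a `cid_sentence` with POS tags attached.
#' @return data.frame with columns `start`, `end` (character offsets),
#'   `from`, `to`, `head` (token indices; head = rightmost noun).
#' @export
chunk_noun_phrases <- function(sentence) {
  tok <- sentence$tokens
  out <- data.frame(start = integer(), end = integer(), from = integer(),
                    to = integer(), head = integer())
  n <- nrow(tok)
  i <- 1L
  while (i <= n) {
    j <- i
    if (!is.na(tok$pos[j]) && tok$pos[j] %in% .NP_DET) j <- j + 1L
    k <- j
    while (k <= n && !is.na(tok$pos[k]) &&
           tok$pos[k] %in% c(.NP_ADJ, .NP_NOUN, .NP_NUM)) k <- k + 1L
    k <- k - 1L
    # trim to end at the last noun of the run
    while (k >= j && !(tok$pos[k] %in% .NP_NOUN)) k <- k - 1L
    if (k >= j) {
      out <- rbind(out, data.frame(start = tok$start[j], end = tok$end[k],
                                   from = j, to = k, head = k))
      i <- k + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Find abbreviation definitions in a document
#'
#' Scans for `(SHORT)` parentheticals (2-10 characters, at least one letter)
#' and validates a candidate long form to the left by strict right-to-left
#' character alignment (each short-form character located in the long form
#' in order, matching last to first, with the first character anchored at a
#' word start). When strict alignment fails, a fallback accepts the single
#' token immediately before the parenthesis if it starts with the short
#' form's first letter and contains all its letters.
#'
#' @param doc a `cid_document` (the raw `doc$text` is scanned).
#' @return named character vector: short form -> long form.
#' @export
find_abbreviations <- function(doc) {
  text <- doc$text
  out <- character()
  m <- gregexpr("\\(\\s*([^()]{1,12}?)\\s*\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  for (ix in seq_along(m)) {
    open <- as.integer(m[ix])
    len <- attr(m, "match.length")[ix]
    short <- trimws(substr(text, open + 1L, open + len - 2L))
    if (nchar(short) < 2L || nchar(short) > 10L) next
    if (!grepl("[A-Za-z]", short)) next
    before <- trimws(substr(text, 1L, open - 1L))
    words <- sc_words(before)
    words <- words[!grepl("^[()]$", words)]
    if (!length(words)) next
    max_words <- min(nchar(short) + 5L, nchar(short) * 2L)
    long <- NA_character_
    for (k in seq_len(min(max_words, length(words)))) {
      cand <- paste(utils::tail(words, k), collapse = " ")
      if (.sh_align(short, cand)) { long <- cand; break }
    }
    if (is.na(long)) {
      # fallback: single preceding token sharing first letter and all letters
      tokcand <- words[length(words)]
      sl <- tolower(strsplit(gsub("[^A-Za-z]", "", short), "")[[1]])
      if (length(sl) &&
          tolower(substr(tokcand, 1L, 1L)) == sl[1] &&
          all(sl %in% strsplit(tolower(tokcand), "")[[1]])) {
        long <- tokcand
      }
    }
    if (!is.na(long) && tolower(long) != tolower(short)) out[short] <- long
  }
  out
}

# Schwartz-Hearst style right-to-left alignment of short form inside long form
.sh_align <- function(short, long) {
  s <- tolower(strsplit(short, "")[[1]])
  s <- s[grepl("[a-z0-9]", s)]
  if (!length(s)) return(FALSE)
  l <- tolower(long)
  lchars <- strsplit(l, "")[[1]]
  j <- length(lchars)
  for (i in rev(seq_along(s))) {
    repeat {
      if (j < 1L) return(FALSE)
      hit <- lchars[j] == s[i]
      if (hit && i == 1L) {
        # first short-form character must anchor a word start
        if (j == 1L || !grepl("[a-z0-9]", lchars[j - 1L])) return(TRUE)
        hit <- FALSE
      }
      j <- j - 1L
      if (hit && i > 1L) break
    }
  }
  FALSE
}

.PREPOSITIONS <- c("of", "in", "on", "for", "with", "to")

#' Grammatical variants of a phrase
#'
#' Generates alternative orderings of a multi-token name: (i) preposition
#' substitution, (ii) preposition drop with substring swap, (iii) last token
#' to the front with an inserted preposition, (iv) first token to the end
#' with a preposition inserted second to last. Determiners are stripped
#' first; the original phrase is never returned.
#'
#' @param phrase character scalar.
#' @param prepositions preposition inventory.
#' @return character vector of variants (possibly empty).
#' @export
grammatical_variants <- function(phrase, prepositions = .PREPOSITIONS) {
  w <- sc_strip_determiners(sc_words(tolower(phrase)))
  out <- character()
  if (length(w) < 2L) return(out)
  pidx <- which(w %in% prepositions)
  for (p in pidx) {
    left <- w[seq_len(p - 1L)]
    right <- w[seq.int(p + 1L, length(w))]
    if (!length(left) || !length(right)) next
    for (q in setdiff(prepositions, w[p])) {          # (i) replace preposition
      out <- c(out, paste(c(left, q, right), collapse = " "))
    }
    out <- c(out, paste(c(right, left), collapse = " "))  # (ii) drop and swap
  }
  if (!length(pidx)) {
    for (q in prepositions) {
      # (iii) last token to front, preposition second
      out <- c(out, paste(c(w[length(w)], q, w[-length(w)]), collapse = " "))
      # (iv) first token to end, preposition second to last
      out <- c(out, paste(c(w[-1L], q, w[1L]), collapse = " "))
    }
  }
  setdiff(unique(out), paste(w, collapse = " "))
}

.NUM_FORMS <- local({
  cardinals <- c("one", "two", "three", "four", "five", "six", "seven",
                 "eight", "nine", "ten", "eleven", "twelve", "thirteen",
                 "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
                 "nineteen", "twenty")
  romans <- tolower(as.character(utils::as.roman(1:20)))
  multiplicatives <- c("single", "double", "triple", "quadruple")
  forms <- list()
  for (v in 1:20) {
    fs <- c(as.character(v), romans[v], cardinals[v])
    if (v <= 4L) fs <- c(fs, multiplicatives[v])
    forms[[length(forms) + 1L]] <- fs
  }
  forms
})

.number_value <- function(token) {
  for (v in seq_along(.NUM_FORMS)) if (token %in% .NUM_FORMS[[v]]) return(v)
  NA_integer_
}

#' Number-form variants of a phrase
#'
#' Every token recognized as a number form (arabic 1-20, roman i-xx,
#' cardinal one-twenty, multiplicative single/double/triple/quadruple) is
#' substituted by each of its other forms, one substitution per variant.
#'
#' @param phrase character scalar.
#' @return character vector of variants (possibly empty).
#' @export
number_variants <- function(phrase) {
  w <- sc_words(tolower(phrase))
  out <- character()
  for (i in seq_along(w)) {
    v <- .number_value(w[i])
    if (is.na(v)) next
    for (f in setdiff(.NUM_FORMS[[v]], w[i])) {
      w2 <- w; w2[i] <- f
      out <- c(out, paste(w2, collapse = " "))
    }
  }
  setdiff(unique(out), paste(w, collapse = " "))
}

.PREFIX_SWAPS <- list(c("macro", "micro"), c("micro", "macro"),
                      c("hyper", "hypo"), c("hypo", "hyper"),
                      c("intra", "inter"), c("inter", "intra"))
.SUFFIX_SWAPS <- list(c("toxicity", "toxic"), c("toxic", "toxicity"),
                      c("emia", "oma"), c("oma", "emia"),
                      c("ic", "y"), c("y", "ic"))
.REMOVABLE_PREFIXES <- c("macro", "micro", "hyper", "hypo", "intra", "inter")
.REMOVABLE_SUFFIXES <- c("toxicity", "toxic", "emia", "oma")

#' Affix variants of a word
#'
#' Applies a fixed affix table: prefix swaps (macro/micro, hyper/hypo,
#' intra/inter) and removals, suffix swaps (-toxicity/-toxic, -emia/-oma,
#' -ic/-y) and removals.
#'
#' @param word character scalar (single token, lowercased internally).
#' @return character vector of variants (possibly empty).
#' @export
affix_variants <- function(word) {
  w <- tolower(word)
  out <- character()
  for (sw in .PREFIX_SWAPS) {
    if (startsWith(w, sw[1]) && nchar(w) > nchar(sw[1])) {
      out <- c(out, paste0(sw[2], substring(w, nchar(sw[1]) + 1L)))
    }
  }
  for (p in .REMOVABLE_PREFIXES) {
    if (startsWith(w, p) && nchar(w) > nchar(p) + 2L) {
      out <- c(out, substring(w, nchar(p) + 1L))
    }
  }
  for (sw in .SUFFIX_SWAPS) {
    if (endsWith(w, sw[1]) && nchar(w) > nchar(sw[1])) {
      out <- c(out, paste0(substr(w, 1L, nchar(w) - nchar(sw[1])), sw[2]))
    }
  }
  for (s in .REMOVABLE_SUFFIXES) {
    if (endsWith(w, s) && nchar(w) > nchar(s) + 2L) {
      out <- c(out, substr(w, 1L, nchar(w) - nchar(s)))
    }
  }
  setdiff(unique(out), w)
}

# affix variants applied token-wise to a phrase
phrase_affix_variants <- function(phrase) {
  w <- sc_words(tolower(phrase))
  out <- character()
  for (i in seq_along(w)) {
    for (v in affix_variants(w[i])) {
      w2 <- w; w2[i] <- v
      out <- c(out, paste(w2, collapse = " "))
    }
  }
  setdiff(unique(out), paste(w, collapse = " "))
}
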