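# Low-level text handling shared by every module. Offsets are 0-based,
# half-open, document-level throughout the package.

.PUNCT_CLASS <- "().,;:!?\"\\[\\]{}"

#' Tokenize a text span
#'
#' Rule-based tokenizer: splits on whitespace and detaches common punctuation
#' characters as single-character tokens. Hyphens and slashes are kept inside
#' tokens. This is the package default; every consumer takes pre-tokenized
#' sentences, so an alternative tokenizer can be substituted upstream.
#'
#' @param text character scalar.
#' @param base integer offset added to all token offsets (0-based).
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open).
#' @export
sc_tokenize <- function(text, base = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  pat <- sprintf("[^%s[:space:]]+|[%s]", .PUNCT_CLASS, .PUNCT_CLASS)
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(
    text = substring(text, starts + 1L, starts + lens),
    start = base + starts,
    end = base + starts + as.integer(lens),
    stringsAsFactors = FALSE
  )
}

# Abbreviations that do not end a sentence when followed by a period.
.SENT_GUARDS <- c("e.g", "i.e", "vs", "etc", "fig", "figs", "dr", "al",
                  "no", "approx", "ca", "cf")

#' Split text into sentence spans
#'
#' Rule-based splitter: a sentence ends at `.`, `?` or `!` followed by
#' whitespace, unless the token preceding the period is on a short
#' abbreviation guard list.
#'
#' @param text character scalar.
#' @param base integer offset added to the returned spans.
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
sc_split_sentences <- function(text, base = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(start = integer(), end = integer())
  if (!nzchar(trimws(text))) return(out)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer()
  for (i in seq_len(n)) {
    if (!(chars[i] %in% c(".", "?", "!"))) next
    if (i < n && !grepl("^[[:space:]]$", chars[i + 1L])) next
    if (chars[i] == ".") {
      prev <- sub(".*?([[:alnum:].]*)$", "\\1", substr(text, max(1L, i - 12L), i - 1L))
      word <- tolower(sub("\\.$", "", prev))
      if (word %in% .SENT_GUARDS) next
      # single capital letter initials ("J. Smith")
      if (grepl("^[A-Z]$", prev)) next
    }
    breaks <- c(breaks, i)
  }
  bounds <- unique(c(0L, breaks, n))
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (e2 > s2) out <- rbind(out, data.frame(start = base + s2, end = base + e2))
  }
  out
}

# determiners stripped before phrase-level matching
.DETERMINERS <- c("the", "a", "an", "this", "that", "these", "those")

sc_strip_determiners <- function(tokens) {
  tokens[!(tolower(tokens) %in% .DETERMINERS)]
}

sc_words <- function(phrase) {
  w <- strsplit(trimws(phrase), "[[:space:]]+")[[1]]
  w[nzchar(w)]
}

# stem a whole phrase token-wise, lowercased
sc_stem_phrase <- function(phrase) {
  paste(vapply(sc_words(tolower(phrase)), porter_stem, character(1)), collapse = " ")
}
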