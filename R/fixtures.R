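# Deterministic synthetic fixtures: toy ontologies, annotated abstracts with
# chain dependency parses, curated-relation tables and special-purpose
# corpora (a linearly separable tagging corpus, random short sentences for
# exhaustive-search checks, and a hand-built document planting one
# coreference pair per sieve). All text is a closed invented vocabulary with
# medical-looking affixes; no real abstracts are shipped.

#' Fixture generator configuration
#'
#' @param seed master seed; every generator is a pure function of its
#'   configuration.
#' @param n_concepts concepts per ontology branch.
#' @param n_docs number of abstracts.
#' @param sentences_per_doc content sentences per abstract (besides the
#'   title sentence).
#' @param inter_sentence_fraction fraction of documents whose planted CID
#'   relation is realized only across sentence boundaries, witnessed by an
#'   anaphoric hyponym ("this complication").
#' @param abbrev_fraction fraction of documents that define a chemical
#'   abbreviation and later assert a relation through the short form only.
#' @param variant_fraction fraction of disease mentions realized as a
#'   pluralized surface variant instead of a dictionary synonym.
#' @param vocab_size size of the filler vocabulary (reserved for future
#'   templates; the template inventory is closed).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 7L, n_concepts = 8L, n_docs = 12L,
                           sentences_per_doc = 4L,
                           inter_sentence_fraction = 0.25,
                           abbrev_fraction = 0.25,
                           variant_fraction = 0, vocab_size = 40L) {
  stopifnot(inter_sentence_fraction >= 0, inter_sentence_fraction <= 1,
            abbrev_fraction >= 0, abbrev_fraction <= 1,
            variant_fraction >= 0, variant_fraction <= 1,
            n_concepts >= 0L, n_docs >= 0L)
  structure(as.list(environment()), class = "fixture_config")
}

.FX_PREFIXES <- c("cardi", "nephr", "hepat", "gastr", "neuro", "dermo",
                  "pulmo", "osteo", "arthro", "vasculo", "glotti", "reno",
                  "myelo", "entero", "cranio", "lympho")
.FX_DIS_SUFFIX <- c("osis", "itis", "opathy", "algia", "oma", "emia")
.FX_CHEM_SUFFIX <- c("ium", "olol", "idine", "ate", "icillin", "omycin")

.FX_VERBS <- c("was", "were", "observed", "monitored", "received", "given",
               "administered", "induced", "caused", "developed", "showed",
               "noted", "treated", "required", "persisted", "suspected",
               "found", "improved", "returned", "prescribed", "remained",
               "confirmed", "diagnosed", "reported")
.FX_ADJS <- c("severe", "acute", "chronic", "blocking", "irregular", "mental",
              "several", "effective", "gastric", "mild")

# closed POS lexicon for fixture text
.fx_pos <- function(tok) {
  lt <- tolower(tok)
  if (lt %in% c("the", "a", "an", "this", "that")) return("DT")
  if (lt %in% c("of", "in", "on", "for", "with", "to", "by", "before", "after")) return("IN")
  if (lt %in% c("and", "or")) return("CC")
  if (lt %in% c("also", "daily", "later")) return("RB")
  if (lt %in% .FX_VERBS) return("VBD")
  if (lt %in% .FX_ADJS) return("JJ")
  if (tok == "(") return("-LRB-")
  if (tok == ")") return("-RRB-")
  if (tok %in% c(".", ",", ";")) return(".")
  if (grepl("^[0-9]+$", lt) || !is.na(.number_value(lt))) return("CD")
  "NN"
}

# chain parse in CoNLL-U form: token 1 is the root, token i attaches to i-1
.fx_conllu <- function(tokens) {
  n <- length(tokens)
  vapply(seq_len(n), function(i) {
    paste(i, tokens[i], tolower(tokens[i]), .fx_pos(tokens[i]), "_", "_",
          if (i == 1L) 0L else i - 1L, if (i == 1L) "root" else "dep",
          "_", "_", sep = "\t")
  }, character(1))
}

.fx_attach <- function(doc) {
  conllu <- character()
  for (sent in doc$sentences) {
    conllu <- c(conllu, .fx_conllu(sent$tokens$text), "")
  }
  attach_parses(doc, conllu)
}

#' Generate a toy ontology
#'
#' Disease-branch (C) concepts cycle through name shapes that give each
#' variant sieve something to resolve: plain names, prepositional names
#' ("X of Y"), numbered names ("type two X") and affixed names
#' ("Xtoxicity"); chemical-branch (D) concepts are plain or multi-token
#' names. Deterministic under the configuration seed.
#'
#' @param cfg a [fixture_config()].
#' @return a `cid_ontology`.
#' @export
make_ontology <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_concepts
  concepts <- data.frame(id = character(), branch = character(),
                         preferred_name = character(), stringsAsFactors = FALSE)
  synonyms <- list()
  if (n > 0L) {
    pre <- rep_len(sample(.FX_PREFIXES), 2L * n)
    for (i in seq_len(n)) {
      id <- sprintf("D%06d", i)
      kind <- (i - 1L) %% 4L
      base <- paste0(pre[i], .FX_DIS_SUFFIX[1L + (i - 1L) %% length(.FX_DIS_SUFFIX)])
      name <- switch(as.character(kind),
                     "0" = base,
                     "1" = paste(base, "of", paste0(pre[i], "um")),
                     "2" = paste("type", c("two", "three")[1L + i %% 2L], base),
                     "3" = paste0(pre[i], "toxicity"))
      syn <- name
      if (kind == 0L && i %% 2L == 0L) syn <- c(syn, paste0(pre[i], "algia"))
      if (kind == 3L) syn <- c(syn, paste0(pre[i], "toxic"))
      concepts <- rbind(concepts, data.frame(id = id, branch = "C",
                                             preferred_name = name,
                                             stringsAsFactors = FALSE))
      synonyms[[id]] <- unique(syn)
    }
    for (i in seq_len(n)) {
      id <- sprintf("D%06d", 5000L + i)
      base <- paste0(pre[n + i], .FX_CHEM_SUFFIX[1L + (i - 1L) %% length(.FX_CHEM_SUFFIX)])
      name <- if (i %% 3L == 0L) paste(base, "hydrochloride") else base
      concepts <- rbind(concepts, data.frame(id = id, branch = "D",
                                             preferred_name = name,
                                             stringsAsFactors = FALSE))
      synonyms[[id]] <- name
    }
  }
  build_ontology(concepts, synonyms)
}

# mention spec: list(surface_tokens, type, id) placed at a token anchor
.fx_template <- function(kind, chem = NULL, dis = NULL, abbr = NULL) {
  plant <- function(tokens, ...) {
    specs <- list(...)
    list(tokens = tokens, specs = specs)
  }
  switch(kind,
    intra = plant(c(chem$surface, "induced", dis$surface, "in", "patients", "."),
                  list(at = 1L, len = length(chem$surface), type = "Chemical", id = chem$id),
                  list(at = length(chem$surface) + 2L, len = length(dis$surface),
                       type = "Disease", id = dis$id)),
    cooccur = plant(c(chem$surface, "was", "given", "and", dis$surface, "was",
                      "monitored", "."),
                    list(at = 1L, len = length(chem$surface), type = "Chemical", id = chem$id),
                    list(at = length(chem$surface) + 4L, len = length(dis$surface),
                         type = "Disease", id = dis$id)),
    filler = plant(c("patients", "were", "monitored", "daily", ".")),
    inter_dis = plant(c(dis$surface, "was", "observed", "in", "several",
                        "patients", "."),
                      list(at = 1L, len = length(dis$surface), type = "Disease", id = dis$id)),
    inter_chem = plant(c("this", "complication", "was", "induced", "by",
                         chem$surface, "."),
                       list(at = 6L, len = length(chem$surface), type = "Chemical",
                            id = chem$id)),
    abbrev_def = plant(c(chem$surface, "(", abbr, ")", "was", "administered", "."),
                       list(at = 1L, len = length(chem$surface), type = "Chemical",
                            id = chem$id)),
    abbrev_use = plant(c(abbr, "induced", dis$surface, "."),
                       list(at = 3L, len = length(dis$surface), type = "Disease",
                            id = dis$id)),
    stop("unknown template ", kind))
}

.fx_abbr <- function(name_tokens) {
  w <- name_tokens[1]
  ch <- strsplit(toupper(w), "")[[1]]
  paste0(ch[1], ch[min(3L, length(ch))], ch[min(5L, length(ch))])
}

#' Generate annotated fixture abstracts
#'
#' Template-built abstracts with gold chemical/disease mentions (surfaces
#' drawn from the ontology's synonym lists), gold CID relations, chain
#' dependency parses, lexicon POS tags, and -- per configuration --
#' relations realized only across sentences through an anaphoric hyponym or
#' a defined-then-reused abbreviation. Deterministic under the seed.
#'
#' @param cfg a [fixture_config()].
#' @param ontology ontology from [make_ontology()] (must be non-empty).
#' @return list of `cid_document` with parses attached.
#' @export
make_documents <- function(cfg, ontology) {
  dis_ids <- branch_concepts(ontology, "C")
  chem_ids <- branch_concepts(ontology, "D")
  stopifnot(length(dis_ids) >= 2L, length(chem_ids) >= 2L)
  set.seed(cfg$seed + 1L)
  docs <- vector("list", cfg$n_docs)
  surface_of <- function(id, variant) {
    syn <- ontology$synonyms[[id]]
    s <- syn[1L + (length(syn) > 1L && stats::runif(1) < 0.5)]
    if (variant && stats::runif(1) < cfg$variant_fraction) s <- paste0(s, "s")
    sc_words(s)
  }
  pick <- function(ids) ids[sample.int(length(ids), 1L)]
  for (d in seq_len(cfg$n_docs)) {
    # split concept pools so negative co-occurrences never collide with a
    # planted gold pair of the same document
    half_d <- length(dis_ids) %/% 2L; half_c <- length(chem_ids) %/% 2L
    pos_dis <- dis_ids[seq_len(half_d)]; neg_dis <- dis_ids[-seq_len(half_d)]
    pos_chem <- chem_ids[seq_len(half_c)]; neg_chem <- chem_ids[-seq_len(half_c)]
    sents <- list(.fx_template("filler"))
    relations <- empty_relations()
    mode <- stats::runif(1)
    if (mode < cfg$inter_sentence_fraction) {
      dis <- list(id = pick(pos_dis)); dis$surface <- surface_of(dis$id, FALSE)
      chem <- list(id = pick(pos_chem)); chem$surface <- surface_of(chem$id, FALSE)
      sents <- c(sents, list(.fx_template("inter_dis", dis = dis),
                             .fx_template("inter_chem", chem = chem)))
      relations <- rbind(relations, data.frame(chemical_id = chem$id,
                                               disease_id = dis$id,
                                               stringsAsFactors = FALSE))
    } else if (mode < cfg$inter_sentence_fraction + cfg$abbrev_fraction) {
      dis <- list(id = pick(pos_dis)); dis$surface <- surface_of(dis$id, FALSE)
      chem <- list(id = pick(pos_chem)); chem$surface <- surface_of(chem$id, FALSE)
      abbr <- .fx_abbr(chem$surface)
      sents <- c(sents, list(.fx_template("abbrev_def", chem = chem, abbr = abbr),
                             .fx_template("abbrev_use", dis = dis, abbr = abbr)))
      relations <- rbind(relations, data.frame(chemical_id = chem$id,
                                               disease_id = dis$id,
                                               stringsAsFactors = FALSE))
    }
    while (length(sents) < 1L + cfg$sentences_per_doc) {
      if (stats::runif(1) < 0.5) {
        dis <- list(id = pick(pos_dis)); dis$surface <- surface_of(dis$id, TRUE)
        chem <- list(id = pick(pos_chem)); chem$surface <- surface_of(chem$id, FALSE)
        sents <- c(sents, list(.fx_template("intra", chem = chem, dis = dis)))
        relations <- rbind(relations, data.frame(chemical_id = chem$id,
                                                 disease_id = dis$id,
                                                 stringsAsFactors = FALSE))
      } else {
        dis <- list(id = pick(neg_dis)); dis$surface <- surface_of(dis$id, TRUE)
        chem <- list(id = pick(neg_chem)); chem$surface <- surface_of(chem$id, FALSE)
        sents <- c(sents, list(.fx_template("cooccur", chem = chem, dis = dis)))
      }
    }
    docs[[d]] <- .fx_assemble(sprintf("%07d", 1000000L + d), sents,
                              unique(relations))
  }
  docs
}

# assemble a document from template sentences: first sentence is the title
.fx_assemble <- function(pmid, sents, relations = empty_relations()) {
  texts <- vapply(sents, function(s) paste(s$tokens, collapse = " "), character(1))
  title <- texts[1]
  abstract <- if (length(texts) > 1L) paste(texts[-1], collapse = " ") else ""
  mentions <- empty_mentions()
  offset <- 0L
  for (k in seq_along(sents)) {
    toks <- sents[[k]]$tokens
    starts <- offset + c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
    ends <- starts + nchar(toks)
    for (spec in sents[[k]]$specs) {
      a <- spec$at; b <- spec$at + spec$len - 1L
      mentions <- rbind(mentions, data.frame(
        start = starts[a], end = ends[b],
        text = paste(toks[a:b], collapse = " "), type = spec$type,
        concept_id = spec$id, provenance = "gold", stringsAsFactors = FALSE))
    }
    offset <- offset + sum(nchar(toks)) + length(toks)  # single spaces + sentence gap
  }
  doc <- new_document(pmid, title, abstract, mentions, relations)
  .fx_attach(doc)
}

#' Curated-relation table for a fixture corpus
#'
#' Gold relations become evidence-M rows referencing the documents that
#' carry them; distractor rows with T/inferred evidence are added on top.
#'
#' @param docs fixture documents.
#' @param n_noise_t,n_noise_inferred number of distractor rows per class.
#' @param seed seed for distractor sampling.
#' @return curated-relation data.frame (`pmids` is a list column).
#' @export
make_ctd_table <- function(docs, n_noise_t = 2L, n_noise_inferred = 2L,
                           seed = 1L) {
  pair_pmids <- list()
  for (doc in docs) {
    r <- doc$relations
    for (j in seq_len(nrow(r))) {
      key <- paste(r$chemical_id[j], r$disease_id[j])
      pair_pmids[[key]] <- unique(c(pair_pmids[[key]], doc$pmid))
    }
  }
  keys <- names(pair_pmids)
  tab <- data.frame(
    chemical_id = vapply(strsplit(keys, " "), `[[`, character(1), 1L),
    disease_id = vapply(strsplit(keys, " "), `[[`, character(1), 2L),
    evidence = rep("M", length(keys)), stringsAsFactors = FALSE)
  tab$pmids <- unname(pair_pmids)
  set.seed(seed)
  all_pmids <- vapply(docs, `[[`, character(1), "pmid")
  mk_noise <- function(m, ev) {
    if (m == 0L) return(NULL)
    data.frame(chemical_id = sprintf("D%06d", 9000L + seq_len(m)),
               disease_id = sprintf("D%06d", 8000L + seq_len(m)),
               evidence = ev,
               pmids = I(replicate(m, sample(all_pmids,
                                             min(2L, length(all_pmids))),
                                   simplify = FALSE)),
               stringsAsFactors = FALSE)
  }
  rbind(tab, mk_noise(n_noise_t, "T"), mk_noise(n_noise_inferred, "inferred"))
}

#' Abstract store for a fixture corpus
#' @param docs fixture documents.
#' @return data.frame with columns `pmid`, `title`, `abstract`.
#' @export
abstract_store <- function(docs) {
  data.frame(pmid = vapply(docs, `[[`, character(1), "pmid"),
             title = vapply(docs, `[[`, character(1), "title"),
             abstract = vapply(docs, `[[`, character(1), "abstract"),
             stringsAsFactors = FALSE)
}

#' Linearly separable tagging corpus
#'
#' Forty single-sentence documents over a closed vocabulary in which every
#' chemical surface and every disease surface is unambiguous, so the
#' word-identity features alone separate the tag classes.
#'
#' @param seed seed controlling the concept assignment.
#' @return list of 40 `cid_document` with parses attached.
#' @export
make_separable_corpus <- function(seed = 1L) {
  set.seed(seed)
  chems <- paste0(.FX_PREFIXES[1:8], "ium")
  diss <- paste0(.FX_PREFIXES[9:16], "osis")
  docs <- vector("list", 40L)
  for (i in seq_len(40L)) {
    chem <- list(id = sprintf("D%06d", 5100L + (i - 1L) %% 8L),
                 surface = chems[1L + (i - 1L) %% 8L])
    dis <- list(id = sprintf("D%06d", 100L + (i - 1L) %/% 8L),
                surface = diss[1L + (i - 1L) %/% 8L])
    tmpl <- if (i %% 2L) "intra" else "cooccur"
    docs[[i]] <- .fx_assemble(sprintf("%07d", 2000000L + i),
                              list(.fx_template(tmpl, chem = chem, dis = dis)))
  }
  docs
}

#' Random short sentences for exhaustive-search checks
#'
#' @param n number of sentences.
#' @param max_tokens maximum sentence length (tokens).
#' @param seed seed.
#' @return list of `cid_sentence` (no parses; POS from the fixture lexicon).
#' @export
make_random_sentences <- function(n = 100L, max_tokens = 6L, seed = 1L) {
  set.seed(seed)
  vocab <- c(paste0(.FX_PREFIXES[1:6], "osis"), paste0(.FX_PREFIXES[7:12], "ium"),
             "patients", "induced", "was", "severe", "the", "showed")
  lapply(seq_len(n), function(i) {
    len <- sample.int(max_tokens, 1L)
    toks <- sample(vocab, len, replace = TRUE)
    starts <- c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
    tok <- data.frame(text = toks, start = starts, end = starts + nchar(toks),
                      stringsAsFactors = FALSE)
    tok$stem <- vapply(tolower(toks), porter_stem, character(1), USE.NAMES = FALSE)
    tok$pos <- vapply(toks, .fx_pos, character(1), USE.NAMES = FALSE)
    new_sentence(tok)
  })
}

#' Hand-built document planting one coreference pair per sieve
#'
#' Returns a document, an ontology and the expected kept-pair table: for
#' each sieve 1-9 there is at least one pair that only that sieve can keep,
#' so disabling a sieve must remove exactly its own pairs.
#'
#' @return list with `doc`, `ontology` and `expected` (data.frame of pair
#'   texts and sieve index).
#' @export
make_sieve_showcase <- function() {
  concepts <- data.frame(
    id = c("C0001", "C0003", "C0004", "C0005", "C0006", "C0007", "C0009",
           "DD0002", "DD0008"),
    branch = c(rep("C", 7L), "D", "D"),
    preferred_name = c("flutteropathy", "stenoma of auriclex",
                       "type two dermopathy", "cardalgia", "prolactinex",
                       "gastric spasm", "glottirosis", "largochem",
                       "ventrix valve blocking agents"),
    stringsAsFactors = FALSE)
  synonyms <- list(
    C0001 = "flutteropathy",
    C0003 = "stenoma of auriclex",
    C0004 = "type two dermopathy",
    C0005 = c("cardalgia", "heartachea"),
    C0006 = c("prolactinex", "microprolactinemia"),
    C0007 = "gastric spasm",
    C0009 = "glottirosis",
    DD0002 = "largochem",
    DD0008 = "ventrix valve blocking agents")
  ontology <- build_ontology(concepts, synonyms)
  M <- function(at, len, type, id) list(at = at, len = len, type = type, id = id)
  S <- function(tokens, ...) list(tokens = tokens, specs = list(...))
  sents <- list(
    S(c("cardiofluttex", "was", "observed", "."), M(1L, 1L, "Disease", "C0001")),
    S(c("bradyflux", "was", "also", "observed", "."), M(1L, 1L, "Disease", "C0001")),
    S(c("largochem", "(", "LGC", ")", "was", "administered", "."),
      M(1L, 1L, "Chemical", "DD0002")),
    S(c("auriclex", "stenoma", "required", "rest", ".")),
    S(c("patients", "developed", "stenoma", "of", "auriclex", "."),
      M(3L, 3L, "Disease", "C0003")),
    S(c("type", "2", "dermopathy", "persisted", ".")),
    S(c("doctors", "noted", "type", "two", "dermopathy", "."),
      M(3L, 3L, "Disease", "C0004")),
    S(c("cardalgia", "was", "diagnosed", "."), M(1L, 1L, "Disease", "C0005")),
    S(c("heartachea", "persisted", "for", "days", ".")),
    S(c("microprolactinoma", "was", "found", "."), M(1L, 1L, "Disease", "C0006")),
    S(c("macroprolactinemia", "was", "suspected", ".")),
    S(c("gastric", "spasm", "improved", "."), M(1L, 2L, "Disease", "C0007")),
    S(c("gastric", "spasms", "returned", ".")),
    S(c("ventrix", "valve", "blocking", "agents", "were", "prescribed", "."),
      M(1L, 4L, "Chemical", "DD0008")),
    S(c("ventrix", "valve", "blockers", "remained", "effective", ".")),
    S(c("glottirosis", "was", "confirmed", "."), M(1L, 1L, "Disease", "C0009")),
    S(c("this", "complication", "required", "care", ".")))
  doc <- .fx_assemble("3000001", sents)
  expected <- data.frame(
    text_a = c("cardiofluttex", "largochem", "stenoma of auriclex",
               "type two dermopathy", "cardalgia", "microprolactinoma",
               "gastric spasm", "ventrix valve blocking agents", "glottirosis"),
    text_b = c("bradyflux", "LGC", "auriclex stenoma", "type 2 dermopathy",
               "heartachea", "macroprolactinemia", "gastric spasms",
               "ventrix valve blockers", "complication"),
    sieve = 1:9, stringsAsFactors = FALSE)
  list(doc = doc, ontology = ontology, expected = expected)
}
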