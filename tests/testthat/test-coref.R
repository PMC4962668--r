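test_that("noun phrase chunking follows the POS pattern and drops determiners", {
  s <- toy_sentence(c("the", "severe", "side", "effect", "was", "seen"),
                    pos = c("DT", "JJ", "NN", "NN", "VBD", "VBN"))
  nps <- chunk_noun_phrases(s)
  expect_equal(nrow(nps), 1L)
  expect_equal(nps$from, 2L)
  expect_equal(nps$to, 4L)
  expect_equal(nps$head, 4L)
  s2 <- toy_sentence(c("was", "seen"), pos = c("VBD", "VBN"))
  expect_equal(nrow(chunk_noun_phrases(s2)), 0L)
})

test_that("every fixture gold mention head is covered by some noun phrase", {
  for (doc in fx_docs()[1:5]) {
    m <- doc$mentions
    for (j in seq_len(nrow(m))) {
      k <- sievecid:::sentence_of_offset(doc, m$start[j])
      sent <- doc$sentences[[k]]
      nps <- chunk_noun_phrases(sent)
      idx <- sievecid:::tokens_in_span(sent, m$start[j], m$end[j])
      head <- idx[length(idx)]
      expect_true(any(nps$from <= head & nps$to >= head))
    }
  }
})

test_that("abbreviation finder matches reported long/short pairs", {
  d <- new_document("11708428", "Treatment with prednisone (PND) was begun.", "")
  expect_equal(unname(find_abbreviations(d)["PND"]), "prednisone")
  d2 <- new_document("x", "Severe hemorrhagic cystitis (HC) developed.", "")
  expect_equal(unname(find_abbreviations(d2)["HC"]), "hemorrhagic cystitis")
  d3 <- new_document("y", "As reported (2003) previously.", "")
  expect_length(find_abbreviations(d3), 0L)
})

test_that("grammatical variants implement preposition and reordering rules", {
  v <- grammatical_variants("calcification of the artery")
  expect_true("artery calcification" %in% v)
  expect_true("calcification in artery" %in% v)
  v2 <- grammatical_variants("mental status alteration")
  expect_true("alteration in mental status" %in% v2)
  expect_length(grammatical_variants("fever"), 0L)
  expect_false("calcification of artery" %in% v)
})

test_that("number variants substitute across numeral, roman, cardinal and multiplicative forms", {
  v <- number_variants("type two diabetes")
  expect_true(all(c("type 2 diabetes", "type ii diabetes",
                    "type double diabetes") %in% v))
  expect_true("grade 3 tumor" %in% number_variants("grade iii tumor"))
  expect_length(number_variants("renal failure"), 0L)
  expect_false("type two diabetes" %in% v)
})

test_that("affix variants swap and strip prefixes and suffixes", {
  expect_true("nephrotoxic" %in% affix_variants("nephrotoxicity"))
  expect_true("microprolactinemia" %in% affix_variants("macroprolactinemia"))
  expect_true("macroprolactinoma" %in% affix_variants("macroprolactinemia"))
  expect_length(affix_variants("fever"), 0L)
  expect_false("hypertension" %in% affix_variants("hypertension"))
})

test_that("same-id, partial-match and hyponym pairs reproduce reported behavior", {
  pd <- fx_canonical_doc()
  kp <- kept_pairs(run_sieves(pd$doc, pd$ontology))
  find_sieve <- function(a, b) {
    hit <- (kp$text_a == a & kp$text_b == b) | (kp$text_a == b & kp$text_b == a)
    kp$sieve[hit]
  }
  expect_equal(find_sieve("Irregular heartbeat", "irregular heart beat"), 1L)
  expect_equal(find_sieve("Calcium channel blocking agents",
                          "Calcium channel blockers"), 8L)
  expect_equal(find_sieve("Hemorrhagic cystitis", "side effect"), 9L)
})

test_that("the showcase fixture is kept pair-for-pair by the intended sieves", {
  sw <- make_sieve_showcase()
  kp <- kept_pairs(run_sieves(sw$doc, sw$ontology))
  expect_equal(nrow(kp), 9L)
  for (i in seq_len(nrow(sw$expected))) {
    e <- sw$expected[i, ]
    hit <- (kp$text_a == e$text_a & kp$text_b == e$text_b) |
      (kp$text_a == e$text_b & kp$text_b == e$text_a)
    expect_equal(kp$sieve[hit], e$sieve)
  }
})

test_that("disabling one sieve removes exactly its pairs and leaves earlier decisions intact", {
  sw <- make_sieve_showcase()
  keyed <- function(kp) paste(pmin(kp$text_a, kp$text_b),
                              pmax(kp$text_a, kp$text_b), kp$sieve)
  full <- kept_pairs(run_sieves(sw$doc, sw$ontology))
  for (k in 1:9) {
    abl <- kept_pairs(run_sieves(sw$doc, sw$ontology, sieves = setdiff(1:9, k)))
    expect_setequal(keyed(abl), keyed(full[full$sieve != k, ]))
    expect_setequal(keyed(abl[abl$sieve < k, ]), keyed(full[full$sieve < k, ]))
  }
})

test_that("kept pairs are symmetric decisions and clusters form a partition", {
  sw <- make_sieve_showcase()
  cl <- run_sieves(sw$doc, sw$ontology)
  members <- sort(unlist(cl$clusters))
  expect_equal(members, seq_len(nrow(cl$items)))
  expect_true(all(cl$kept$a != cl$kept$b))
  # re-running with the pair order flipped cannot change decisions: keeping
  # is defined on unordered pairs, so each kept pair appears exactly once
  expect_equal(anyDuplicated(paste(pmin(cl$kept$a, cl$kept$b),
                                   pmax(cl$kept$a, cl$kept$b))), 0L)
})

test_that("a document whose mentions all share one id collapses to one cluster", {
  m <- data.frame(start = c(0L, 22L), end = c(11L, 32L),
                  text = c("cardiospasm", "heartaches"),
                  type = "Disease", concept_id = "D0007",
                  provenance = "gold", stringsAsFactors = FALSE)
  d <- new_document("1", "cardiospasm was seen. heartaches persisted.", "",
                    mentions = m)
  cl <- run_sieves(d, fx_ontology())
  mention_items <- which(cl$items$kind == "mention")
  comp <- vapply(cl$clusters, function(cc) any(mention_items %in% cc), logical(1))
  expect_equal(sum(comp), 1L)
})

test_that("label propagation types noun phrases from their cluster and keeps gold intact", {
  sw <- make_sieve_showcase()
  cl <- run_sieves(sw$doc, sw$ontology)
  before <- sw$doc$mentions
  after <- propagate_entity_labels(sw$doc, cl)
  gold_after <- after$mentions[after$mentions$provenance == "gold", ]
  rownames(gold_after) <- NULL
  expect_equal(gold_after, before)
  coref <- after$mentions[after$mentions$provenance == "coref", ]
  expect_true(nrow(coref) > 0L)
  # the anaphoric hyponym inherits the disease id from its antecedent
  hyp <- coref[coref$text == "complication", ]
  expect_equal(hyp$type, "Disease")
  expect_equal(hyp$concept_id, "C0009")
  # clusters with only noun phrases produce no new mentions
  np_only <- cl$clusters[vapply(cl$clusters, function(cc)
    all(cl$items$kind[cc] == "np"), logical(1))]
  np_texts <- unlist(lapply(np_only, function(cc) cl$items$text[cc]))
  expect_false(any(coref$text %in% setdiff(np_texts, cl$items$text[cl$items$kind == "mention"])))
})

test_that("variant generators never return their input", {
  phrases <- c("calcification of artery", "type two diabetes",
               "macroprolactinemia", "mental status alteration")
  for (p in phrases) {
    expect_false(tolower(p) %in% grammatical_variants(p))
    expect_false(tolower(p) %in% number_variants(p))
    expect_false(tolower(p) %in% sievecid:::phrase_affix_variants(p))
  }
})
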