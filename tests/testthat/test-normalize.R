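test_that("identity-W SSI score equals the token-overlap closed form", {
  ont <- fx_ontology()
  ssi0 <- fx_ssi_identity()
  overlap <- function(mtext, id) {
    # independent closed form: sum over tokens of count products
    a <- table(sievecid:::.bow_tokens(mtext))
    b <- table(sievecid:::concept_name_tokens(ont, id))
    common <- intersect(names(a), names(b))
    sum(as.numeric(a[common]) * as.numeric(b[common]))
  }
  docs <- fx_docs()
  for (doc in docs[1:4]) {
    for (j in seq_len(nrow(doc$mentions))) {
      for (id in ont$concepts$id[c(1, 5, 9, 13)]) {
        expect_equal(ssi_score(ssi0, doc$mentions$text[j], ont, id),
                     overlap(doc$mentions$text[j], id))
      }
    }
  }
})

test_that("trained SSI ranks the gold concept first on training mentions", {
  ont <- fx_ontology()
  docs <- fx_docs()
  ssi <- train_ssi(docs, ont, epochs = 5, seed = 2)
  ssi_b <- train_ssi(docs, ont, epochs = 5, seed = 2)
  expect_identical(ssi$correlation, ssi_b$correlation)
  rank1 <- 0L; total <- 0L
  for (doc in docs) {
    m <- doc$mentions
    for (j in seq_len(nrow(m))) {
      branch <- if (m$type[j] == "Disease") "C" else "D"
      cands <- sort(sievecid:::branch_concepts(ont, branch))
      sc <- vapply(cands, function(id) ssi_score(ssi, m$text[j], ont, id),
                   numeric(1))
      total <- total + 1L
      rank1 <- rank1 + (cands[which.max(sc)] == m$concept_id[j])
    }
  }
  expect_gte(rank1 / total, 0.95)
})

test_that("skip-gram vectors have the configured dimension and unit self-cosine", {
  sents <- lapply(fx_docs()[1:6], function(d)
    unlist(lapply(d$sentences, function(s) tolower(s$tokens$text))))
  emb <- train_skipgram(sents, dim = 200, epochs = 2, seed = 1)
  expect_equal(ncol(emb$vectors), 200L)
  v <- emb$vectors[1, ]
  expect_equal(sum(v * v) / (sqrt(sum(v^2)) * sqrt(sum(v^2))), 1)
  expect_false("notinthevocab" %in% rownames(emb$vectors))
})

test_that("words sharing contexts by construction become distributionally close", {
  wins <- 0L
  for (seed in 1:5) {
    ctx <- c("caused", "severe", "injury", "in", "heart", "tissue")
    corp <- c(
      replicate(30, c("cardiotoxicity", sample(ctx, 4)), simplify = FALSE),
      replicate(30, c("cardiac", sample(ctx, 4)), simplify = FALSE),
      replicate(30, c("zebra", sample(c("stripes", "grass", "runs", "fast",
                                        "herd"), 4)), simplify = FALSE))
    emb <- train_skipgram(corp, dim = 25, window = 4, epochs = 4, seed = seed)
    cos <- function(a, b) {
      va <- emb$vectors[a, ]; vb <- emb$vectors[b, ]
      sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    }
    wins <- wins + (cos("cardiotoxicity", "cardiac") > cos("cardiotoxicity", "zebra"))
  }
  expect_gte(wins, 4L)
})

test_that("embedding similarity is symmetric, 1 for identical text, 0 when OOV", {
  ont <- fx_ontology()
  sents <- lapply(fx_docs(), function(d)
    unlist(lapply(d$sentences, function(s) tolower(s$tokens$text))))
  emb <- train_skipgram(sents, dim = 30, epochs = 2, seed = 3)
  id <- ont$concepts$id[1]
  pref <- ont$concepts$preferred_name[1]
  expect_equal(embedding_similarity(pref, ont, id, emb), 1, tolerance = 1e-10)
  expect_equal(embedding_similarity("qqqq zzzz", ont, id, emb), 0)
  id2 <- ont$concepts$id[3]
  a <- embedding_similarity(ont$concepts$preferred_name[3], ont, id, emb)
  b <- embedding_similarity(pref, ont, id2, emb)
  expect_equal(a, embedding_similarity(ont$concepts$preferred_name[3], ont, id, emb))
  expect_true(is.finite(a) && is.finite(b))
})

test_that("back-off resolves exact synonyms by SSI and falls back to embeddings", {
  ont <- fx_ontology()
  ssi0 <- fx_ssi_identity()
  # stage 1: unique synonym with identity W
  nb <- normalize_backoff(ont$concepts$preferred_name[2], "Disease", ont,
                          ssi = ssi0, ssi_threshold = 1)
  expect_equal(nb$concept_id, ont$concepts$id[2])
  expect_equal(nb$stage, "ssi")
  # stage 2: mention OOV to the SSI vocabulary but embedding-similar to one
  # concept's preferred name by planted co-occurrence
  pref <- tolower(ont$concepts$preferred_name[1])
  ptoks <- sc_words(pref)
  corp <- c(replicate(40, c("mystery", sample(c(ptoks, "seen"), 2)),
                      simplify = FALSE),
            replicate(40, c(ptoks, "seen"), simplify = FALSE),
            replicate(40, c("other", "words", "entirely", "here"),
                      simplify = FALSE))
  emb <- train_skipgram(corp, dim = 20, window = 3, epochs = 5, seed = 2)
  nb2 <- normalize_backoff("mystery", "Disease", ont, ssi = ssi0, emb = emb,
                           ssi_threshold = 1, emb_threshold = 0.1)
  expect_equal(nb2$stage, "embedding")
  expect_false(is.na(nb2$concept_id))
  # both stages below threshold -> NONE at the configured score
  nb3 <- normalize_backoff("qqqq", "Disease", ont, ssi = ssi0, emb = emb,
                           ssi_threshold = 1, emb_threshold = 2,
                           none_threshold = -0.5)
  expect_true(is.na(nb3$concept_id))
  expect_equal(nb3$score, -0.5)
  expect_equal(nb3$stage, "none")
})

test_that("back-off never returns a concept from the wrong branch", {
  ont <- fx_ontology()
  ssi0 <- fx_ssi_identity()
  dis_ids <- sievecid:::branch_concepts(ont, "C")
  chem_ids <- sievecid:::branch_concepts(ont, "D")
  for (doc in fx_docs()[1:5]) {
    for (j in seq_len(nrow(doc$mentions))) {
      r <- normalize_backoff(doc$mentions$text[j], doc$mentions$type[j], ont,
                             ssi = fx_ssi_identity())
      if (is.na(r$concept_id)) next
      if (doc$mentions$type[j] == "Disease") {
        expect_true(r$concept_id %in% dis_ids)
      } else {
        expect_true(r$concept_id %in% chem_ids)
      }
    }
  }
})
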