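test_that("candidate generation crosses chemicals with diseases per sentence", {
  m <- data.frame(start = c(0L, 10L, 23L), end = c(8L, 18L, 32L),
                  text = c("chematol", "chemurol", "dermatoma"),
                  type = c("Chemical", "Chemical", "Disease"),
                  concept_id = c("D1", "D2", "C1"), provenance = "gold",
                  stringsAsFactors = FALSE)
  d <- new_document("1", "chematol  chemurol and dermatoma.", "", mentions = m)
  expect_equal(nrow(candidate_pairs(d)), 2L)
  m2 <- m[m$type == "Chemical", ]
  d2 <- new_document("2", "chematol  chemurol and dermatoma.", "", mentions = m2)
  expect_equal(nrow(candidate_pairs(d2)), 0L)
})

test_that("shortest dependency paths agree with an exhaustive oracle on random trees", {
  set.seed(5)
  for (t in 1:50) {
    n <- 8L
    parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    deps <- data.frame(head = parent[2:n], dep = 2:n, label = paste0("r", 2:n),
                       stringsAsFactors = FALSE)
    tok <- data.frame(text = letters[1:n], start = (0:(n - 1)) * 2L,
                      end = (0:(n - 1)) * 2L + 1L, stem = letters[1:n],
                      pos = "NN", stringsAsFactors = FALSE)
    s <- sievecid:::new_sentence(tok, deps, 1L)
    ab <- sample.int(n, 2L)
    sp <- shortest_dependency_path(s, ab[1], ab[2])
    g <- igraph::graph_from_edgelist(cbind(parent[2:n], 2:n), directed = FALSE)
    oracle <- as.integer(igraph::shortest_paths(g, ab[1], ab[2])$vpath[[1]])
    expect_identical(sp$nodes, oracle)
    expect_equal(nrow(sp$arcs), length(oracle) - 1L)
  }
})

test_that("degenerate dependency paths behave as specified", {
  deps <- data.frame(head = 1L, dep = 2L, label = "dobj",
                     stringsAsFactors = FALSE)
  tok <- data.frame(text = c("a", "b"), start = c(0L, 2L), end = c(1L, 3L),
                    stem = c("a", "b"), pos = "NN", stringsAsFactors = FALSE)
  s <- sievecid:::new_sentence(tok, deps, 1L)
  sp <- shortest_dependency_path(s, 1L, 2L)
  expect_equal(sp$nodes, c(1L, 2L))
  expect_equal(sp$arcs$dir, "down")
  sp0 <- shortest_dependency_path(s, 2L, 2L)
  expect_equal(sp0$nodes, 2L)
  expect_equal(nrow(sp0$arcs), 0L)
  # disconnected graph: absent path
  s2 <- sievecid:::new_sentence(
    data.frame(text = c("a", "b", "c"), start = c(0L, 2L, 4L),
               end = c(1L, 3L, 5L), stem = c("a", "b", "c"), pos = "NN",
               stringsAsFactors = FALSE),
    data.frame(head = 1L, dep = 2L, label = "x", stringsAsFactors = FALSE), 1L)
  expect_null(shortest_dependency_path(s2, 1L, 3L))
})

test_that("a path of length 2 yields exactly 2 edge walks and 1 vertex walk", {
  doc <- fx_docs()[[which(vapply(fx_docs(), function(d)
    nrow(candidate_pairs(d)) > 0, logical(1)))[1]]]
  cand <- candidate_pairs(doc)
  f <- extract_relation_features(doc, cand$chem[1], cand$dis[1],
                                 config = list(token = FALSE, neighbor = FALSE,
                                               window = FALSE, pair = FALSE))
  hc <- sievecid:::mention_head_token(doc, cand$chem[1])
  hd <- sievecid:::mention_head_token(doc, cand$dis[1])
  sp <- shortest_dependency_path(doc$sentences[[hc$sentence_index]],
                                 hc$token, hd$token)
  plen <- nrow(sp$arcs)
  expect_equal(sum(f[startsWith(names(f), "sdp:ew:")]), plen)
  expect_equal(sum(f[startsWith(names(f), "sdp:vw:")]), max(0L, plen - 1L))
})

test_that("feature families are controlled exactly by their flags and extraction is pure", {
  doc <- fx_docs()[[which(vapply(fx_docs(), function(d)
    nrow(candidate_pairs(d)) > 0, logical(1)))[1]]]
  cand <- candidate_pairs(doc)
  all_f <- extract_relation_features(doc, cand$chem[1], cand$dis[1])
  expect_identical(all_f,
                   extract_relation_features(doc, cand$chem[1], cand$dis[1]))
  fams <- c(token = "tok", neighbor = "nbr", window = "win", pair = "pair",
            path = "sdp")
  present <- unique(sub(":.*", "", names(all_f)))
  expect_setequal(present, unname(fams))
  for (flag in names(fams)) {
    cfgf <- stats::setNames(as.list(names(fams) != flag), names(fams))
    f <- extract_relation_features(doc, cand$chem[1], cand$dis[1], config = cfgf)
    expect_false(any(startsWith(names(f), paste0(fams[[flag]], ":"))))
  }
})

test_that("window features replace entity tokens by type placeholders", {
  doc <- fx_docs()[[which(vapply(fx_docs(), function(d)
    nrow(candidate_pairs(d)) > 0, logical(1)))[1]]]
  cand <- candidate_pairs(doc)
  f <- extract_relation_features(doc, cand$chem[1], cand$dis[1])
  win <- names(f)[startsWith(names(f), "win:")]
  expect_true(any(grepl("CHEM", win)) && any(grepl("DIS", win)))
  chem_text <- tolower(doc$mentions$text[cand$chem[1]])
  expect_false(any(grepl(chem_text, win, fixed = TRUE)))
})

test_that("the linear classifier separates a separable toy set and honors C", {
  feats <- c(replicate(10, c(trigger = 1, x = 1), simplify = FALSE),
             replicate(10, c(other = 1, x = 1), simplify = FALSE))
  labels <- rep(c("CID", "none"), each = 10)
  m <- train_relation_model(feats, labels, C = 1)
  pred <- vapply(feats, function(f) relation_score(m, f) > 0, logical(1))
  expect_equal(pred, labels == "CID")
  m_small <- train_relation_model(feats, labels, C = 1e-4)
  expect_lt(max(abs(m_small$weights)), max(abs(m$weights)))
  expect_error(train_relation_model(feats[1:10], labels[1:10]), "single class")
})

test_that("planted path-trigger signal is recovered on held-out fixture data", {
  cfg_tr <- fixture_config(seed = 21, n_docs = 25, sentences_per_doc = 3,
                           inter_sentence_fraction = 0, abbrev_fraction = 0)
  ont <- make_ontology(cfg_tr)
  train <- make_documents(cfg_tr, ont)
  cfg_te <- fixture_config(seed = 22, n_docs = 15, sentences_per_doc = 3,
                           inter_sentence_fraction = 0, abbrev_fraction = 0)
  test <- make_documents(cfg_te, make_ontology(cfg_te))
  tr <- relation_training_data(train)
  m <- train_relation_model(tr$features, tr$labels)
  te <- relation_training_data(test)
  pred <- vapply(te$features, function(f) relation_score(m, f) > 0, logical(1))
  truth <- te$labels == "CID"
  res <- prf(sum(pred & truth), sum(pred & !truth), sum(!pred & truth))
  expect_gte(res$f1, 0.95)
})

test_that("abstract-level prediction is a set and grows monotonically with coreference", {
  cfg <- fixture_config(seed = 31, n_docs = 20, sentences_per_doc = 2,
                        inter_sentence_fraction = 0.5, abbrev_fraction = 0)
  ont <- make_ontology(cfg)
  docs <- make_documents(cfg, ont)
  intra <- docs[vapply(docs, function(d) nrow(candidate_pairs(d)) > 0, logical(1))]
  tr <- relation_training_data(intra)
  m <- train_relation_model(tr$features, tr$labels)
  inter <- docs[vapply(docs, function(d)
    nrow(d$relations) > 0 && nrow(candidate_pairs(d)) == 0, logical(1))]
  expect_true(length(inter) > 0L)
  d <- inter[[1]]
  p_no <- predict_cid(d, m, ont, use_coref = FALSE)
  p_yes <- predict_cid(d, m, ont, use_coref = TRUE)
  expect_equal(nrow(p_no), 0L)
  expect_true(nrow(p_yes) > 0L)
  key <- function(p) paste(p$chemical_id, p$disease_id)
  expect_true(all(key(p_no) %in% key(p_yes)))
  expect_true(all(key(p_yes) %in%
                    paste(d$relations$chemical_id, d$relations$disease_id)))
  expect_equal(anyDuplicated(key(p_yes)), 0L)
})
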