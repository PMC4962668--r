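silver_inputs <- function() {
  fx("silver_inputs", function() {
    cfg <- fixture_config(seed = 9, n_docs = 15, sentences_per_doc = 3,
                          inter_sentence_fraction = 0, abbrev_fraction = 0,
                          variant_fraction = 0)
    ont <- make_ontology(cfg)
    docs <- make_documents(cfg, ont)
    list(cfg = cfg, ont = ont, docs = docs,
         table = make_ctd_table(docs, n_noise_t = 3, n_noise_inferred = 2,
                                seed = 1),
         store = abstract_store(docs))
  })
}

test_that("relation filtering keeps exactly the M rows, idempotently", {
  tab <- data.frame(chemical_id = paste0("c", 1:5), disease_id = paste0("d", 1:5),
                    evidence = c("M", "T", "M", "inferred", "M"),
                    stringsAsFactors = FALSE)
  tab$pmids <- replicate(5, "1", simplify = FALSE)
  kept <- filter_relations(tab)
  expect_equal(kept$chemical_id, c("c1", "c3", "c5"))
  expect_identical(filter_relations(kept), kept)
  expect_equal(nrow(filter_relations(tab[tab$evidence == "T", ])), 0L)
})

test_that("abstract collection resolves pmids against the store with bookkeeping", {
  store <- data.frame(pmid = c("A", "B"), title = c("Title a.", "Title b."),
                      abstract = c("Body a.", "Body b."),
                      stringsAsFactors = FALSE)
  rel <- data.frame(chemical_id = c("c1", "c2"), disease_id = c("d1", "d2"),
                    evidence = "M", stringsAsFactors = FALSE)
  rel$pmids <- list(c("A", "B"), c("B", "C"))
  expect_message(docs <- collect_abstracts(rel, store), "not in store")
  expect_setequal(vapply(docs, `[[`, character(1), "pmid"), c("A", "B"))
  b <- docs[[which(vapply(docs, `[[`, character(1), "pmid") == "B")]]
  expect_equal(nrow(b$relations), 2L)
  a <- docs[[which(vapply(docs, `[[`, character(1), "pmid") == "A")]]
  expect_equal(a$relations$chemical_id, "c1")
  rel0 <- rel; rel0$pmids <- list(character(), character())
  expect_length(collect_abstracts(rel0, store), 0L)
})

test_that("overlap removal is exact set subtraction preserving order", {
  docs <- silver_inputs()$docs
  pmids <- vapply(docs, `[[`, character(1), "pmid")
  excl <- pmids[c(2, 5)]
  kept <- remove_overlap(docs, excl)
  expect_equal(vapply(kept, `[[`, character(1), "pmid"), setdiff(pmids, excl))
  expect_length(remove_overlap(docs, pmids), 0L)
  expect_equal(length(remove_overlap(docs, character())), length(docs))
})

test_that("dictionary annotation is case-insensitive leftmost-longest", {
  tsv <- c("id\tbranch\tpreferred_name\tsynonyms",
           "C1\tC\tliver cancer\tliver cancer|cancer",
           "D1\tD\tcisplatin\tcisplatin")
  ont <- load_ontology(tsv)
  d <- new_document("5", "Cisplatin and liver cancer were studied.", "")
  ann <- annotate_mentions(list(d), ont)[[1]]
  expect_equal(ann$mentions$text, c("Cisplatin", "liver cancer"))
  expect_equal(ann$mentions$concept_id, c("D1", "C1"))
  expect_equal(ann$mentions$type, c("Chemical", "Disease"))
  d2 <- new_document("6", "Only cancer here.", "")
  ann2 <- annotate_mentions(list(d2), ont)[[1]]
  expect_equal(ann2$mentions$text, "cancer")
})

test_that("planted mentions are recovered exactly by dictionary annotation", {
  si <- silver_inputs()
  bare <- lapply(si$docs, function(d) new_document(d$pmid, d$title, d$abstract))
  ann <- annotate_mentions(bare, si$ont)
  for (i in seq_along(ann)) {
    got <- ann[[i]]$mentions[, c("start", "end", "concept_id")]
    want <- si$docs[[i]]$mentions[, c("start", "end", "concept_id")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("sentence filtering keeps exactly gold-pair witnesses with correct stats", {
  si <- silver_inputs()
  res <- filter_sentences(si$docs)
  # independent oracle: count by hand over sentences
  exp_sent <- 0L; exp_chem <- 0L; exp_dis <- 0L; exp_inst <- 0L
  for (doc in si$docs) {
    gold <- paste(doc$relations$chemical_id, doc$relations$disease_id)
    m <- doc$mentions
    sent_of <- vapply(m$start, function(s) sievecid:::sentence_of_offset(doc, s),
                      integer(1))
    for (k in seq_along(doc$sentences)) {
      chems <- which(sent_of == k & m$type == "Chemical")
      diss <- which(sent_of == k & m$type == "Disease")
      if (!length(chems) || !length(diss)) next
      wit <- 0L
      for (ci in chems) for (di in diss) {
        wit <- wit + (paste(m$concept_id[ci], m$concept_id[di]) %in% gold)
      }
      if (wit > 0L) {
        exp_sent <- exp_sent + 1L
        exp_chem <- exp_chem + length(chems)
        exp_dis <- exp_dis + length(diss)
        exp_inst <- exp_inst + wit
      }
    }
  }
  expect_equal(res$stats$sentences_kept, exp_sent)
  expect_equal(res$stats$chemical_mentions, exp_chem)
  expect_equal(res$stats$disease_mentions, exp_dis)
  expect_equal(res$stats$relation_instances, exp_inst)
  for (d in res$corpus) {
    expect_true(all(c("Chemical", "Disease") %in% d$mentions$type))
  }
  # type-only relaxation keeps at least as many sentences
  relaxed <- filter_sentences(si$docs, strict = FALSE)
  expect_gte(relaxed$stats$sentences_kept, res$stats$sentences_kept)
})

test_that("build_silver equals its stage-by-stage composition and avoids exclusions", {
  si <- silver_inputs()
  excl <- si$store$pmid[1:3]
  res <- build_silver(si$table, si$store, excl, si$ont)
  manual <- filter_sentences(
    annotate_mentions(
      remove_overlap(
        collect_abstracts(filter_relations(si$table), si$store), excl),
      si$ont))
  expect_equal(lapply(res$corpus, `[[`, "text"),
               lapply(manual$corpus, `[[`, "text"))
  expect_equal(res$stats$sentences_kept, manual$stats$sentences_kept)
  src <- sub("\\..*$", "", vapply(res$corpus, `[[`, character(1), "pmid"))
  expect_length(intersect(src, excl), 0L)
  expect_equal(res$stats$pmids_removed,
               res$stats$pmids_collected -
                 length(remove_overlap(collect_abstracts(
                   filter_relations(si$table), si$store), excl)))
  # every emitted relation instance comes from the filtered M table
  mkeys <- paste(filter_relations(si$table)$chemical_id,
                 filter_relations(si$table)$disease_id)
  for (d in res$corpus) {
    expect_true(all(paste(d$relations$chemical_id, d$relations$disease_id)
                    %in% mkeys))
  }
})
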