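test_that("tokenizer records exact half-open offsets and detaches punctuation", {
  tok <- sc_tokenize("Aspirin (ASA) works.")
  expect_equal(tok$text, c("Aspirin", "(", "ASA", ")", "works", "."))
  txt <- "Aspirin (ASA) works."
  expect_equal(substring(txt, tok$start + 1, tok$end), tok$text)
  expect_true(all(tok$start < tok$end))
  expect_true(all(diff(tok$start) > 0))
})

test_that("sentence splitter honors abbreviation guards", {
  sp <- sc_split_sentences("Dosage was 5 mg, e.g. daily. Effects were mild.")
  expect_equal(nrow(sp), 2L)
  sp2 <- sc_split_sentences("One sentence only")
  expect_equal(nrow(sp2), 1L)
})

test_that("pubtator reading maps blocks structurally and validates offsets", {
  lines <- c(
    "123|t|Naloxone reverses effects.",
    "123|a|Hypertension was seen after naloxone.",
    "123\t0\t8\tNaloxone\tChemical\tD009270",
    "123\t27\t39\tHypertension\tDisease\tD006973",
    "123\tCID\tD009270\tD006973",
    "")
  docs <- read_pubtator(lines)
  expect_length(docs, 1L)
  d <- docs[[1]]
  expect_equal(nrow(d$mentions), 2L)
  expect_equal(nrow(d$relations), 1L)
  expect_true(all(d$mentions$provenance == "gold"))
  expect_equal(substring(d$text, d$mentions$start + 1, d$mentions$end),
               d$mentions$text)
  expect_length(read_pubtator(character()), 0L)

  bad <- lines
  bad[3] <- "123\t0\t8\tWrongtxt\tChemical\tD009270"
  expect_error(read_pubtator(bad), "mismatch")
  bad2 <- lines
  bad2[4] <- "123\t27\t39\tHypertension\tGene\tD006973"
  expect_error(read_pubtator(bad2), "unknown annotation type")
})

test_that("pubtator round trip is lossless on the fixture corpus", {
  docs <- fx_docs()
  lines <- write_pubtator(docs)
  docs2 <- read_pubtator(lines)
  expect_equal(lapply(docs2, function(d) d[c("pmid", "title", "abstract",
                                             "mentions", "relations")]),
               lapply(docs, function(d) d[c("pmid", "title", "abstract",
                                            "mentions", "relations")]))
  expect_identical(write_pubtator(docs2), lines)
})

test_that("unlinked mentions serialize as -1 and docs without mentions as headers", {
  d <- new_document("9", "Fever noted.", "",
                    mentions = data.frame(start = 0L, end = 5L, text = "Fever",
                                          type = "Disease", concept_id = "-1",
                                          provenance = "ner"))
  lines <- write_pubtator(list(d))
  expect_true(any(grepl("\t-1$", lines)))
  d0 <- new_document("10", "Nothing here.", "")
  expect_equal(write_pubtator(list(d0)), c("10|t|Nothing here.", "10|a|", ""))
})

test_that("attach_parses fills deps and verifies token forms", {
  d <- new_document("7", "Drugs cause harm.", "")
  conllu <- c("1\tDrugs\tdrug\tNNS\t_\t_\t2\tnsubj\t_\t_",
              "2\tcause\tcause\tVBP\t_\t_\t0\troot\t_\t_",
              "3\tharm\tharm\tNN\t_\t_\t2\tdobj\t_\t_",
              "4\t.\t.\t.\t_\t_\t2\tpunct\t_\t_", "")
  d2 <- attach_parses(d, conllu)
  expect_equal(nrow(d2$sentences[[1]]$deps), 4L)
  expect_equal(d2$sentences[[1]]$root, 2L)
  expect_equal(d2$sentences[[1]]$tokens$pos[1], "NNS")
  bad <- sub("Drugs", "Drug", conllu)
  expect_error(attach_parses(d, bad), "FORM")
  expect_error(attach_parses(d, conllu[1:2]), "parse rows")
})

test_that("fixture parses are connected as undirected graphs", {
  for (doc in fx_docs()[1:4]) {
    for (sent in doc$sentences) {
      n <- nrow(sent$tokens)
      if (n < 2L) next
      g <- igraph::graph_from_edgelist(
        cbind(sent$deps$head[sent$deps$head > 0], sent$deps$dep[sent$deps$head > 0]),
        directed = FALSE)
      expect_true(igraph::is_connected(g))
    }
  }
})

test_that("ontology loading builds an exact inverse name index", {
  tsv <- c("id\tbranch\tpreferred_name\tsynonyms",
           "D1\tC\tliver cancer\tliver cancer|hepatic cancer",
           "D2\tD\taspirin\taspirin")
  ont <- load_ontology(tsv)
  expect_setequal(ontology_lookup(ont, "Hepatic Cancer"), "D1")
  expect_setequal(ontology_lookup(ont, "aspirin"), "D2")
  expect_length(ontology_lookup(ont, "unknown"), 0L)
  for (id in ont$concepts$id) {
    for (s in ont$synonyms[[id]]) {
      expect_true(id %in% ontology_lookup(ont, s))
    }
  }
  dup <- c(tsv, "D1\tC\tother\tother")
  expect_error(load_ontology(dup), "duplicate")
  rt <- load_ontology(ontology_to_tsv(ont))
  expect_equal(rt$name_index, ont$name_index)
})

test_that("curated-relation table round trips with evidence validation", {
  tsv <- c("chemical_id\tdisease_id\tevidence\tpmids",
           "D10\tD20\tM\t111|222", "D11\tD21\tT\t333", "D12\tD22\tinferred\t")
  tab <- read_ctd_table(tsv)
  expect_equal(tab$evidence, c("M", "T", "inferred"))
  expect_equal(tab$pmids[[1]], c("111", "222"))
  expect_length(tab$pmids[[3]], 0L)
  expect_error(read_ctd_table(sub("\tM\t", "\tX\t", tsv)), "evidence")
  expect_equal(read_ctd_table(ctd_table_to_tsv(tab))$pmids, tab$pmids)
})
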