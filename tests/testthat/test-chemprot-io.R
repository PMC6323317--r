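test_that("tokenizer splits punctuation but preserves bracketed units", {
  tk <- tokenize_text("SGT interacts with the GHR.")
  expect_equal(tk$token, c("SGT", "interacts", "with", "the", "GHR", "."))
  # spans are 0-based half-open slices of the input
  expect_equal(substring("SGT interacts with the GHR.", tk$start + 1,
                         tk$end),
               tk$token)

  expect_equal(nrow(tokenize_text("")), 0L)
  expect_equal(tokenize_text("P2Y(2) receptor")$token,
               c("P2Y(2)", "receptor"))
  expect_equal(tokenize_text("(EGFR)")$token, "(EGFR)")
  expect_equal(tokenize_text("( EGFR )")$token, c("(", "EGFR", ")"))
  expect_equal(tokenize_text("alpha, beta.")$token,
               c("alpha", ",", "beta", "."))
})

test_that("token spans are strictly increasing and cover all non-space text", {
  set.seed(42)
  vocab <- c("kinase", "binds,", "(IL6)", "x.", "a", "-3.5", "e.g.")
  for (i in 1:50) {
    txt <- paste(sample(vocab, sample(1:8, 1), replace = TRUE),
                 collapse = " ")
    tk <- tokenize_text(txt)
    expect_true(all(diff(tk$start) > 0))
    expect_true(all(tk$end[-nrow(tk)] <= tk$start[-1]))
    reassembled <- paste(tk$token, collapse = "")
    expect_equal(reassembled, gsub("[ \t\n]", "", txt))
  }
})

test_that("sentence splitter handles terminators, abbreviations and tabs", {
  expect_equal(nrow(split_sentences("A b. C d.")), 2L)
  expect_equal(nrow(split_sentences("no terminator here")), 1L)
  # abbreviations and initials do not split
  expect_equal(nrow(split_sentences(
    "Treatment with e.g. aspirin vs. placebo was tested.")), 1L)
  expect_equal(nrow(split_sentences("Fig. 2 shows the J. Smith data.")), 1L)
  # tab (the title/body separator) is a hard boundary
  s <- split_sentences("Title without period\tBody starts here.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text[1], "Title without period")
  # spans point back into the text
  txt <- "IL6R binds tamoxifen. EGFR does not."
  s <- split_sentences(txt)
  expect_equal(substring(txt, s$start + 1, s$end), s$text)
  expect_equal(nrow(s), 2L)
})

test_that("corpus reader validates offsets, types and relation arguments", {
  corpus <- make_table3_corpus()
  expect_s3_class(corpus, "chemprot_corpus")
  expect_equal(nrow(corpus$documents), 1L)
  expect_equal(nrow(corpus$mentions), 3L)
  m <- corpus$mentions[corpus$mentions$term_id == "T16", ]
  expect_equal(m$etype, "CHEMICAL")
  expect_equal(m$surface, "INS37217")
  expect_equal(corpus$relations$cpr, 5L)

  dir <- withr::local_tempdir()
  # corrupted offset -> integrity error naming pmid and term
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.", body = "Aspirin binds X.",
                      stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = "T1", etype = "CHEMICAL",
                      start = 4L, end = 11L, surface = "Aspirin",
                      stringsAsFactors = FALSE))
  expect_error(read_chemprot_corpus(p$abstracts, p$entities),
               "integrity")
  # unknown entity type -> format error
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.", body = "Aspirin binds X.",
                      stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = "T1", etype = "DRUG",
                      start = 3L, end = 10L, surface = "Aspirin",
                      stringsAsFactors = FALSE))
  expect_error(read_chemprot_corpus(p$abstracts, p$entities),
               "unknown entity type")
  # dangling relation argument -> format error
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.", body = "Aspirin binds X.",
                      stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = "T1", etype = "CHEMICAL",
                      start = 3L, end = 10L, surface = "Aspirin",
                      stringsAsFactors = FALSE),
    rels = data.frame(pmid = "1", cpr = 3L, arg1 = "T1", arg2 = "T9",
                      stringsAsFactors = FALSE))
  expect_error(read_chemprot_corpus(p$abstracts, p$entities, p$relations),
               "dangling")
})

test_that("relation file is optional and empty relations mean CPR:10 only", {
  dir <- withr::local_tempdir()
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.",
                      body = "Aspirin binds EGFR.", stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = c("T1", "T2"),
                      etype = c("CHEMICAL", "GENE-Y"),
                      start = c(3L, 17L), end = c(10L, 21L),
                      surface = c("Aspirin", "EGFR"),
                      stringsAsFactors = FALSE),
    rels = data.frame(pmid = character(), cpr = integer(),
                      arg1 = character(), arg2 = character()))
  corpus <- read_chemprot_corpus(p$abstracts, p$entities, p$relations)
  expect_equal(nrow(corpus$relations), 0L)
  dict <- data.frame(word = "binds", cpr = 3L)
  cands <- build_candidates(corpus, dict)
  expect_equal(cands$pairs$label, 10L)
})

test_that("a synthetic corpus round-trips through write + read exactly", {
  sc <- synth_corpus(synth_config(n_docs = 5, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_synth_corpus(sc, dir)
  back <- read_chemprot_corpus(paths["abstracts"], paths["entities"],
                               paths["relations"])
  expect_equal(back$documents, sc$corpus$documents,
               ignore_attr = "row.names")
  expect_equal(back$mentions, sc$corpus$mentions, ignore_attr = "row.names")
  expect_equal(back$relations, sc$corpus$relations,
               ignore_attr = "row.names")
  dict <- read_interaction_dictionary(paths["dictionary"])
  expect_equal(dict, sc$dictionary, ignore_attr = "row.names")
})

test_that("prediction writer emits the challenge format, sorted and strict", {
  path <- withr::local_tempfile(fileext = ".tsv")
  preds <- data.frame(pmid = "14507899", cpr = 5L, arg1 = "T16",
                      arg2 = "T15", stringsAsFactors = FALSE)
  write_cpi_predictions(preds, path)
  expect_equal(readLines(path), "14507899\tCPR:5\tArg1:T16\tArg2:T15")

  write_cpi_predictions(preds[0, ], path)
  expect_equal(length(readLines(path)), 0L)

  expect_error(write_cpi_predictions(rbind(preds, preds), path),
               "duplicate")
  bad <- preds; bad$cpr <- 7L
  expect_error(write_cpi_predictions(bad, path), "evaluated groups")

  # term ids sort numerically (T2 before T10), pmid first
  many <- data.frame(pmid = c("2", "1", "1"), cpr = c(3L, 4L, 3L),
                     arg1 = c("T1", "T10", "T2"), arg2 = c("T2", "T1", "T1"),
                     stringsAsFactors = FALSE)
  write_cpi_predictions(many, path)
  expect_equal(read_cpi_predictions(path)$arg1, c("T2", "T10", "T1"))
})

test_that("every mention lands in exactly one sentence, or is repaired", {
  sc <- synth_corpus(synth_config(n_docs = 10, seed = 5))
  cs <- corpus_sentences(sc$corpus)
  expect_true(all(!is.na(cs$mention_sentence)))
  expect_equal(cs$n_repairs, 0L)

  # an entity spanning a (false) sentence boundary triggers the repair rule
  dir <- withr::local_tempdir()
  body <- "Binding of compound No. 5 to EGFR was shown."
  ft <- paste0("T.", "\t", body)
  s <- as.integer(regexpr("No. 5", ft, fixed = TRUE)) - 1L
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.", body = body,
                      stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = c("T1", "T2"),
                      etype = c("CHEMICAL", "GENE-Y"),
                      start = c(s, as.integer(regexpr("EGFR", ft)) - 1L),
                      end = c(s + 5L, as.integer(regexpr("EGFR", ft)) + 3L),
                      surface = c("No. 5", "EGFR"), stringsAsFactors = FALSE))
  corpus <- read_chemprot_corpus(p$abstracts, p$entities)
  # force a splitter with no abbreviation knowledge to create the break
  cs2 <- corpus_sentences(corpus, splitter = function(t)
    split_sentences(t, abbreviations = character(0)))
  expect_gte(cs2$n_repairs, 1L)
  expect_true(all(!is.na(cs2$mention_sentence)))
})
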