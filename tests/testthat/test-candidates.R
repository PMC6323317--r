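test_that("dictionary loader lower-cases, dedupes and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("agonist\t5", "Agonist\t5", "inhibits\t4"), path)
  d <- read_interaction_dictionary(path)
  expect_equal(nrow(d), 2L)
  expect_equal(d$cpr[d$word == "agonist"], 5L)

  writeLines(character(0), path)
  expect_equal(nrow(read_interaction_dictionary(path)), 0L)

  writeLines(c("agonist\t5", "agonist\t3"), path)
  expect_error(read_interaction_dictionary(path), "conflicting")
  writeLines("agonist\t11", path)
  expect_error(read_interaction_dictionary(path), "1-10")

  seed <- read_interaction_dictionary(
    system.file("extdata", "interaction_words.tsv", package = "cpistack"))
  expect_true(all(c(3, 4, 5, 6, 9) %in% seed$cpr))
  expect_false(anyDuplicated(seed$word) > 0)
})

test_that("interaction-word matching is per-occurrence and case-insensitive", {
  dict <- data.frame(word = c("agonist", "enhances", "caused"),
                     cpr = c(5L, 3L, 9L), stringsAsFactors = FALSE)
  tokens <- c("The", "Agonist", "enhances", "binding", "agonist", ".")
  m <- match_interaction_words(tokens, dict)
  expect_equal(m$token_index, c(2L, 3L, 5L))
  expect_equal(m$cpr, c(5L, 3L, 5L))
  # brute-force recount over random token sequences
  set.seed(9)
  vocab <- c(dict$word, "binding", "the", "with", "receptor")
  for (i in 1:30) {
    tk <- sample(vocab, sample(3:12, 1), replace = TRUE)
    m <- match_interaction_words(tk, dict)
    oracle <- which(tolower(tk) %in% dict$word)
    expect_equal(m$token_index, oracle)
  }
  expect_equal(nrow(match_interaction_words(c("no", "hits"), dict)), 0L)
  # optional suffix stemming
  m <- match_interaction_words(c("agonists"), dict, stem = TRUE)
  expect_equal(m$entry, "agonist")
  expect_equal(nrow(match_interaction_words(c("agonists"), dict)), 0L)
})

test_that("pair construction is the chemical x protein cartesian product", {
  mk <- function(n_chem, n_prot) {
    n <- n_chem + n_prot
    data.frame(pmid = "1", term_id = paste0("T", 1:n),
               etype = c(rep("CHEMICAL", n_chem),
                         rep(c("GENE-Y", "GENE-N"), length.out = n_prot)),
               start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
               surface = paste0("e", 1:n), stringsAsFactors = FALSE)
  }
  expect_equal(nrow(build_pairs(mk(2, 3))), 6L)
  expect_equal(nrow(build_pairs(mk(0, 3))), 0L)
  expect_equal(nrow(build_pairs(mk(2, 0))), 0L)
  # deterministic order: chemical offset first, protein offset within
  p <- build_pairs(mk(2, 2))
  expect_equal(p$chem_term, c("T1", "T1", "T2", "T2"))
  # property: #pairs = #chem x #prot on random mixes
  set.seed(4)
  for (i in 1:20) {
    nc <- sample(0:4, 1); np <- sample(0:4, 1)
    expect_equal(nrow(build_pairs(mk(nc, np))), nc * np)
  }
})

test_that("label assignment is total with documented conflict handling", {
  pairs <- data.frame(pmid = c("1", "1", "2"),
                      chem_term = c("T1", "T1", "T1"),
                      prot_term = c("T2", "T3", "T2"),
                      stringsAsFactors = FALSE)
  rels <- data.frame(pmid = "1", cpr = 4L, arg1 = "T1", arg2 = "T2",
                     stringsAsFactors = FALSE)
  lab <- assign_labels(pairs, rels)
  expect_equal(as.integer(lab), c(4L, 10L, 10L))

  # evaluated group beats non-evaluated; lowest evaluated id wins
  rels2 <- data.frame(pmid = "1", cpr = c(7L, 4L, 3L),
                      arg1 = "T1", arg2 = "T2", stringsAsFactors = FALSE)
  lab2 <- assign_labels(pairs[1, ], rels2)
  expect_equal(as.integer(lab2), 3L)
  expect_equal(length(attr(lab2, "conflicts")), 1L)
})

test_that("masking replaces focal and bystander entities span-wise", {
  corpus <- make_table3_corpus()
  cands <- build_candidates(
    corpus, read_interaction_dictionary(
      system.file("extdata", "interaction_words.tsv", package = "cpistack")))
  # Two chemicals x one protein -> two pairs; the annotated focal pair
  expect_equal(nrow(cands$pairs), 2L)
  focal <- which(cands$pairs$chem_term == "T16")
  ms <- cands$masked[[cands$pairs$pair_id[focal]]]
  expect_equal(ms$text, table3_masked)
  # partial-span replacement: 'retinal' inside 'subretinal' -> subCPT10
  expect_true("subCPT10" %in% ms$tokens$token)
  expect_equal(names(ms$cpt_pos), "T10")
  # masking is invertible
  expect_equal(unmask_entities(ms), table3_sentence)
  # the other pair masks INS37217 as a CPT bystander
  other <- which(cands$pairs$chem_term == "T10")
  ms2 <- cands$masked[[cands$pairs$pair_id[other]]]
  expect_true("CPT16" %in% ms2$tokens$token)
  expect_true("subCHEM" %in% ms2$tokens$token)
  expect_equal(unmask_entities(ms2), table3_sentence)
})

test_that("triplets inherit the pair label, one per interaction word", {
  corpus <- make_table3_corpus()
  dict <- read_interaction_dictionary(
    system.file("extdata", "interaction_words.tsv", package = "cpistack"))
  cands <- build_candidates(corpus, dict)
  # agonist, enhances, caused -> 3 triplets per pair
  for (pid in cands$pairs$pair_id) {
    tr <- cands$triplets[cands$triplets$pair_id == pid, ]
    expect_equal(nrow(tr), 3L)
    expect_setequal(tr$entry, c("agonist", "enhances", "caused"))
    expect_true(all(tr$label == cands$pairs$label[
      cands$pairs$pair_id == pid]))
  }
  expect_equal(cands$pairs$label[cands$pairs$chem_term == "T16"], 5L)
})

test_that("candidate counts obey the recount oracle on synthetic corpora", {
  sc <- synth_corpus(synth_config(n_docs = 12, seed = 21))
  cands <- build_candidates(sc$corpus, sc$dictionary)
  cs <- corpus_sentences(sc$corpus)
  # brute-force recount: per sentence, #pairs = #chem x #prot and
  # #triplets = #pairs x #dictionary-hits
  n_pairs <- 0L; n_triplets <- 0L
  for (i in seq_len(nrow(cs$sentences))) {
    rows <- which(sc$corpus$mentions$pmid == cs$sentences$pmid[i] &
                    !is.na(cs$mention_sentence) &
                    cs$mention_sentence == cs$sentences$index[i])
    rows <- rows[cs$mention_sentence[rows] == cs$sentences$index[i] &
                   sc$corpus$mentions$pmid[rows] == cs$sentences$pmid[i]]
    et <- sc$corpus$mentions$etype[rows]
    nc <- sum(et == "CHEMICAL"); np <- sum(et != "CHEMICAL")
    n_pairs <- n_pairs + nc * np
    if (nc * np > 0) {
      tk <- tokenize_text(cs$sentences$text[i])$token
      hits <- sum(tolower(tk) %in% sc$dictionary$word)
      n_triplets <- n_triplets + nc * np * hits
    }
  }
  expect_equal(nrow(cands$pairs), n_pairs)
  expect_equal(nrow(cands$triplets), n_triplets)
  cc <- candidate_counts(cands)
  expect_equal(cc$n_pairs, n_pairs)
  expect_equal(sum(cc$pairs_by_class),
               sum(cands$pairs$label %in% c(3, 4, 5, 6, 9)))
})

test_that("cross-sentence gold relations are reported as unreachable", {
  dir <- withr::local_tempdir()
  body <- "Aspirin was given. EGFR was measured."
  ft <- paste0("T.", "\t", body)
  loc <- function(w) as.integer(regexpr(w, ft, fixed = TRUE)) - 1L
  p <- write_corpus_files(dir,
    docs = data.frame(pmid = "1", title = "T.", body = body,
                      stringsAsFactors = FALSE),
    ents = data.frame(pmid = "1", term_id = c("T1", "T2"),
                      etype = c("CHEMICAL", "GENE-Y"),
                      start = c(loc("Aspirin"), loc("EGFR")),
                      end = c(loc("Aspirin") + 7L, loc("EGFR") + 4L),
                      surface = c("Aspirin", "EGFR"),
                      stringsAsFactors = FALSE),
    rels = data.frame(pmid = "1", cpr = 3L, arg1 = "T1", arg2 = "T2",
                      stringsAsFactors = FALSE))
  corpus <- read_chemprot_corpus(p$abstracts, p$entities, p$relations)
  cands <- build_candidates(corpus, data.frame(word = "given", cpr = 3L))
  expect_equal(nrow(cands$pairs), 0L)
  expect_equal(cands$coverage$n_unreachable, 1L)
})

test_that("masking round-trips across the whole synthetic corpus", {
  sc <- synth_corpus(synth_config(n_docs = 8, seed = 31))
  cands <- build_candidates(sc$corpus, sc$dictionary)
  cs <- cands$sentences
  for (i in seq_len(nrow(cands$pairs))) {
    ms <- cands$masked[[cands$pairs$pair_id[i]]]
    sent <- cs$text[cs$pmid == cands$pairs$pmid[i] &
                      cs$index == cands$pairs$sent[i]]
    expect_equal(unmask_entities(ms), sent)
    expect_equal(ms$tokens$token[ms$chem_pos], "CHEM")
    expect_equal(ms$tokens$token[ms$prot_pos], "PROT")
  }
})
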