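#' @title Synthetic ChemProt-format corpora
#' @description Generates desk-scale corpora in the exact three-file
#'   ChemProt TSV dialect, with planted CPR structure: every sentence is an
#'   instantiation of a class template that embeds a class-typical
#'   interaction word (classes 3/4/5/6/9), a neutral co-occurrence word
#'   (class 10), or no interaction word at all (also class 10). Each
#'   template carries a hand-specified dependency tree, so the whole
#'   pipeline — including shortest-path features — runs deterministically
#'   with no parser. The generator does not attempt realistic biomedical
#'   language; it emulates the structural signals the features read
#'   (interaction words, adjacency, brackets, appositives, trigger-word
#'   windows, path topologies).
#' @name synthetic_corpus
NULL

.synth_class_words <- list(
  "3" = c("activates", "upregulates", "induces", "stimulates", "enhances",
          "potentiates"),
  "4" = c("inhibits", "suppresses", "blocks", "downregulates", "attenuates"),
  "5" = c("agonist", "agonizes"),
  "6" = c("antagonist", "antagonizes"),
  "9" = c("substrate", "metabolizes"),
  "10" = c("observed", "measured", "detected", "quantified"))

.synth_chemicals <- c("tamoxifen", "metformin", "dopamine", "estradiol",
                      "quercetin", "caffeine", "ibuprofen", "morphine",
                      "nicotine", "serotonin")
.synth_proteins <- c("EGFR", "AKT1", "CYP3A4", "ABCB1", "MAPK1", "TNF",
                     "IL6R", "GPR55", "DRD2", "HTR2A")

.tpl <- function(class, tokens, heads, labels) {
  stopifnot(length(tokens) == length(heads), length(heads) == length(labels))
  list(class = class, tokens = tokens, heads = heads, labels = labels,
       chem = which(tokens == "%CHEM%"), prot = which(tokens == "%PROT%"),
       iw = which(tokens == "%IW%"), extra = which(tokens == "%EXTRA%"))
}

#' The synthetic template grammar
#'
#' @return List of templates; each has `class`, `tokens` (with `%CHEM%`,
#'   `%PROT%`, `%IW%`, `%EXTRA%` slots), a dependency tree (`heads`,
#'   `labels`) and the slot positions.
#' @export
synth_templates <- function() {
  list(
    # -- CPR:3 (up-regulator / activator)
    .tpl("3", c("%CHEM%", "%IW%", "%PROT%", "expression", "in", "treated",
                "cells", "."),
         c(2, 0, 4, 2, 7, 7, 4, 2),
         c("nsubj", "root", "compound", "obj", "case", "amod", "nmod",
           "punct")),
    .tpl("3", c("%PROT%", "is", "strongly", "%IW%", "by", "%CHEM%", "in",
                "vivo", "."),
         c(4, 4, 4, 0, 6, 4, 8, 4, 4),
         c("nsubj:pass", "aux", "advmod", "root", "case", "obl", "case",
           "obl", "punct")),
    .tpl("3", c("treatment", "with", "%CHEM%", "%IW%", "%PROT%", "activity",
                "significantly", "."),
         c(4, 3, 1, 0, 6, 4, 4, 4),
         c("nsubj", "case", "nmod", "root", "compound", "obj", "advmod",
           "punct")),
    .tpl("3", c("%CHEM%", "%IW%", "the", "orphan", "receptor", "(",
                "%PROT%", ")", "in", "neurons", "."),
         c(2, 0, 5, 5, 2, 7, 5, 7, 10, 2, 2),
         c("nsubj", "root", "det", "amod", "obj", "punct", "appos", "punct",
           "case", "obl", "punct")),
    # -- CPR:4 (down-regulator / inhibitor)
    .tpl("4", c("%CHEM%", "%IW%", "%PROT%", "expression", "in", "treated",
                "cells", "."),
         c(2, 0, 4, 2, 7, 7, 4, 2),
         c("nsubj", "root", "compound", "obj", "case", "amod", "nmod",
           "punct")),
    .tpl("4", c("%PROT%", "is", "strongly", "%IW%", "by", "%CHEM%", "in",
                "vivo", "."),
         c(4, 4, 4, 0, 6, 4, 8, 4, 4),
         c("nsubj:pass", "aux", "advmod", "root", "case", "obl", "case",
           "obl", "punct")),
    .tpl("4", c("%CHEM%", "treatment", "markedly", "%IW%", "the",
                "phosphorylation", "of", "%PROT%", "."),
         c(2, 4, 4, 0, 6, 4, 8, 6, 4),
         c("compound", "nsubj", "advmod", "root", "det", "obj", "case",
           "nmod", "punct")),
    # -- CPR:5 (agonist)
    .tpl("5", c("the", "selective", "%IW%", "%CHEM%", "bound", "%PROT%",
                "receptors", "."),
         c(4, 4, 4, 5, 0, 7, 5, 5),
         c("det", "amod", "compound", "nsubj", "root", "compound", "obj",
           "punct")),
    .tpl("5", c("the", "%IW%", "activity", "of", "%CHEM%", "at", "human",
                "%PROT%", "was", "examined", "."),
         c(3, 3, 10, 5, 3, 8, 8, 5, 10, 0, 10),
         c("det", "compound", "nsubj", "case", "nmod", "case", "amod",
           "nmod", "aux", "root", "punct")),
    .tpl("5", c("%CHEM%", "is", "a", "full", "%IW%", "at", "%PROT%", "."),
         c(5, 5, 5, 5, 0, 7, 5, 5),
         c("nsubj", "cop", "det", "amod", "root", "case", "obl", "punct")),
    # -- CPR:6 (antagonist)
    .tpl("6", c("%CHEM%", "acts", "at", "%PROT%", "as", "a", "selective",
                "%IW%", "."),
         c(2, 0, 4, 2, 8, 8, 8, 2, 2),
         c("nsubj", "root", "case", "obl", "case", "det", "amod", "obl",
           "punct")),
    .tpl("6", c("%CHEM%", "(", "a", "selective", "%IW%", ")", "targeted",
                "%PROT%", "."),
         c(7, 5, 5, 5, 1, 5, 0, 7, 7),
         c("nsubj", "punct", "det", "amod", "appos", "punct", "root", "obj",
           "punct")),
    .tpl("6", c("%CHEM%", "binds", "%PROT%", ",", "a", "receptor", "%IW%",
                "."),
         c(2, 0, 2, 7, 7, 7, 3, 2),
         c("nsubj", "root", "obj", "punct", "det", "compound", "appos",
           "punct")),
    # -- CPR:9 (substrate)
    .tpl("9", c("%CHEM%", "is", "a", "%IW%", "of", "%PROT%", "in", "the",
                "synthesis", "pathway", "."),
         c(4, 4, 4, 0, 6, 4, 10, 10, 10, 4, 4),
         c("nsubj", "cop", "det", "root", "case", "nmod", "case", "det",
           "compound", "nmod", "punct")),
    .tpl("9", c("the", "%PROT%", "%CHEM%", "conjugate", "acts", "as", "a",
                "%IW%", "in", "the", "synthesis", "pathway", "."),
         c(4, 4, 4, 5, 0, 8, 8, 5, 12, 12, 12, 8, 5),
         c("det", "compound", "compound", "nsubj", "root", "case", "det",
           "obl", "case", "det", "compound", "nmod", "punct")),
    .tpl("9", c("%PROT%", "rapidly", "%IW%", "%CHEM%", "to", "an",
                "inactive", "product", "."),
         c(3, 3, 0, 3, 8, 8, 8, 3, 3),
         c("nsubj", "advmod", "root", "obj", "case", "det", "amod", "obl",
           "punct")),
    # -- CPR:10 (no interaction): neutral co-occurrence wording
    .tpl("10", c("%CHEM%", "and", "%PROT%", "were", "%IW%", "in", "plasma",
                 "samples", "."),
         c(5, 3, 1, 5, 0, 8, 8, 5, 5),
         c("nsubj", "cc", "conj", "aux", "root", "case", "compound", "obl",
           "punct")),
    .tpl("10", c("%CHEM%", ",", "a", "%PROT%", "analog", ",", "was", "also",
                 "%IW%", "."),
         c(9, 5, 5, 5, 1, 5, 9, 9, 0, 9),
         c("nsubj", "punct", "det", "compound", "appos", "punct", "aux",
           "advmod", "root", "punct")),
    .tpl("10", c("levels", "of", "%CHEM%", ",", "%EXTRA%", "and", "%PROT%",
                 "were", "%IW%", "in", "serum", "."),
         c(9, 3, 1, 5, 3, 7, 3, 9, 0, 11, 9, 9),
         c("nsubj", "case", "nmod", "punct", "conj", "cc", "conj", "aux",
           "root", "case", "obl", "punct")),
    .tpl("10", c("%PROT%", "expression", "and", "%CHEM%", "levels", "were",
                 "%IW%", "in", "parallel", "."),
         c(2, 7, 5, 5, 2, 7, 0, 9, 7, 7),
         c("compound", "nsubj", "cc", "compound", "conj", "aux", "root",
           "case", "obl", "punct")),
    .tpl("10", c("%CHEM%", "did", "not", "alter", "%PROT%", "activity",
                 "."),
         c(4, 4, 4, 0, 6, 4, 4),
         c("nsubj", "aux", "advmod", "root", "compound", "obj", "punct")))
}

#' The generator's interaction-word dictionary
#'
#' Maps every word the template grammar can embed to its planted CPR
#' group, including the neutral class-10 co-occurrence words.
#'
#' @return data.frame with columns `word`, `cpr`.
#' @export
synth_dictionary <- function() {
  data.frame(word = unlist(.synth_class_words, use.names = FALSE),
             cpr = as.integer(rep(names(.synth_class_words),
                                  lengths(.synth_class_words))),
             stringsAsFactors = FALSE)
}

#' Synthetic-corpus configuration
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences in each document body.
#' @param class_prior Named sampling probabilities over the planted classes
#'   "3","4","5","6","9","10"; must sum to 1. The default leans on classes
#'   4 and 10, echoing the skew of real CPI corpora where most candidate
#'   pairs do not interact.
#' @param noise Label-noise rate: with this probability a sentence's
#'   planted label is flipped uniformly to another class (the interaction
#'   word keeps signalling the original class).
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 40L, sentences_per_doc = 3L,
                         class_prior = c("3" = 0.15, "4" = 0.18, "5" = 0.12,
                                         "6" = 0.12, "9" = 0.13,
                                         "10" = 0.30),
                         noise = 0, seed = 1L) {
  stopifnot(n_docs >= 1L, sentences_per_doc >= 1L,
            abs(sum(class_prior) - 1) < 1e-8,
            setequal(names(class_prior), names(.synth_class_words)),
            noise >= 0, noise < 1)
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 class_prior = class_prior, noise = noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.no_space_before <- c(".", ",", ";", ":")

.assemble_tokens <- function(tokens) {
  text <- ""
  starts <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    sep <- if (i == 1L || tokens[i] %in% .no_space_before) "" else " "
    starts[i] <- nchar(text) + nchar(sep)   # 0-based
    text <- paste0(text, sep, tokens[i])
  }
  list(text = text, starts = starts, ends = starts + nchar(tokens))
}

#' Generate a synthetic corpus with planted CPR structure
#'
#' @param cfg A [synth_config()].
#' @return A `synth_corpus` list: `corpus` (a `chemprot_corpus`), `gold`
#'   (one row per planted focal pair: pmid, chem/prot term ids, planted
#'   class, assigned label after noise, interaction word), `dictionary`
#'   (the generator's word-to-CPR dictionary), `parse_store` and `parser`
#'   (fixture parses for every generated sentence shape, and the adapter
#'   over them).
#' @export
synth_corpus <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  templates <- synth_templates()
  tpl_class <- vapply(templates, `[[`, character(1), "class")
  classes <- names(cfg$class_prior)
  set.seed(cfg$seed)

  docs <- list(); ments <- list(); rels <- list(); gold <- list()
  store <- list(); store_keys <- character(0)
  title_tokens <- c("Profiling", "of", "ligand", "receptor", "binding", ".")
  title <- .assemble_tokens(title_tokens)$text

  for (d in seq_len(cfg$n_docs)) {
    pmid <- as.character(100000L + d)
    body <- ""
    doc_ents <- list()
    for (s in seq_len(cfg$sentences_per_doc)) {
      cls <- sample(classes, 1L, prob = cfg$class_prior)
      tmpl <- templates[[sample(which(tpl_class == cls), 1L)]]
      chem <- sample(.synth_chemicals, 2L)  # [2] feeds the %EXTRA% slot
      prot <- sample(.synth_proteins, 1L)
      ptype <- sample(c("GENE-Y", "GENE-N"), 1L)
      iw <- if (length(tmpl$iw)) sample(.synth_class_words[[cls]], 1L)
      else NA_character_

      realized <- tmpl$tokens
      realized[tmpl$chem] <- chem[1]
      realized[tmpl$prot] <- prot
      if (length(tmpl$extra)) realized[tmpl$extra] <- chem[2]
      if (length(tmpl$iw)) realized[tmpl$iw] <- iw
      substr(realized[1], 1, 1) <- toupper(substr(realized[1], 1, 1))

      asm <- .assemble_tokens(realized)
      sent_base <- nchar(body) + (if (nzchar(body)) 1L else 0L)
      body <- if (nzchar(body)) paste(body, asm$text) else asm$text

      ent_slots <- c(chem = tmpl$chem, prot = tmpl$prot,
                     if (length(tmpl$extra)) c(extra = tmpl$extra))
      for (nm in names(ent_slots)) {
        i <- ent_slots[[nm]]
        doc_ents[[length(doc_ents) + 1L]] <- data.frame(
          pmid = pmid,
          etype = if (nm == "prot") ptype else "CHEMICAL",
          start = sent_base + asm$starts[i],
          end = sent_base + asm$ends[i],
          surface = realized[i], role = nm, stringsAsFactors = FALSE)
      }

      lab <- cls
      if (cfg$noise > 0 && stats::runif(1) < cfg$noise) {
        lab <- sample(setdiff(classes, cls), 1L)
      }
      gold[[length(gold) + 1L]] <- data.frame(
        pmid = pmid, sent = s, planted = as.integer(cls),
        label = as.integer(lab), iw = iw,
        ent_chem = length(doc_ents) - length(ent_slots) + 1L,
        ent_prot = length(doc_ents) - length(ent_slots) + 2L,
        stringsAsFactors = FALSE)

      # one stored parse per realized sentence shape
      masked_tokens <- realized
      masked_tokens[tmpl$chem] <- "CHEM"
      masked_tokens[tmpl$prot] <- "PROT"
      if (length(tmpl$extra)) masked_tokens[tmpl$extra] <- "ENT"
      key <- .normalize_parse_key(masked_tokens)
      if (!key %in% store_keys) {
        store_keys <- c(store_keys, key)
        store[[length(store) + 1L]] <- list(
          tokens = masked_tokens,
          edges = data.frame(head = tmpl$heads,
                             dep = seq_along(tmpl$heads),
                             label = tmpl$labels, stringsAsFactors = FALSE))
      }
    }
    docs[[d]] <- data.frame(pmid = pmid, title = title, body = body,
                            stringsAsFactors = FALSE)
    dm <- do.call(rbind, doc_ents)
    # term ids in offset order; shift offsets into the full_text frame
    dm$orig <- seq_len(nrow(dm))
    dm <- dm[order(dm$start), , drop = FALSE]
    dm$term_id <- paste0("T", seq_len(nrow(dm)))
    base <- nchar(title) + 1L  # title + tab separator
    dm$start <- dm$start + base
    dm$end <- dm$end + base
    ments[[d]] <- dm

    drows <- which(vapply(gold, function(g) g$pmid == pmid, logical(1)))
    for (gi in drows) {
      g <- gold[[gi]]
      gold[[gi]]$chem_term <- dm$term_id[match(g$ent_chem, dm$orig)]
      gold[[gi]]$prot_term <- dm$term_id[match(g$ent_prot, dm$orig)]
      if (g$label != 10L) {
        rels[[length(rels) + 1L]] <- data.frame(
          pmid = pmid, cpr = g$label,
          arg1 = gold[[gi]]$chem_term, arg2 = gold[[gi]]$prot_term,
          stringsAsFactors = FALSE)
      }
    }
  }

  documents <- do.call(rbind, docs)
  documents$full_text <- chemprot_full_text(documents$title, documents$body)
  mentions <- do.call(rbind, ments)
  mentions <- mentions[, c("pmid", "term_id", "etype", "start", "end",
                           "surface")]
  rownames(mentions) <- NULL
  relations <- if (length(rels)) do.call(rbind, rels) else
    data.frame(pmid = character(), cpr = integer(), arg1 = character(),
               arg2 = character(), stringsAsFactors = FALSE)
  gold <- do.call(rbind, gold)
  gold$ent_chem <- gold$ent_prot <- NULL

  corpus <- structure(list(documents = documents, mentions = mentions,
                           relations = relations, sep = "\t"),
                      class = "chemprot_corpus")
  # generated offsets must satisfy the reader's integrity invariant
  slice <- substr(documents$full_text[match(mentions$pmid, documents$pmid)],
                  mentions$start + 1L, mentions$end)
  stopifnot(identical(slice, mentions$surface))

  structure(list(corpus = corpus, gold = gold,
                 dictionary = synth_dictionary(),
                 parse_store = store,
                 parser = parser_from_fixtures(store), cfg = cfg),
            class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("Synthetic ChemProt corpus:", nrow(x$corpus$documents), "documents,",
      nrow(x$gold), "planted focal pairs (seed", x$cfg$seed, ")\n")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the three corpus TSVs, the generator dictionary and the JSON-lines
#' parse fixtures.
#'
#' @param sc A `synth_corpus`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths.
#' @export
write_synth_corpus <- function(sc, dir, prefix = "synth") {
  stopifnot(inherits(sc, "synth_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_chemprot_corpus(sc$corpus, dir, prefix = prefix)
  dict_path <- file.path(dir, paste0(prefix, "_dictionary.tsv"))
  writeLines(paste(sc$dictionary$word, sc$dictionary$cpr, sep = "\t"),
             dict_path, useBytes = TRUE)
  parse_path <- file.path(dir, paste0(prefix, "_parses.jsonl"))
  write_parse_fixtures(sc$parse_store, parse_path)
  invisible(c(paths, dictionary = dict_path, parses = parse_path))
}
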