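# Shared fixtures: tiny corpora built in code, fake masked sentences and
# random dependency graphs for oracle comparisons.

write_corpus_files <- function(dir, docs, ents, rels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "abstracts.tsv")
  pe <- file.path(dir, "entities.tsv")
  writeLines(paste(docs$pmid, docs$title, docs$body, sep = "\t"), pa)
  writeLines(if (nrow(ents)) paste(ents$pmid, ents$term_id, ents$etype,
                                   ents$start, ents$end, ents$surface,
                                   sep = "\t") else character(0), pe)
  pr <- NULL
  if (!is.null(rels)) {
    pr <- file.path(dir, "relations.tsv")
    writeLines(if (nrow(rels)) paste(rels$pmid, paste0("CPR:", rels$cpr),
                                     "Y ", paste0("CPR", rels$cpr),
                                     paste0("Arg1:", rels$arg1),
                                     paste0("Arg2:", rels$arg2),
                                     sep = "\t") else character(0), pr)
  }
  list(abstracts = pa, entities = pe, relations = pr)
}

# The agonist sentence used throughout the worked examples: one protein,
# two chemicals, one of them ("retinal") strictly inside the word
# "subretinal".
table3_sentence <- paste("P2Y(2) receptor agonist INS37217 enhances",
                         "functional recovery after detachment caused by",
                         "subretinal injection in normal and rds mice.")
table3_masked <- paste("PROT agonist CHEM enhances functional recovery",
                       "after detachment caused by subCPT10 injection in",
                       "normal and rds mice.")

make_table3_corpus <- function(dir = withr::local_tempdir()) {
  title <- "Functional recovery study."
  full <- paste0(title, "\t", table3_sentence)
  off <- function(pat, shift = 0L) {
    as.integer(regexpr(pat, full, fixed = TRUE)) - 1L + shift
  }
  ents <- data.frame(
    pmid = "14507899",
    term_id = c("T10", "T15", "T16"),
    etype = c("CHEMICAL", "GENE-Y", "CHEMICAL"),
    start = c(off("subretinal", 3L), off("P2Y(2) receptor"),
              off("INS37217")),
    stringsAsFactors = FALSE)
  ents$surface <- c("retinal", "P2Y(2) receptor", "INS37217")
  ents$end <- ents$start + nchar(ents$surface)
  rels <- data.frame(pmid = "14507899", cpr = 5L, arg1 = "T16",
                     arg2 = "T15", stringsAsFactors = FALSE)
  paths <- write_corpus_files(
    dir, docs = data.frame(pmid = "14507899", title = title,
                           body = table3_sentence,
                           stringsAsFactors = FALSE),
    ents = ents, rels = rels)
  read_chemprot_corpus(paths$abstracts, paths$entities, paths$relations)
}

# Minimal masked_sentence stand-in for feature unit tests
make_masked <- function(tokens, chem_pos, prot_pos, cpt_pos = integer(0)) {
  structure(list(
    tokens = data.frame(token = tokens,
                        start = seq_along(tokens) - 1L,
                        end = seq_along(tokens), stringsAsFactors = FALSE),
    chem_pos = chem_pos, prot_pos = prot_pos, cpt_pos = cpt_pos,
    replacements = NULL, n_tokens = length(tokens)),
    class = "masked_sentence")
}

DEP_LABELS <- c("nsubj", "obj", "compound", "nmod", "appos", "case", "det",
                "amod")

rand_dep_graph <- function(n, p = 0.35) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- if (any(keep)) {
    flip <- stats::runif(sum(keep)) < 0.5
    data.frame(head = ifelse(flip, pairs[1, keep], pairs[2, keep]),
               dep = ifelse(flip, pairs[2, keep], pairs[1, keep]),
               label = sample(DEP_LABELS, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(head = integer(), dep = integer(), label = character(),
               stringsAsFactors = FALSE)
  }
  dep_graph(paste0("w", seq_len(n)), edges)
}

to_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges[, c("head", "dep")] else
      data.frame(head = integer(), dep = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n)))
}

igraph_dists <- function(g) {
  igraph::distances(to_igraph(g))
}

# A memorizing learner: recalls the exact label of any row it was trained
# on and falls back to class priors otherwise. Used as a leakage canary.
memorizer <- function(seed = 1L) {
  make_learner("custom", seed = seed, params = list(
    fit = function(X, y) {
      list(keys = apply(X, 1, paste, collapse = "|"),
           labels = as.character(y), levels = levels(y),
           prior = as.numeric(prop.table(table(y))))
    },
    predict = function(model, X) {
      keys <- apply(X, 1, paste, collapse = "|")
      out <- matrix(rep(model$prior, each = length(keys)),
                    nrow = length(keys),
                    dimnames = list(NULL, model$levels))
      hit <- match(keys, model$keys)
      for (i in which(!is.na(hit))) {
        out[i, ] <- as.numeric(model$levels == model$labels[hit[i]])
      }
      out
    }))
}

# Naive re-implementations of the window rules, used as oracles.
naive_window_flag <- function(tokens, a, b, words, window = 3,
                              prefix = FALSE) {
  lo <- seq_len(a - 1)
  lo <- lo[lo >= a - window]
  hi <- seq(b + 1, length.out = window)
  hi <- hi[hi <= length(tokens)]
  win <- tolower(tokens[c(lo, hi)])
  if (prefix) {
    any(vapply(words, function(w) any(startsWith(win, w)), logical(1)))
  } else {
    any(win %in% words)
  }
}

naive_region_flag <- function(tokens, positions, words) {
  any(tolower(tokens[min(positions):max(positions)]) %in% words)
}

fit_synth_model <- function(n_docs = 20, seed = 7, folds = 5, ...) {
  sc <- synth_corpus(synth_config(n_docs = n_docs, seed = seed))
  list(sc = sc,
       fit = cpi_stack(sc$corpus, sc$dictionary, sc$parser, folds = folds,
                       seed = seed, ...))
}
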