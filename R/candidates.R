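#' @title Candidate CPI pairs and triplets
#' @description A CPI pair is a chemical mention and a protein mention
#'   (GENE-Y or GENE-N) co-occurring in one sentence; a CPI triplet adds one
#'   interaction word from the same sentence. Pairs inherit their CPR label
#'   from the gold relation annotations, defaulting to CPR:10 (no
#'   interaction); every triplet of a pair shares the pair's label. Before
#'   parsing, the focal chemical is masked as `CHEM`, the focal protein as
#'   `PROT`, and every other tagged entity as `CPT` plus the numeric part of
#'   its term identifier (so entity T10 becomes `CPT10`).
#' @name candidates
NULL

#' Load an interaction-word dictionary
#'
#' Two-column TSV: word, CPR group (1-10). Words are lower-cased and
#' deduplicated; the same word listed twice with conflicting groups is an
#' error.
#'
#' @param path TSV path. The packaged seed dictionary is at
#'   `system.file("extdata", "interaction_words.tsv", package = "cpistack")`.
#' @return data.frame with columns `word`, `cpr`.
#' @export
read_interaction_dictionary <- function(path) {
  df <- .read_tsv(path, 2L)
  if (nrow(df) == 0) {
    return(data.frame(word = character(), cpr = integer(),
                      stringsAsFactors = FALSE))
  }
  word <- tolower(trimws(df[[1]]))
  cpr <- suppressWarnings(as.integer(df[[2]]))
  if (any(!nzchar(word))) stop("empty interaction word", call. = FALSE)
  if (anyNA(cpr) || any(cpr < 1L | cpr > 10L)) {
    stop("interaction-word dictionary: CPR group must be an integer 1-10",
         call. = FALSE)
  }
  first <- !duplicated(word)
  conflict <- tapply(cpr, word, function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    stop("dictionary word '", names(conflict)[which(conflict)[1]],
         "' mapped to conflicting CPR groups", call. = FALSE)
  }
  data.frame(word = word[first], cpr = cpr[first], stringsAsFactors = FALSE)
}

#' Match interaction words against a token sequence
#'
#' Case-insensitive exact token match; with `stem = TRUE` a token missing
#' from the dictionary is retried with the suffixes `s`, `es`, `ed`, `ing`
#' stripped. One match is emitted per token occurrence, ordered by position.
#'
#' @param tokens Character vector of sentence tokens.
#' @param dictionary data.frame from [read_interaction_dictionary()].
#' @param stem Enable suffix stripping (default off).
#' @return data.frame: `token_index` (1-based), `word` (matched surface),
#'   `entry` (dictionary word), `cpr`.
#' @export
match_interaction_words <- function(tokens, dictionary, stem = FALSE) {
  low <- tolower(tokens)
  hit <- match(low, dictionary$word)
  if (stem) {
    for (suf in c("ing", "ed", "es", "s")) {
      need <- is.na(hit) & endsWith(low, suf)
      if (any(need)) {
        stripped <- substr(low[need], 1L, nchar(low[need]) - nchar(suf))
        hit[need] <- match(stripped, dictionary$word)
      }
    }
  }
  idx <- which(!is.na(hit))
  data.frame(token_index = idx, word = tokens[idx],
             entry = dictionary$word[hit[idx]],
             cpr = dictionary$cpr[hit[idx]], stringsAsFactors = FALSE)
}

#' Build all CPI pairs of a sentence
#'
#' Full cartesian product of the sentence's chemical mentions and protein
#' mentions (GENE-Y and GENE-N both count as proteins), ordered by chemical
#' offset then protein offset.
#'
#' @param mentions data.frame of the sentence's entity mentions (rows of
#'   `corpus$mentions`).
#' @return data.frame with one row per pair: `chem_term`, `prot_term`,
#'   `chem_row`, `prot_row` (row indices into `mentions`).
#' @export
build_pairs <- function(mentions) {
  chem <- which(mentions$etype == "CHEMICAL")
  prot <- which(mentions$etype %in% c("GENE-Y", "GENE-N"))
  chem <- chem[order(mentions$start[chem], mentions$term_id[chem])]
  prot <- prot[order(mentions$start[prot], mentions$term_id[prot])]
  if (!length(chem) || !length(prot)) {
    return(data.frame(chem_term = character(), prot_term = character(),
                      chem_row = integer(), prot_row = integer(),
                      stringsAsFactors = FALSE))
  }
  # expand.grid varies its first factor fastest: chem-major, prot ascending
  g <- expand.grid(prot_row = prot, chem_row = chem)
  data.frame(chem_term = mentions$term_id[g$chem_row],
             prot_term = mentions$term_id[g$prot_row],
             chem_row = g$chem_row, prot_row = g$prot_row,
             stringsAsFactors = FALSE)
}

#' Assign CPR labels to candidate pairs from gold relations
#'
#' A pair annotated as `(pmid, chem term, prot term)` receives the annotated
#' CPR group; an unannotated pair is labeled CPR:10 (no interaction). When
#' one pair carries conflicting annotations, an evaluated group (3/4/5/6/9)
#' wins over a non-evaluated one, and the lowest CPR id wins among evaluated
#' groups; conflicts are reported in the `conflicts` attribute.
#'
#' @param pairs data.frame with columns `pmid`, `chem_term`, `prot_term`.
#' @param relations `corpus$relations`-shaped data.frame.
#' @return Integer label vector (1-10) aligned with `pairs`.
#' @export
assign_labels <- function(pairs, relations) {
  if (!nrow(pairs)) return(integer(0))
  lab <- rep(10L, nrow(pairs))
  conflicts <- character(0)
  if (nrow(relations)) {
    rk <- paste(relations$pmid, relations$arg1, relations$arg2, sep = "\r")
    pk <- paste(pairs$pmid, pairs$chem_term, pairs$prot_term, sep = "\r")
    for (i in seq_len(nrow(pairs))) {
      cprs <- unique(relations$cpr[rk == pk[i]])
      if (!length(cprs)) next
      if (length(cprs) > 1L) {
        conflicts <- c(conflicts, pk[i])
        ev <- cprs[cprs %in% CPR_EVALUATED]
        cprs <- if (length(ev)) min(ev) else min(cprs)
      }
      lab[i] <- as.integer(cprs[1])
    }
  }
  attr(lab, "conflicts") <- conflicts
  lab
}

#' Mask the entities of a sentence for one focal pair
#'
#' Span-based replacement on the sentence text: the focal chemical becomes
#' `CHEM`, the focal protein `PROT`, and every other tagged entity `CPTk`
#' with k the numeric part of its term id. Replacement precedes
#' tokenization, so a multi-word entity collapses to one token, and an
#' entity strictly inside a word is replaced in place, preserving the
#' surrounding characters (e.g. `subretinal` with the entity `retinal`
#' becomes `subCPT10`). Entities overlapping a focal span are absorbed by
#' the focal placeholder.
#'
#' @param sentence One row of the `sentences` data.frame from
#'   [corpus_sentences()] (needs `start`, `end`, `text`).
#' @param mentions Entity mentions lying in this sentence (corpus offsets).
#' @param chem_term,prot_term Term ids of the focal chemical and protein.
#' @return A `masked_sentence` list: `text`, `tokens` (tokenization of the
#'   masked text), `chem_pos`, `prot_pos`, `cpt_pos` (named integer vector,
#'   token positions by term id), `replacements` (bookkeeping for
#'   unmasking), `n_tokens`.
#' @export
mask_entities <- function(sentence, mentions, chem_term, prot_term) {
  ci <- match(chem_term, mentions$term_id)
  pr <- match(prot_term, mentions$term_id)
  if (is.na(ci) || is.na(pr)) {
    stop("focal terms not found among the sentence's mentions", call. = FALSE)
  }
  if (mentions$start[ci] < mentions$end[pr] &&
      mentions$start[pr] < mentions$end[ci]) {
    stop("overlapping focal mentions: ", chem_term, " / ", prot_term,
         call. = FALSE)
  }
  s0 <- sentence$start  # corpus offset of sentence char 1
  repl <- data.frame(term = c(chem_term, prot_term),
                     start = c(mentions$start[ci], mentions$start[pr]) - s0,
                     end = c(mentions$end[ci], mentions$end[pr]) - s0,
                     tag = c("CHEM", "PROT"), stringsAsFactors = FALSE)
  others <- setdiff(seq_len(nrow(mentions)), c(ci, pr))
  others <- others[order(mentions$start[others], -mentions$end[others])]
  for (j in others) {
    os <- mentions$start[j] - s0; oe <- mentions$end[j] - s0
    if (any(os < repl$end & repl$start < oe)) next  # absorbed / nested
    repl <- rbind(repl, data.frame(
      term = mentions$term_id[j], start = os, end = oe,
      tag = paste0("CPT", sub("^T", "", mentions$term_id[j])),
      stringsAsFactors = FALSE))
  }
  repl <- repl[order(repl$start), , drop = FALSE]
  txt <- sentence$text
  out <- character(0); pos <- 0L  # 0-based cursor into txt
  new_start <- integer(nrow(repl))
  new_len <- 0L
  for (r in seq_len(nrow(repl))) {
    pre <- substr(txt, pos + 1L, repl$start[r])
    new_len <- new_len + nchar(pre)
    new_start[r] <- new_len
    out <- c(out, pre, repl$tag[r])
    new_len <- new_len + nchar(repl$tag[r])
    pos <- repl$end[r]
  }
  out <- c(out, substr(txt, pos + 1L, nchar(txt)))
  masked <- paste0(out, collapse = "")
  repl$surface <- substr(rep(txt, nrow(repl)), repl$start + 1L, repl$end)
  repl$masked_start <- new_start

  tokens <- tokenize_text(masked)
  tok_of <- function(p0) {
    k <- which(tokens$start <= p0 & tokens$end > p0)
    if (!length(k)) stop("internal: placeholder outside any token")
    k[1]
  }
  posv <- vapply(repl$masked_start, tok_of, integer(1))
  i_chem <- which(repl$tag == "CHEM")
  i_prot <- which(repl$tag == "PROT")
  i_cpt <- setdiff(seq_len(nrow(repl)), c(i_chem, i_prot))
  cpt <- posv[i_cpt]
  names(cpt) <- repl$term[i_cpt]
  structure(list(text = masked, tokens = tokens,
                 chem_pos = posv[i_chem], prot_pos = posv[i_prot],
                 cpt_pos = cpt, replacements = repl,
                 n_tokens = nrow(tokens)),
            class = "masked_sentence")
}

#' Invert entity masking
#'
#' Reconstructs the original sentence text from a [mask_entities()] result;
#' used to verify that masking is information-preserving.
#'
#' @param masked A `masked_sentence`.
#' @return The original sentence text.
#' @export
unmask_entities <- function(masked) {
  txt <- masked$text
  r <- masked$replacements
  for (i in rev(seq_len(nrow(r)))) {
    txt <- paste0(substr(txt, 1L, r$masked_start[i]),
                  r$surface[i],
                  substr(txt, r$masked_start[i] + nchar(r$tag[i]) + 1L,
                         nchar(txt)))
  }
  txt
}

#' Build the full candidate set of a corpus
#'
#' Segments every document, enumerates CPI pairs per sentence, assigns gold
#' labels, masks each pair's sentence, and matches interaction words to form
#' CPI triplets. Gold relations whose arguments never co-occur in one
#' sentence are sentence-unreachable and reported, not silently dropped.
#'
#' @param corpus A `chemprot_corpus`.
#' @param dictionary Interaction-word dictionary data.frame.
#' @param stem Passed to [match_interaction_words()].
#' @param splitter Sentence splitter, passed to [corpus_sentences()].
#' @return A `cpi_candidates` list: `pairs` (one row per candidate pair:
#'   pair_id, pmid, sentence index, chem/prot term ids, label), `triplets`
#'   (one row per candidate triplet: triplet_id, pair_id, iw token index,
#'   word, dictionary CPR), `masked` (list of `masked_sentence`, indexed by
#'   pair_id), `sentences`, `coverage` (annotation reachability counts).
#' @export
build_candidates <- function(corpus, dictionary, stem = FALSE,
                             splitter = split_sentences) {
  cs <- corpus_sentences(corpus, splitter = splitter)
  sents <- cs$sentences
  pairs_l <- list(); trips_l <- list(); masked <- list()
  for (d in unique(sents$pmid)) {
    dm_rows <- which(corpus$mentions$pmid == d)
    dsent <- which(sents$pmid == d)
    for (si in dsent) {
      in_s <- dm_rows[!is.na(cs$mention_sentence[dm_rows]) &
                        cs$mention_sentence[dm_rows] == sents$index[si]]
      if (length(in_s) < 2L) next
      men <- corpus$mentions[in_s, , drop = FALSE]
      p <- build_pairs(men)
      if (!nrow(p)) next
      p$pmid <- d
      p$sent <- sents$index[si]
      for (r in seq_len(nrow(p))) {
        pid <- length(masked) + 1L
        ms <- mask_entities(sents[si, ], men, p$chem_term[r], p$prot_term[r])
        masked[[pid]] <- ms
        pairs_l[[pid]] <- data.frame(
          pair_id = pid, pmid = d, sent = sents$index[si],
          chem_term = p$chem_term[r], prot_term = p$prot_term[r],
          stringsAsFactors = FALSE)
        mt <- match_interaction_words(ms$tokens$token, dictionary, stem = stem)
        if (nrow(mt)) {
          trips_l[[length(trips_l) + 1L]] <- data.frame(
            pair_id = pid, iw_index = mt$token_index, word = mt$word,
            entry = mt$entry, iw_cpr = mt$cpr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(pairs_l)) do.call(rbind, pairs_l) else
    data.frame(pair_id = integer(), pmid = character(), sent = integer(),
               chem_term = character(), prot_term = character(),
               stringsAsFactors = FALSE)
  triplets <- if (length(trips_l)) do.call(rbind, trips_l) else
    data.frame(pair_id = integer(), iw_index = integer(), word = character(),
               entry = character(), iw_cpr = integer(), stringsAsFactors = FALSE)
  if (nrow(triplets)) {
    triplets$triplet_id <- seq_len(nrow(triplets))
    triplets <- triplets[, c("triplet_id", "pair_id", "iw_index", "word",
                             "entry", "iw_cpr")]
  } else {
    triplets$triplet_id <- integer(0)
  }
  lab <- assign_labels(pairs, corpus$relations)
  pairs$label <- as.integer(lab)
  if (nrow(triplets)) {
    triplets$label <- pairs$label[match(triplets$pair_id, pairs$pair_id)]
  } else {
    triplets$label <- integer(0)
  }

  ann <- unique(paste(corpus$relations$pmid, corpus$relations$arg1,
                      corpus$relations$arg2, sep = "\r"))
  got <- unique(paste(pairs$pmid, pairs$chem_term, pairs$prot_term,
                      sep = "\r"))
  coverage <- list(n_annotations = length(ann),
                   n_reachable = sum(ann %in% got),
                   n_unreachable = sum(!ann %in% got),
                   n_repairs = cs$n_repairs,
                   n_label_conflicts = length(attr(lab, "conflicts")))

  structure(list(pairs = pairs, triplets = triplets, masked = masked,
                 sentences = sents, coverage = coverage),
            class = "cpi_candidates")
}

#' @export
print.cpi_candidates <- function(x, ...) {
  cat("CPI candidates:", nrow(x$pairs), "pairs,", nrow(x$triplets),
      "triplets over", nrow(x$sentences), "sentences\n")
  if (x$coverage$n_unreachable) {
    cat("  ", x$coverage$n_unreachable,
        "gold annotations are sentence-unreachable\n")
  }
  invisible(x)
}

#' Candidate-construction counts per split
#'
#' Tabulates pair and triplet totals plus per-class counts over the
#' evaluated CPR groups, in the layout used to audit candidate construction
#' against a corpus's reported statistics.
#'
#' @param candidates A `cpi_candidates` object.
#' @return List with `n_pairs`, `n_triplets`, `pairs_by_class`,
#'   `triplets_by_class` (named by CPR group 3/4/5/6/9).
#' @export
candidate_counts <- function(candidates) {
  stopifnot(inherits(candidates, "cpi_candidates"))
  pb <- vapply(CPR_EVALUATED, function(k) sum(candidates$pairs$label == k),
               integer(1))
  tb <- vapply(CPR_EVALUATED, function(k) sum(candidates$triplets$label == k),
               integer(1))
  names(pb) <- names(tb) <- paste0("CPR:", CPR_EVALUATED)
  list(n_pairs = nrow(candidates$pairs),
       n_triplets = nrow(candidates$triplets),
       pairs_by_class = pb, triplets_by_class = tb)
}
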