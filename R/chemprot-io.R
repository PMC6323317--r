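#' @title ChemProt corpus input/output
#' @description Readers and writers for the ChemProt tab-separated corpus
#'   dialect: an abstracts file (pmid, title, body), an entities file
#'   (pmid, term id, type, start, end, surface) and an optional relations
#'   file (pmid, CPR group, evaluation flag, label, Arg1, Arg2). Character
#'   offsets index into the document `full_text`, the concatenation of the
#'   title and the body; offsets are 0-based and half-open.
#' @name chemprot_io
NULL

CPR_EVALUATED <- c(3L, 4L, 5L, 6L, 9L)
ENTITY_TYPES <- c("CHEMICAL", "GENE-Y", "GENE-N")

#' Assemble the offset reference frame of a document
#'
#' @param title,body Character scalars.
#' @param sep Separator between title and body; the ChemProt convention is a
#'   tab character.
#' @return `title + sep + body`.
#' @export
chemprot_full_text <- function(title, body, sep = "\t") {
  paste0(title, sep, body)
}

.read_tsv <- function(path, n_min) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- as.data.frame(matrix(character(0), 0L, n_min),
                         stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  df <- utils::read.delim(path, header = FALSE, quote = "", comment.char = "",
                          colClasses = "character", fill = TRUE,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  if (!nrow(df)) return(empty)
  if (nrow(df) > 0 && ncol(df) < n_min) {
    stop("expected at least ", n_min, " tab-separated columns in ", path,
         call. = FALSE)
  }
  df
}

#' Read a ChemProt-format corpus split
#'
#' Reads abstracts, entity mentions and (optionally) gold relation
#' annotations, validates every mention surface against its `full_text`
#' slice, and resolves relation arguments to mentions.
#'
#' @param abstract_path Path to the abstracts TSV (pmid, title, body).
#' @param entity_path Path to the entities TSV
#'   (pmid, term id `Tn`, type, start, end, surface).
#' @param relation_path Optional path to the relations TSV
#'   (pmid, `CPR:k`, eval flag, label, `Arg1:Tn`, `Arg2:Tm`); omit for
#'   prediction-mode corpora, which then carry zero relations.
#' @param sep Title/body separator used to build `full_text`.
#' @param one_based Set `TRUE` if the entity file uses 1-based inclusive
#'   offsets; they are converted to the package's 0-based half-open frame.
#' @return An object of class `chemprot_corpus`: a list with data.frames
#'   `documents` (pmid, title, body, full_text), `mentions` (pmid, term_id,
#'   etype, start, end, surface) and `relations` (pmid, cpr, arg1, arg2).
#' @export
read_chemprot_corpus <- function(abstract_path, entity_path,
                                 relation_path = NULL, sep = "\t",
                                 one_based = FALSE) {
  ab <- .read_tsv(abstract_path, 3L)
  documents <- data.frame(pmid = ab[[1]], title = ab[[2]], body = ab[[3]],
                          stringsAsFactors = FALSE)
  if (anyDuplicated(documents$pmid)) {
    stop("duplicate pmid in abstracts file", call. = FALSE)
  }
  if (any(!nzchar(documents$pmid))) stop("empty pmid", call. = FALSE)
  documents$full_text <- chemprot_full_text(documents$title, documents$body,
                                            sep = sep)

  en <- .read_tsv(entity_path, 6L)
  if (nrow(en) == 0) {
    mentions <- data.frame(pmid = character(), term_id = character(),
                           etype = character(), start = integer(),
                           end = integer(), surface = character(),
                           stringsAsFactors = FALSE)
  } else {
    mentions <- data.frame(pmid = en[[1]], term_id = en[[2]], etype = en[[3]],
                           start = as.integer(en[[4]]), end = as.integer(en[[5]]),
                           surface = en[[6]], stringsAsFactors = FALSE)
    if (one_based) {
      mentions$start <- mentions$start - 1L
    }
    bad_type <- !mentions$etype %in% ENTITY_TYPES
    if (any(bad_type)) {
      stop("unknown entity type '", mentions$etype[which(bad_type)[1]],
           "' (pmid ", mentions$pmid[which(bad_type)[1]], ")", call. = FALSE)
    }
    ft <- documents$full_text[match(mentions$pmid, documents$pmid)]
    if (anyNA(ft)) {
      i <- which(is.na(ft))[1]
      stop("entity pmid ", mentions$pmid[i], " not present in abstracts file",
           call. = FALSE)
    }
    slice <- substr(ft, mentions$start + 1L, mentions$end)
    bad <- is.na(mentions$start) | is.na(mentions$end) |
      mentions$start < 0L | mentions$start >= mentions$end |
      mentions$end > nchar(ft) | slice != mentions$surface
    if (any(bad)) {
      i <- which(bad)[1]
      stop("corpus integrity error: entity ", mentions$term_id[i], " of pmid ",
           mentions$pmid[i], " does not match its full_text slice (got '",
           slice[i], "', annotated '", mentions$surface[i], "')",
           call. = FALSE)
    }
  }

  if (is.null(relation_path)) {
    relations <- data.frame(pmid = character(), cpr = integer(),
                            arg1 = character(), arg2 = character(),
                            stringsAsFactors = FALSE)
  } else {
    re <- .read_tsv(relation_path, 4L)
    if (nrow(re) == 0) {
      relations <- data.frame(pmid = character(), cpr = integer(),
                              arg1 = character(), arg2 = character(),
                              stringsAsFactors = FALSE)
    } else {
      # 6-column challenge format (pmid, CPR:k, eval, label, Arg1:, Arg2:) or
      # a condensed 4-column form (pmid, CPR:k, Arg1:, Arg2:)
      if (ncol(re) >= 6L) {
        a1 <- re[[5]]; a2 <- re[[6]]
      } else {
        a1 <- re[[3]]; a2 <- re[[4]]
      }
      relations <- data.frame(
        pmid = re[[1]],
        cpr = suppressWarnings(as.integer(sub("^CPR:", "", re[[2]]))),
        arg1 = sub("^Arg1:", "", a1),
        arg2 = sub("^Arg2:", "", a2),
        stringsAsFactors = FALSE)
      if (anyNA(relations$cpr) || any(relations$cpr < 1L | relations$cpr > 10L)) {
        stop("relation format error: CPR group outside CPR:1..CPR:10",
             call. = FALSE)
      }
      key <- paste(mentions$pmid, mentions$term_id)
      miss1 <- !paste(relations$pmid, relations$arg1) %in% key
      miss2 <- !paste(relations$pmid, relations$arg2) %in% key
      if (any(miss1 | miss2)) {
        i <- which(miss1 | miss2)[1]
        stop("relation format error: dangling argument in pmid ",
             relations$pmid[i], " (", relations$arg1[i], ", ",
             relations$arg2[i], ")", call. = FALSE)
      }
    }
  }

  structure(list(documents = documents, mentions = mentions,
                 relations = relations, sep = sep),
            class = "chemprot_corpus")
}

#' @export
print.chemprot_corpus <- function(x, ...) {
  cat("ChemProt corpus:", nrow(x$documents), "documents,",
      nrow(x$mentions), "entity mentions,",
      nrow(x$relations), "relation annotations\n")
  invisible(x)
}

#' Write a corpus back to the three-file ChemProt TSV layout
#'
#' @param corpus A `chemprot_corpus`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; writes `<prefix>_abstracts.tsv`,
#'   `<prefix>_entities.tsv`, `<prefix>_relations.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_chemprot_corpus <- function(corpus, dir, prefix = "corpus") {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pa <- file.path(dir, paste0(prefix, "_abstracts.tsv"))
  pe <- file.path(dir, paste0(prefix, "_entities.tsv"))
  pr <- file.path(dir, paste0(prefix, "_relations.tsv"))
  .write_lines <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  d <- corpus$documents
  .write_lines(paste(d$pmid, d$title, d$body, sep = "\t"), pa)
  m <- corpus$mentions
  .write_lines(paste(m$pmid, m$term_id, m$etype, m$start, m$end, m$surface,
                     sep = "\t"), pe)
  r <- corpus$relations
  .write_lines(paste(r$pmid, paste0("CPR:", r$cpr), "Y ",
                     paste0("CPR", r$cpr), paste0("Arg1:", r$arg1),
                     paste0("Arg2:", r$arg2), sep = "\t"), pr)
  invisible(c(abstracts = pa, entities = pe, relations = pr))
}

#' Write predictions in the challenge submission format
#'
#' One line per extracted interaction:
#' `pmid<TAB>CPR:k<TAB>Arg1:Tn<TAB>Arg2:Tm`, sorted by pmid, then the
#' numeric part of the argument term ids, then CPR group. Only the
#' evaluated groups CPR:3/4/5/6/9 may be emitted.
#'
#' @param preds data.frame with columns `pmid`, `cpr`, `arg1`, `arg2`
#'   (term ids without the `Arg1:`/`Arg2:` prefix).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cpi_predictions <- function(preds, path) {
  stopifnot(is.data.frame(preds),
            all(c("pmid", "cpr", "arg1", "arg2") %in% names(preds)))
  if (nrow(preds)) {
    if (!all(preds$cpr %in% CPR_EVALUATED)) {
      stop("predictions must be restricted to the evaluated groups CPR:",
           paste(CPR_EVALUATED, collapse = "/"), call. = FALSE)
    }
    key <- paste(preds$pmid, preds$cpr, preds$arg1, preds$arg2)
    if (anyDuplicated(key)) stop("duplicate prediction records", call. = FALSE)
    o <- order(preds$pmid,
               as.integer(sub("^T", "", preds$arg1)),
               as.integer(sub("^T", "", preds$arg2)),
               preds$cpr)
    preds <- preds[o, , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(preds)) {
    writeLines(paste(preds$pmid, paste0("CPR:", preds$cpr),
                     paste0("Arg1:", preds$arg1), paste0("Arg2:", preds$arg2),
                     sep = "\t"), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a predictions file written by [write_cpi_predictions()]
#'
#' @param path Prediction TSV path.
#' @return data.frame with columns `pmid`, `cpr`, `arg1`, `arg2`.
#' @export
read_cpi_predictions <- function(path) {
  df <- .read_tsv(path, 4L)
  if (nrow(df) == 0) {
    return(data.frame(pmid = character(), cpr = integer(), arg1 = character(),
                      arg2 = character(), stringsAsFactors = FALSE))
  }
  cpr <- suppressWarnings(as.integer(sub("^CPR:", "", df[[2]])))
  if (anyNA(cpr)) {
    stop("malformed prediction line ", which(is.na(cpr))[1], call. = FALSE)
  }
  data.frame(pmid = df[[1]], cpr = cpr,
             arg1 = sub("^Arg1:", "", df[[3]]),
             arg2 = sub("^Arg2:", "", df[[4]]), stringsAsFactors = FALSE)
}

#' Read a relations TSV without resolving against a corpus
#'
#' Accepts the 6-column challenge format (pmid, `CPR:k`, eval flag, label,
#' `Arg1:Tn`, `Arg2:Tm`) or the condensed 4-column form; useful for
#' standalone evaluation of prediction files against gold annotations.
#'
#' @param path Relations TSV path.
#' @return data.frame with columns `pmid`, `cpr`, `arg1`, `arg2`.
#' @export
read_relation_file <- function(path) {
  re <- .read_tsv(path, 4L)
  if (nrow(re) == 0) {
    return(data.frame(pmid = character(), cpr = integer(),
                      arg1 = character(), arg2 = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(re) >= 6L) { a1 <- re[[5]]; a2 <- re[[6]] }
  else { a1 <- re[[3]]; a2 <- re[[4]] }
  cpr <- suppressWarnings(as.integer(sub("^CPR:", "", re[[2]])))
  if (anyNA(cpr)) stop("malformed relation line ", which(is.na(cpr))[1],
                       call. = FALSE)
  data.frame(pmid = re[[1]], cpr = cpr, arg1 = sub("^Arg1:", "", a1),
             arg2 = sub("^Arg2:", "", a2), stringsAsFactors = FALSE)
}

#' Sentence-segment every document of a corpus
#'
#' Applies [split_sentences()] to each document's `full_text` and assigns
#' each entity mention to the sentence containing it. A mention crossing a
#' sentence boundary triggers the boundary-repair rule: the earlier sentence
#' is extended (sentences merged) to cover the mention, and the repair is
#' counted, so no entity is ever dropped silently.
#'
#' @param corpus A `chemprot_corpus`.
#' @param splitter Sentence splitting function `function(text) ->`
#'   data.frame(start, end, text); defaults to [split_sentences()].
#' @return A list with `sentences` (data.frame: pmid, index, start, end,
#'   text), `mention_sentence` (sentence index aligned with
#'   `corpus$mentions`, NA for none) and `n_repairs`.
#' @export
corpus_sentences <- function(corpus, splitter = split_sentences) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  out <- list(); repairs <- 0L
  ms_idx <- rep(NA_integer_, nrow(corpus$mentions))
  for (i in seq_len(nrow(corpus$documents))) {
    pmid <- corpus$documents$pmid[i]
    sents <- splitter(corpus$documents$full_text[i])
    men <- which(corpus$mentions$pmid == pmid)
    if (nrow(sents) && length(men)) {
      repeat {
        merged <- FALSE
        for (j in men) {
          s <- corpus$mentions$start[j]; e <- corpus$mentions$end[j]
          covers <- which(sents$start <= s & sents$end >= e)
          if (!length(covers)) {
            touch <- which(sents$start < e & sents$end > s)
            if (!length(touch)) touch <- max(which(sents$start <= s))
            a <- min(touch); b <- max(max(touch), min(a + 1L, nrow(sents)))
            full <- corpus$documents$full_text[i]
            sents <- rbind(
              if (a > 1L) sents[seq_len(a - 1L), ] else NULL,
              data.frame(start = sents$start[a], end = max(sents$end[b], e),
                         text = substr(full, sents$start[a] + 1L,
                                       max(sents$end[b], e)),
                         stringsAsFactors = FALSE),
              if (b < nrow(sents)) sents[seq(b + 1L, nrow(sents)), ] else NULL)
            repairs <- repairs + 1L
            merged <- TRUE
            break
          }
        }
        if (!merged) break
      }
    }
    if (nrow(sents)) {
      sents$pmid <- pmid
      sents$index <- seq_len(nrow(sents))
      out[[length(out) + 1L]] <- sents
      for (j in men) {
        s <- corpus$mentions$start[j]; e <- corpus$mentions$end[j]
        k <- which(sents$start <= s & sents$end >= e)
        if (length(k)) ms_idx[j] <- k[1]
      }
    }
  }
  sentences <- if (length(out)) {
    do.call(rbind, out)[, c("pmid", "index", "start", "end", "text")]
  } else {
    data.frame(pmid = character(), index = integer(), start = integer(),
               end = integer(), text = character(), stringsAsFactors = FALSE)
  }
  list(sentences = sentences, mention_sentence = ms_idx, n_repairs = repairs)
}
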