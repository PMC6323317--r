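#' @title Semantic-pattern and dependency-graph features
#' @description Hand-crafted features computed from the masked token
#'   sequence (sentence length, entity positions, adjacency, bracketing,
#'   trigger-word windows, negation and conjunction cues) and from the
#'   dependency graph (shortest-dependency-path step counts and word
#'   distances, path topology type, one-hot typed dependencies, appositive
#'   flag). All window features share one window rule: `window` tokens
#'   before the first focal element and `window` tokens after the last.
#' @name features
NULL

#' Feature-extraction configuration
#'
#' @param window Token window size for the trigger-word features (the
#'   number of words inspected before e1 and after e2); default 3.
#' @param negation_words,conjunction_words Case-insensitive token lists for
#'   the negation and compound-meaning cues scanned over the region covered
#'   by the candidate.
#' @param substrate_prefixes Case-insensitive prefixes of
#'   substrate-indicative words (covers product/production,
#'   generate/generated, synthetic/synthesis, pathway).
#' @param significant_prefix Prefix for the `Significant` cue.
#' @return A list of class `cpi_feature_config`.
#' @export
cpi_feature_config <- function(
    window = 3L,
    negation_words = c("not", "no", "n't", "without", "incapable", "unable",
                       "neither", "nor", "cannot", "fail", "fails", "failed",
                       "lack", "lacks", "lacked", "absence"),
    conjunction_words = c("although", "though", "therefore", "whereas",
                          "however", "but", "while", "yet", "moreover",
                          "nevertheless"),
    substrate_prefixes = c("product", "pathway", "generat", "synthe"),
    significant_prefix = "significant") {
  structure(list(window = as.integer(window),
                 negation_words = tolower(negation_words),
                 conjunction_words = tolower(conjunction_words),
                 substrate_prefixes = tolower(substrate_prefixes),
                 significant_prefix = tolower(significant_prefix)),
            class = "cpi_feature_config")
}

.window_tokens <- function(tokens, first_pos, last_pos, window) {
  lo <- seq_len(first_pos - 1L)
  lo <- lo[lo >= first_pos - window]
  hi <- seq(last_pos + 1L, length.out = window)
  hi <- hi[hi <= length(tokens)]
  tolower(tokens[c(lo, hi)])
}

.has_prefix <- function(words, prefixes) {
  any(vapply(prefixes, function(p) any(startsWith(words, p)), logical(1)))
}

.in_brackets <- function(tokens, pos) {
  if (grepl("[][(){}]", tokens[pos])) return(TRUE)
  before <- if (pos > 1L) tokens[seq_len(pos - 1L)] else character(0)
  after <- if (pos < length(tokens)) tokens[seq(pos + 1L, length(tokens))]
  else character(0)
  any(before %in% c("(", "[", "{")) && any(after %in% c(")", "]", "}"))
}

#' Semantic-pattern features of a CPI pair
#'
#' Emits, on the masked token sequence: `SenLen` (number of tokens),
#' `pos_e1`/`pos_e2` (tokens lying before the first-/second-occurring focal
#' entity), `NEntities` (other tagged entities in the sentence),
#' `Significant`, `isBracket`, `isSubstrate`, `isAdjacent`, and the
#' negation and conjunction cue flags over the region covered by the pair.
#' When a dependency graph is supplied, the CHEM-PROT shortest-path step
#' count `steps_sp3`, its word distance `words_sp3` and the `no_path3`
#' sentinel flag are included (a disconnected pair takes the sentence token
#' count as step/word sentinel).
#'
#' @param masked A `masked_sentence` from [mask_entities()].
#' @param graph Optional `dep_graph` over the masked tokens.
#' @param config A [cpi_feature_config()].
#' @return Named numeric vector.
#' @export
pair_semantic_features <- function(masked, graph = NULL,
                                   config = cpi_feature_config()) {
  tokens <- masked$tokens$token
  n <- length(tokens)
  a <- min(masked$chem_pos, masked$prot_pos)  # e1 = first-occurring focal
  b <- max(masked$chem_pos, masked$prot_pos)
  if (a < 1L || b > n) stop("focal pair not inside sentence", call. = FALSE)
  win <- .window_tokens(tokens, a, b, config$window)
  region <- tolower(tokens[a:b])
  out <- c(
    SenLen = n,
    pos_e1 = a - 1L,
    pos_e2 = b - 1L,
    NEntities = length(masked$cpt_pos),
    Significant = as.numeric(.has_prefix(win, config$significant_prefix)),
    isBracket = as.numeric(.in_brackets(tokens, masked$chem_pos) ||
                             .in_brackets(tokens, masked$prot_pos)),
    isSubstrate = as.numeric(.has_prefix(win, config$substrate_prefixes)),
    isAdjacent = as.numeric(b - a == 1L),
    negation = as.numeric(any(region %in% config$negation_words)),
    conjunction = as.numeric(any(region %in% config$conjunction_words)))
  if (!is.null(graph)) {
    p3 <- shortest_dep_path(graph, masked$chem_pos, masked$prot_pos)
    out <- c(out,
             steps_sp3 = if (is.null(p3)) n else p3$length,
             words_sp3 = if (is.null(p3)) n else length(p3$nodes),
             no_path3 = as.numeric(is.null(p3)))
  }
  out
}

#' Semantic-pattern features of a CPI triplet
#'
#' All pair features plus `pos_iw` (tokens before the interaction word),
#' the CHEM-iw and iw-PROT shortest-path step counts `steps_sp1` /
#' `steps_sp2` (when a graph is supplied), a one-hot of the path topology
#' [sp_type()] (types 0-7 plus the disconnected sentinel), and a one-hot of
#' the dictionary CPR group of the interaction word. The negation and
#' conjunction region extends to cover the interaction word.
#'
#' @param masked A `masked_sentence`.
#' @param iw_index Token position of the interaction word.
#' @param iw_cpr Dictionary-mapped CPR group (1-10) of the interaction word.
#' @param graph Optional `dep_graph`.
#' @param config A [cpi_feature_config()].
#' @return Named numeric vector.
#' @export
triplet_semantic_features <- function(masked, iw_index, iw_cpr, graph = NULL,
                                      config = cpi_feature_config()) {
  tokens <- masked$tokens$token
  n <- length(tokens)
  out <- pair_semantic_features(masked, graph = graph, config = config)
  lo <- min(masked$chem_pos, masked$prot_pos, iw_index)
  hi <- max(masked$chem_pos, masked$prot_pos, iw_index)
  region <- tolower(tokens[lo:hi])
  out["negation"] <- as.numeric(any(region %in% config$negation_words))
  out["conjunction"] <- as.numeric(any(region %in% config$conjunction_words))
  out <- c(out, pos_iw = iw_index - 1L)
  st <- -1L
  if (!is.null(graph)) {
    p1 <- shortest_dep_path(graph, masked$chem_pos, iw_index)
    p2 <- shortest_dep_path(graph, iw_index, masked$prot_pos)
    out <- c(out,
             steps_sp1 = if (is.null(p1)) n else p1$length,
             words_sp1 = if (is.null(p1)) n else length(p1$nodes),
             no_path1 = as.numeric(is.null(p1)),
             steps_sp2 = if (is.null(p2)) n else p2$length,
             words_sp2 = if (is.null(p2)) n else length(p2$nodes),
             no_path2 = as.numeric(is.null(p2)))
    st <- sp_type(graph, masked$chem_pos, iw_index, masked$prot_pos)
  }
  st_levels <- c(-1L, 0:7)
  st_onehot <- as.numeric(st_levels == st)
  names(st_onehot) <- paste0("sp_type_", sub("^-1$", "m1", st_levels))
  cpr_onehot <- as.numeric(1:10 == iw_cpr)
  names(cpr_onehot) <- paste0("iw_cpr_", 1:10)
  c(out, st_onehot, cpr_onehot)
}

#' Shortest-dependency-path label features
#'
#' Collects the typed-dependency labels along the CHEM-PROT path (and, for
#' triplets, the CHEM-iw and iw-PROT paths) for one-hot encoding over the
#' fit-time label vocabulary, plus an appositive-presence flag: a CHEM-PROT
#' path containing an `appos` dependency signals that the two mentions are
#' in apposition rather than interacting.
#'
#' @param graph A `dep_graph` over the masked tokens.
#' @param masked A `masked_sentence`.
#' @param iw_index Optional interaction-word token position (triplets).
#' @return List with `labels` (named list of character vectors: `sp3` and,
#'   for triplets, `sp1`, `sp2`) and `num` (named numeric: `appos_sp3`).
#' @export
sdp_label_features <- function(graph, masked, iw_index = NULL) {
  p3 <- shortest_dep_path(graph, masked$chem_pos, masked$prot_pos)
  labels <- list(sp3 = path_labels(p3))
  if (!is.null(iw_index)) {
    labels$sp1 <- path_labels(shortest_dep_path(graph, masked$chem_pos,
                                                iw_index))
    labels$sp2 <- path_labels(shortest_dep_path(graph, iw_index,
                                                masked$prot_pos))
  }
  list(labels = labels,
       num = c(appos_sp3 = as.numeric(any(grepl("^appos", labels$sp3)))))
}

.onehot_labels <- function(labels, vocab, prefix) {
  v <- as.numeric(vocab %in% labels)
  names(v) <- paste0(prefix, "_dep_", vocab)
  v
}

#' Assemble a named-column feature matrix for a candidate track
#'
#' Runs the semantic and dependency-path extractors over every candidate of
#' one track and assembles a numeric matrix with a frozen column registry.
#' With `registry = NULL` the call is a fit: the dependency-label
#' vocabulary is learned from the supplied parses and the column order is
#' frozen. With a registry from a previous fit, columns are aligned to it
#' exactly: dependency labels unseen at fit time encode as all-zero
#' one-hots and fit-time columns missing here are zero-filled.
#'
#' @param candidates A `cpi_candidates` object.
#' @param parser A parser adapter function (see [parse_masked()]).
#' @param track `"pair"` or `"triplet"`.
#' @param registry `NULL` (fit) or a registry from a previous call.
#' @param config A [cpi_feature_config()].
#' @return List with `X` (numeric matrix, one row per candidate in the
#'   track's table order), `registry` and `graphs` (per-pair parse cache,
#'   indexed by pair_id).
#' @export
encode_matrix <- function(candidates, parser, track = c("pair", "triplet"),
                          registry = NULL, config = cpi_feature_config()) {
  track <- match.arg(track)
  stopifnot(inherits(candidates, "cpi_candidates"))
  graphs <- lapply(candidates$masked, parse_masked, adapter = parser)

  rows <- if (track == "pair") candidates$pairs else candidates$triplets
  vecs <- vector("list", nrow(rows))
  labsets <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    pid <- rows$pair_id[i]
    ms <- candidates$masked[[pid]]
    g <- graphs[[pid]]
    if (track == "pair") {
      sem <- pair_semantic_features(ms, graph = g, config = config)
      sdp <- sdp_label_features(g, ms)
    } else {
      sem <- triplet_semantic_features(ms, rows$iw_index[i], rows$iw_cpr[i],
                                       graph = g, config = config)
      sdp <- sdp_label_features(g, ms, iw_index = rows$iw_index[i])
    }
    vecs[[i]] <- c(sem, sdp$num)
    labsets[[i]] <- sdp$labels
  }

  path_names <- if (track == "pair") "sp3" else c("sp3", "sp1", "sp2")
  if (is.null(registry)) {
    vocab <- sort(unique(unlist(lapply(labsets, function(l) unlist(l)))))
    base_cols <- if (length(vecs)) names(vecs[[1]]) else
      .base_feature_names(track)
    cols <- c(base_cols,
              unlist(lapply(path_names, function(p)
                paste0(p, "_dep_", vocab))))
    registry <- list(track = track, columns = cols, dep_vocab = vocab,
                     base = base_cols)
  } else {
    if (!identical(registry$track, track)) {
      stop("feature registry was fitted for the '", registry$track,
           "' track", call. = FALSE)
    }
    vocab <- registry$dep_vocab
  }

  X <- matrix(0, nrow = nrow(rows), ncol = length(registry$columns),
              dimnames = list(NULL, registry$columns))
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    unknown <- setdiff(names(v), registry$base)
    if (length(unknown)) {
      stop("novel feature name(s) at predict time: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    X[i, names(v)] <- v
    for (p in path_names) {
      oh <- .onehot_labels(labsets[[i]][[p]], vocab, p)
      if (length(oh)) X[i, names(oh)] <- oh
    }
  }
  list(X = X, registry = registry, graphs = graphs)
}

.base_feature_names <- function(track) {
  base <- c("SenLen", "pos_e1", "pos_e2", "NEntities", "Significant",
            "isBracket", "isSubstrate", "isAdjacent", "negation",
            "conjunction", "steps_sp3", "words_sp3", "no_path3", "appos_sp3")
  if (track == "pair") return(base)
  c(base[1:13], "pos_iw", "steps_sp1", "words_sp1", "no_path1", "steps_sp2",
    "words_sp2", "no_path2",
    paste0("sp_type_", c("m1", 0:7)), paste0("iw_cpr_", 1:10), "appos_sp3")
}
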