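#' @title Dependency graphs and shortest dependency paths
#' @description A dependency graph has one node per token of a masked
#'   sentence and typed dependency edges (head, dependent, label). Shortest
#'   dependency paths (SDPs) are computed on the undirected view of the
#'   graph, the standard practice for SDP-based relation extraction; ties
#'   between equal-length paths are broken by the lexicographically smallest
#'   node-index sequence so the whole pipeline is deterministic.
#' @name depgraph
NULL

#' Construct a dependency graph
#'
#' @param tokens Character vector of node tokens (node i = token i).
#' @param edges data.frame with columns `head`, `dep` (1-based node
#'   indices; a head of 0 marks the root and is dropped) and `label`.
#' @return A `dep_graph` object.
#' @export
dep_graph <- function(tokens, edges) {
  n <- length(tokens)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(head = integer(), dep = integer(),
                        label = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(head = as.integer(edges$head),
                        dep = as.integer(edges$dep),
                        label = as.character(edges$label),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$head != 0L, , drop = FALSE]
    if (nrow(edges)) {
      if (any(edges$head < 1L | edges$head > n | edges$dep < 1L |
                edges$dep > n)) {
        stop("dependency edge endpoint outside node range", call. = FALSE)
      }
      key <- paste(edges$head, edges$dep)
      if (anyDuplicated(key)) {
        stop("more than one labeled edge for an ordered node pair",
             call. = FALSE)
      }
    }
  }
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    h <- edges$head[i]; d <- edges$dep[i]
    adj[[h]] <- c(adj[[h]], d)
    adj[[d]] <- c(adj[[d]], h)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(tokens = tokens, edges = edges, adj = adj, n = n),
            class = "dep_graph")
}

#' @export
print.dep_graph <- function(x, ...) {
  cat("Dependency graph:", x$n, "nodes,", nrow(x$edges), "typed edges\n")
  invisible(x)
}

.bfs_dist <- function(g, from) {
  dist <- rep(NA_integer_, g$n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in g$adj[[u]]) {
        if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; nxt <- c(nxt, v) }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Shortest dependency path between two nodes
#'
#' Minimum-edge-count path on the undirected graph. Among equal-length
#' paths the lexicographically smallest node-index sequence is returned.
#'
#' @param g A `dep_graph`.
#' @param a,b Node indices.
#' @return A `dep_path` list (`nodes`, `labels`, `length`) or `NULL` when
#'   `a` and `b` are disconnected. `a == b` yields a path of length 0.
#' @export
shortest_dep_path <- function(g, a, b) {
  stopifnot(inherits(g, "dep_graph"))
  if (a < 1L || a > g$n || b < 1L || b > g$n) {
    stop("invalid node index", call. = FALSE)
  }
  if (a == b) {
    return(structure(list(nodes = a, labels = character(0), length = 0L),
                     class = "dep_path"))
  }
  dist_b <- .bfs_dist(g, b)
  if (is.na(dist_b[a])) return(NULL)
  nodes <- a
  cur <- a
  while (cur != b) {
    nbr <- g$adj[[cur]]
    nbr <- nbr[!is.na(dist_b[nbr]) & dist_b[nbr] == dist_b[cur] - 1L]
    cur <- min(nbr)  # adjacency sorted: smallest next node = lexicographic min
    nodes <- c(nodes, cur)
  }
  labels <- character(length(nodes) - 1L)
  for (i in seq_len(length(nodes) - 1L)) {
    u <- nodes[i]; v <- nodes[i + 1L]
    hit <- which(g$edges$head == u & g$edges$dep == v)
    if (!length(hit)) hit <- which(g$edges$head == v & g$edges$dep == u)
    labels[i] <- g$edges$label[hit[1]]
  }
  structure(list(nodes = nodes, labels = labels, length = length(nodes) - 1L),
            class = "dep_path")
}

#' Dependency-label multiset of a path
#'
#' @param path A `dep_path` (or `NULL`).
#' @return Character vector of edge labels (with multiplicity); empty for a
#'   length-0 or missing path.
#' @export
path_labels <- function(path) {
  if (is.null(path)) return(character(0))
  path$labels
}

.path_edge_set <- function(path) {
  if (is.null(path) || path$length == 0L) return(character(0))
  u <- path$nodes[-length(path$nodes)]
  v <- path$nodes[-1]
  paste(pmin(u, v), pmax(u, v))
}

#' Topology type of the (e1, iw, e2) sub-structure
#'
#' Classifies how the two entities and the interaction word relate in the
#' dependency graph, as an integer 0-7:
#' \describe{
#'   \item{0}{iw lies on a shortest path between e1 and e2 (e1-iw-e2).}
#'   \item{1}{e1 lies on a shortest path between iw and e2 (iw-e1-e2).}
#'   \item{2}{e2 lies on a shortest path between e1 and iw (e1-e2-iw).}
#'   \item{3}{star: no element between the other two; the three pairwise
#'     SDPs all share edges (they meet at a hub).}
#'   \item{4}{triangle: the three pairwise SDPs are mutually edge-disjoint,
#'     forming a cycle through e1, iw and e2.}
#'   \item{5}{star plus a separate path between e1 and e2.}
#'   \item{6}{star plus a separate path between iw and e2.}
#'   \item{7}{star plus a separate path between iw and e1.}
#' }
#' A disconnected triple returns the sentinel -1, which downstream feature
#' encoding carries as its own one-hot category.
#'
#' @param g A `dep_graph`.
#' @param e1,iw,e2 Node indices of entity 1, the interaction word, entity 2.
#' @return Integer in -1, 0..7.
#' @export
sp_type <- function(g, e1, iw, e2) {
  stopifnot(inherits(g, "dep_graph"))
  d1 <- .bfs_dist(g, e1); di <- .bfs_dist(g, iw)
  d12 <- d1[e2]; d1i <- d1[iw]; di2 <- di[e2]
  if (is.na(d12) || is.na(d1i) || is.na(di2)) return(-1L)
  # betweenness on shortest paths (any shortest path, not just the
  # tie-broken representative)
  if (d1i + di2 == d12) return(0L)
  if (d1i + d12 == di2) return(1L)
  if (d12 + di2 == d1i) return(2L)
  s12 <- .path_edge_set(shortest_dep_path(g, e1, e2))
  s1i <- .path_edge_set(shortest_dep_path(g, e1, iw))
  si2 <- .path_edge_set(shortest_dep_path(g, iw, e2))
  dj_12_1i <- !length(intersect(s12, s1i))
  dj_12_i2 <- !length(intersect(s12, si2))
  dj_1i_i2 <- !length(intersect(s1i, si2))
  n_dj <- dj_12_1i + dj_12_i2 + dj_1i_i2
  if (n_dj == 3L) return(4L)
  if (n_dj == 2L) {
    if (dj_12_1i && dj_12_i2) return(5L)  # e1-e2 path separate from the legs
    if (dj_12_i2 && dj_1i_i2) return(6L)  # iw-e2 path separate
    return(7L)                            # iw-e1 path separate
  }
  3L
}

#' Parse a masked sentence through a parser adapter
#'
#' A parser adapter is any function mapping a masked token sequence
#' (character vector) to a `dep_graph` over exactly those tokens; bundled
#' adapters are the fixture store ([parser_from_fixtures()]) and the
#' CoNLL-U reader ([read_conllu_parses()]).
#'
#' @param masked A `masked_sentence` from [mask_entities()], or a character
#'   vector of tokens.
#' @param adapter The adapter function.
#' @return A `dep_graph`.
#' @export
parse_masked <- function(masked, adapter) {
  tokens <- if (inherits(masked, "masked_sentence")) masked$tokens$token
  else as.character(masked)
  g <- adapter(tokens)
  if (!inherits(g, "dep_graph") || g$n != length(tokens)) {
    stop("parser adapter contract violation: node count must equal token ",
         "count", call. = FALSE)
  }
  g
}

.normalize_parse_key <- function(tokens) {
  tokens[grepl("^(CHEM|PROT|CPT[0-9]+|ENT)$", tokens)] <- "ENT"
  paste(tokens, collapse = "\r")
}

#' Build a parser adapter from stored fixture parses
#'
#' Looks a token sequence up by exact match first, then with all entity
#' placeholders (`CHEM`, `PROT`, `CPTk`) normalized to a generic `ENT`
#' symbol, so one stored parse covers every focal-pair masking of the same
#' sentence shape.
#'
#' @param store List of records, each `list(tokens = <chr>, edges =
#'   <data.frame head/dep/label>)`, e.g. from [read_parse_fixtures()].
#' @return An adapter `function(tokens) -> dep_graph`.
#' @export
parser_from_fixtures <- function(store) {
  exact <- new.env(parent = emptyenv())
  norm <- new.env(parent = emptyenv())
  for (rec in store) {
    key <- paste(rec$tokens, collapse = "\r")
    assign(key, rec, envir = exact)
    nk <- .normalize_parse_key(rec$tokens)
    if (!exists(nk, envir = norm, inherits = FALSE)) {
      assign(nk, rec, envir = norm)
    }
  }
  function(tokens) {
    key <- paste(tokens, collapse = "\r")
    rec <- if (exists(key, envir = exact, inherits = FALSE)) {
      get(key, envir = exact)
    } else {
      nk <- .normalize_parse_key(tokens)
      if (!exists(nk, envir = norm, inherits = FALSE)) {
        stop("no fixture parse for token sequence: ",
             paste(tokens, collapse = " "), call. = FALSE)
      }
      get(nk, envir = norm)
    }
    dep_graph(tokens, rec$edges)
  }
}

#' Read JSON-lines parse fixtures
#'
#' One record per line: `{"tokens": [...], "edges": [[head, dep, label],
#'   ...]}`.
#'
#' @param path File path.
#' @return A store list usable with [parser_from_fixtures()].
#' @export
read_parse_fixtures <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    edges <- if (length(rec$edges)) {
      data.frame(head = vapply(rec$edges, function(e) as.integer(e[[1]]), integer(1)),
                 dep = vapply(rec$edges, function(e) as.integer(e[[2]]), integer(1)),
                 label = vapply(rec$edges, function(e) as.character(e[[3]]), character(1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(head = integer(), dep = integer(), label = character(),
                 stringsAsFactors = FALSE)
    }
    list(tokens = vapply(rec$tokens, as.character, character(1)), edges = edges)
  })
}

#' Write JSON-lines parse fixtures
#'
#' @param store List of `list(tokens, edges)` records.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_parse_fixtures <- function(store, path) {
  lines <- vapply(store, function(rec) {
    edges <- lapply(seq_len(nrow(rec$edges)), function(i) {
      list(rec$edges$head[i], rec$edges$dep[i], rec$edges$label[i])
    })
    jsonlite::toJSON(list(tokens = rec$tokens, edges = edges),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sentence parses from a CoNLL-U file
#'
#' Minimal CoNLL-U support: sentences separated by blank lines; columns
#' ID, FORM, ..., HEAD (7th), DEPREL (8th); multi-word-token and empty-node
#' lines are skipped.
#'
#' @param path CoNLL-U file path.
#' @return A store list usable with [parser_from_fixtures()].
#' @export
read_conllu_parses <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  store <- list()
  cur <- list()
  flush <- function(cur, store) {
    if (!length(cur)) return(store)
    tok <- vapply(cur, `[[`, character(1), 2L)
    head <- as.integer(vapply(cur, `[[`, character(1), 7L))
    rel <- vapply(cur, `[[`, character(1), 8L)
    edges <- data.frame(head = head, dep = seq_along(tok), label = rel,
                        stringsAsFactors = FALSE)
    c(store, list(list(tokens = tok, edges = edges)))
  }
  for (l in lines) {
    if (!nzchar(trimws(l))) { store <- flush(cur, store); cur <- list(); next }
    if (startsWith(l, "#")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || grepl("[-.]", f[1])) next
    cur[[length(cur) + 1L]] <- f
  }
  flush(cur, store)
}
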