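chain_graph <- function(n, labels = rep("dep", n - 1)) {
  dep_graph(paste0("w", 1:n),
            data.frame(head = 1:(n - 1), dep = 2:n, label = labels))
}

test_that("shortest paths match breadth-first oracle values", {
  g <- chain_graph(5)
  p <- shortest_dep_path(g, 1, 5)
  expect_equal(p$length, 4L)
  expect_equal(p$nodes, 1:5)
  expect_equal(shortest_dep_path(g, 3, 3)$length, 0L)
  expect_error(shortest_dep_path(g, 0, 3), "invalid node")
  # disconnected
  g2 <- dep_graph(c("a", "b", "c"),
                  data.frame(head = 1, dep = 2, label = "nsubj"))
  expect_null(shortest_dep_path(g2, 1, 3))
})

test_that("random graphs: distances equal igraph, paths are lexicographically minimal", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    g <- rand_dep_graph(n)
    D <- igraph_dists(g)
    a <- sample(n, 1); b <- sample(n, 1)
    p <- shortest_dep_path(g, a, b)
    if (is.infinite(D[a, b])) {
      expect_null(p)
    } else {
      expect_equal(p$length, as.integer(D[a, b]))
      # validity: consecutive nodes adjacent
      if (p$length > 0) {
        for (j in seq_len(p$length)) {
          expect_true(p$nodes[j + 1] %in% g$adj[[p$nodes[j]]])
        }
      }
      # lexicographic minimality among all shortest paths (igraph oracle)
      all_sp <- igraph::all_shortest_paths(to_igraph(g), from = a,
                                           to = b)$vpaths
      seqs <- lapply(all_sp, function(v) as.integer(v))
      keys <- vapply(seqs, function(s)
        paste(sprintf("%03d", s), collapse = ""), character(1))
      expect_equal(p$nodes, seqs[[which.min(keys)]])
    }
  }
})

test_that("path length is symmetric and satisfies the triangle inequality", {
  set.seed(77)
  for (i in 1:40) {
    g <- rand_dep_graph(sample(4:7, 1), p = 0.6)
    n <- g$n
    d <- function(a, b) {
      p <- shortest_dep_path(g, a, b)
      if (is.null(p)) NA_integer_ else p$length
    }
    a <- sample(n, 1); b <- sample(n, 1); c <- sample(n, 1)
    expect_equal(d(a, b), d(b, a))
    dab <- d(a, b); dbc <- d(b, c); dac <- d(a, c)
    if (!anyNA(c(dab, dbc, dac))) expect_lte(dac, dab + dbc)
  }
})

test_that("path topology types match their defining shapes", {
  # chain e1 - iw - e2 -> type 0
  g <- chain_graph(3)
  expect_equal(sp_type(g, 1, 2, 3), 0L)
  # orderings 1 and 2
  expect_equal(sp_type(g, 2, 1, 3), 1L)  # e1 between iw and e2
  expect_equal(sp_type(g, 1, 3, 2), 2L)  # e2 between e1 and iw
  # star with hub 4
  g <- dep_graph(paste0("w", 1:4),
                 data.frame(head = 4, dep = 1:3, label = "dep"))
  expect_equal(sp_type(g, 1, 2, 3), 3L)
  # triangle
  g <- dep_graph(paste0("w", 1:3),
                 data.frame(head = c(1, 2, 3), dep = c(2, 3, 1),
                            label = "dep"))
  expect_equal(sp_type(g, 1, 2, 3), 4L)
  # star with length-2 legs plus a separate connecting path
  star2 <- function(extra_head, extra_dep) {
    # e1=1, iw=2, e2=3; legs 1-4-7, 2-5-7, 3-6-7
    dep_graph(paste0("w", 1:7),
              data.frame(head = c(1, 4, 2, 5, 3, 6, extra_head),
                         dep = c(4, 7, 5, 7, 6, 7, extra_dep),
                         label = "dep"))
  }
  expect_equal(sp_type(star2(1, 3), 1, 2, 3), 5L)  # extra e1-e2 edge
  expect_equal(sp_type(star2(2, 3), 1, 2, 3), 6L)  # extra iw-e2 edge
  expect_equal(sp_type(star2(2, 1), 1, 2, 3), 7L)  # extra iw-e1 edge
  # disconnected triple -> sentinel
  g <- dep_graph(c("a", "b", "c"),
                 data.frame(head = 1, dep = 2, label = "dep"))
  expect_equal(sp_type(g, 1, 2, 3), -1L)
})

test_that("every returned type's defining predicate re-checks independently", {
  # independent checker built on igraph distances and path enumeration
  check_type <- function(g, e1, iw, e2, t) {
    D <- igraph_dists(g)
    if (any(is.infinite(c(D[e1, e2], D[e1, iw], D[iw, e2])))) {
      return(t == -1L)
    }
    betw <- c(D[e1, iw] + D[iw, e2] == D[e1, e2],
              D[iw, e1] + D[e1, e2] == D[iw, e2],
              D[e1, e2] + D[e2, iw] == D[e1, iw])
    if (any(betw)) return(t == (which(betw)[1] - 1L))
    lex_path <- function(a, b) {
      sp <- igraph::all_shortest_paths(to_igraph(g), from = a, to = b)$vpaths
      seqs <- lapply(sp, as.integer)
      keys <- vapply(seqs, function(s)
        paste(sprintf("%03d", s), collapse = ""), character(1))
      s <- seqs[[which.min(keys)]]
      paste(pmin(s[-length(s)], s[-1]), pmax(s[-length(s)], s[-1]))
    }
    p12 <- lex_path(e1, e2); p1i <- lex_path(e1, iw); pi2 <- lex_path(iw, e2)
    dj <- c(length(intersect(p12, p1i)) == 0,
            length(intersect(p12, pi2)) == 0,
            length(intersect(p1i, pi2)) == 0)
    if (all(dj)) return(t == 4L)
    if (sum(dj) == 2) {
      if (dj[1] && dj[2]) return(t == 5L)
      if (dj[2] && dj[3]) return(t == 6L)
      return(t == 7L)
    }
    t == 3L
  }
  # exhaustive over all 4-node graphs, all ordered triples
  pairs4 <- utils::combn(4, 2)
  trips <- expand.grid(e1 = 1:4, iw = 1:4, e2 = 1:4)
  trips <- trips[trips$e1 != trips$iw & trips$iw != trips$e2 &
                   trips$e1 != trips$e2, ]
  for (mask in 0:(2^6 - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:5)) > 0)
    edges <- if (length(sel)) {
      data.frame(head = pairs4[1, sel], dep = pairs4[2, sel], label = "dep")
    } else data.frame(head = integer(), dep = integer(),
                      label = character())
    g <- dep_graph(paste0("w", 1:4), edges)
    for (r in seq_len(nrow(trips))) {
      t <- sp_type(g, trips$e1[r], trips$iw[r], trips$e2[r])
      expect_true(check_type(g, trips$e1[r], trips$iw[r], trips$e2[r], t))
    }
  }
  # random 5-6 node graphs
  set.seed(303)
  for (i in 1:150) {
    g <- rand_dep_graph(sample(5:6, 1), p = 0.4)
    v <- sample(g$n, 3)
    t <- sp_type(g, v[1], v[2], v[3])
    expect_true(check_type(g, v[1], v[2], v[3], t))
  }
})

test_that("path labels expose typed dependencies and the appositive cue", {
  g <- dep_graph(c("SGT", "interacts", "GHR"),
                 data.frame(head = c(2, 2), dep = c(1, 3),
                            label = c("nsubj", "compound")))
  p <- shortest_dep_path(g, 1, 3)
  expect_setequal(path_labels(p), c("nsubj", "compound"))
  expect_equal(path_labels(shortest_dep_path(g, 2, 2)), character(0))
  ms <- make_masked(c("CHEM", ",", "PROT"), 1L, 3L)
  g2 <- dep_graph(c("CHEM", ",", "PROT"),
                  data.frame(head = c(1, 1), dep = c(2, 3),
                             label = c("punct", "appos")))
  f <- sdp_label_features(g2, ms)
  expect_equal(unname(f$num["appos_sp3"]), 1)
  expect_true("appos" %in% f$labels$sp3)
})

test_that("parser adapters honour the node-count contract and fixtures", {
  store <- list(list(tokens = c("CHEM", "binds", "PROT"),
                     edges = data.frame(head = c(2, 2), dep = c(1, 3),
                                        label = c("nsubj", "obj"))))
  ad <- parser_from_fixtures(store)
  g <- parse_masked(c("CHEM", "binds", "PROT"), ad)
  expect_s3_class(g, "dep_graph")
  # normalized lookup: other placeholder assignments reuse the same parse
  g2 <- parse_masked(c("PROT", "binds", "CHEM"), ad)
  expect_equal(g2$edges$label, g$edges$label)
  g3 <- parse_masked(c("CPT4", "binds", "CHEM"), ad)
  expect_equal(g3$n, 3L)
  expect_error(parse_masked(c("CHEM", "inhibits", "PROT"), ad),
               "no fixture parse")
  bad <- function(tokens) dep_graph(c("x", "y"), NULL)
  expect_error(parse_masked(c("CHEM", "binds", "PROT"), bad),
               "contract violation")
  # determinism
  expect_identical(parse_masked(c("CHEM", "binds", "PROT"), ad),
                   parse_masked(c("CHEM", "binds", "PROT"), ad))
})

test_that("JSON-lines and CoNLL-U parse stores round-trip", {
  store <- list(
    list(tokens = c("CHEM", "binds", "PROT", "."),
         edges = data.frame(head = c(2, 2, 2), dep = c(1, 3, 4),
                            label = c("nsubj", "obj", "punct"))),
    list(tokens = c("one"),
         edges = data.frame(head = integer(), dep = integer(),
                            label = character())))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_parse_fixtures(store, path)
  back <- read_parse_fixtures(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$tokens, store[[1]]$tokens)
  expect_equal(back[[1]]$edges$label, store[[1]]$edges$label)
  expect_equal(back[[2]]$edges, store[[2]]$edges)

  cpath <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c(
    "# sent_id = 1",
    "1\tCHEM\t_\t_\t_\t_\t2\tnsubj\t_\t_",
    "2\tbinds\t_\t_\t_\t_\t0\troot\t_\t_",
    "3\tPROT\t_\t_\t_\t_\t2\tobj\t_\t_",
    "",
    "1\tsingle\t_\t_\t_\t_\t0\troot\t_\t_"), cpath)
  st <- read_conllu_parses(cpath)
  expect_equal(length(st), 2L)
  expect_equal(st[[1]]$tokens, c("CHEM", "binds", "PROT"))
  g <- parse_masked(st[[1]]$tokens, parser_from_fixtures(st))
  expect_equal(nrow(g$edges), 2L)  # root line carries no edge
})
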