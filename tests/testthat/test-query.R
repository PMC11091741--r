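test_that("a 3-step chain with R = last step yields the 4-node query", {
  w <- awr("w", c(1, 2, 3), rbind(c(1, 2), c(2, 3)))
  qg <- build_query_graph(w, target_step = NA, R = 3)
  expect_equal(qg$node_tools, c(1L, 2L, 3L, QUERY_TOOL))
  expect_equal(sort_edges(qg$edges),
               sort_edges(rbind(c(1, 2), c(2, 3), c(3, 4))))
  expect_equal(qg$input_length, 3)
})

test_that("a single-step workflow yields the minimal query {step, q}", {
  w <- awr("w", 7L)
  qg <- build_query_graph(w, NA, R = 1)
  expect_equal(qg$node_tools, c(7L, QUERY_TOOL))
  expect_equal(sort_edges(qg$edges), sort_edges(rbind(c(1, 2))))
})

test_that("upstream closure excludes branches not feeding R", {
  # 1 -> 2, 1 -> 3; R = {2}: node 3 is not upstream of R
  w <- awr("w", c(1, 2, 3), rbind(c(1, 2), c(1, 3)))
  qg <- build_query_graph(w, NA, R = 2)
  expect_equal(qg$steps, c(1L, 2L))
  expect_equal(qg$node_tools, c(1L, 2L, QUERY_TOOL))
})

test_that("upstream closure matches a brute-force reverse-reachability oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(3:9, 1)
    edges <- random_dag(n, 0.35)
    w <- awr("w", sample(20, n, replace = TRUE), edges)
    R <- sample(n, sample(1:2, 1))
    qg <- build_query_graph(w, NA, R)
    expect_equal(qg$steps, oracle_upstream(n, edges, R))
  }
})

test_that("query node has only incoming edges, all from R", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    w <- awr("w", sample(20, n, replace = TRUE), random_dag(n, 0.4))
    R <- sample(n, sample(1:3, 1))
    qg <- build_query_graph(w, NA, R)
    q <- length(qg$node_tools)
    expect_false(any(qg$edges[, 1] == q))
    into_q <- qg$edges[qg$edges[, 2] == q, 1]
    expect_setequal(into_q, qg$r_nodes)
  }
})

test_that("R must be non-empty and must not contain the target", {
  w <- awr("w", c(1, 2), rbind(c(1, 2)))
  expect_error(build_query_graph(w, 2, integer(0)), "at least one")
  expect_error(build_query_graph(w, 2, R = 2), "target step")
})

test_that("graph-mode query count equals steps with in-degree >= 1", {
  # linear 3-step workflow: 2 queries
  w <- awr("w", c(1, 2, 3), rbind(c(1, 2), c(2, 3)))
  expect_length(extract_prefix_queries(w, "graph"), 2)
  # diamond 1 -> {2, 3} -> 4: 3 queries, one with R = {2, 3}
  d <- awr("d", c(1, 2, 3, 4),
           rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  qs <- extract_prefix_queries(d, "graph")
  expect_length(qs, 3)
  r_sizes <- vapply(qs, function(q) length(q$r_nodes), integer(1))
  expect_equal(sort(r_sizes), c(1L, 1L, 2L))
  # property over random DAGs
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    edges <- random_dag(n)
    w <- awr("w", sample(9, n, replace = TRUE), edges)
    indeg_pos <- if (nrow(edges) > 0) length(unique(edges[, 2])) else 0
    expect_length(extract_prefix_queries(w, "graph"), indeg_pos)
  }
})

test_that("sequence mode yields L - 1 prefix queries for a linear workflow", {
  w <- awr("w", c(4, 5, 6, 7), cbind(1:3, 2:4))
  qs <- extract_prefix_queries(w, "sequence")
  expect_length(qs, 3)
  expect_equal(qs[[2]]$node_tools, c(4L, 5L, QUERY_TOOL))
  expect_equal(qs[[2]]$target, 6L)
})

test_that("sequence queries on a path equal graph queries with R = last", {
  w <- awr("w", c(3, 1, 4), rbind(c(1, 2), c(2, 3)))
  sq <- extract_prefix_queries(w, "sequence")
  for (k in seq_along(sq)) {
    prefix_w <- awr("p", w$tool_indices[seq_len(k)],
                    if (k > 1) cbind(seq_len(k - 1), 2:k) else NULL)
    gq <- build_query_graph(prefix_w, NA, R = k)
    expect_equal(sq[[k]]$node_tools, gq$node_tools)
    expect_equal(sort_edges(sq[[k]]$edges), sort_edges(gq$edges))
    expect_equal(sq[[k]]$r_nodes, gq$r_nodes)
  }
})

test_that("identical (prefix, target) pairs within a workflow collapse", {
  # path with a repeated bigram: 1,2,1,2 -> targets for prefix (1) and
  # (1,2,1) differ, but prefixes (1,2) vs (1,2) cannot arise twice; build a
  # workflow where two equal prefixes predict the same target
  w <- awr("w", c(1, 2, 1, 2), cbind(1:3, 2:4))
  qs <- extract_prefix_queries(w, "sequence")
  sigs <- vapply(qs, function(q)
    paste(paste(q$node_tools, collapse = ","), q$target, sep = "->"),
    character(1))
  expect_false(anyDuplicated(sigs) > 0)
})

test_that("connectivity matrix is the 0/1 adjacency with a_in = t(a_out)", {
  w <- awr("w", c(1, 2), rbind(c(1, 2)))
  qg <- build_query_graph(w, NA, R = 2)
  conn <- build_connectivity(qg)
  want <- matrix(0, 3, 3)
  want[1, 2] <- 1   # edge step1 -> step2
  want[2, 3] <- 1   # edge step2 -> q
  expect_equal(conn$a_out, want)
  expect_identical(conn$a_in, t(conn$a_out))
  expect_true(all(conn$A %in% c(0, 1)))
  expect_equal(dim(conn$A), c(3, 6))
  expect_equal(sum(conn$a_out), nrow(qg$edges))
})

test_that("connectivity row/column sums equal node degrees", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    w <- awr("w", sample(9, n, replace = TRUE), random_dag(n))
    qg <- build_query_graph(w, NA, R = sample(n, 1))
    conn <- build_connectivity(qg)
    m <- length(qg$node_tools)
    outdeg <- vapply(seq_len(m), function(i) sum(qg$edges[, 1] == i),
                     numeric(1))
    indeg <- vapply(seq_len(m), function(i) sum(qg$edges[, 2] == i),
                    numeric(1))
    expect_equal(rowSums(conn$a_out), outdeg)
    expect_equal(colSums(conn$a_out), indeg)
  }
})

test_that("query sets round-trip through JSONL", {
  g <- det_grammar()
  corpus <- generate_corpus(g, 3)
  qs <- corpus_queries(corpus, "graph")
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_queries_jsonl(qs, f)
  back <- read_queries_jsonl(f)
  expect_length(back, length(qs))
  for (i in seq_along(qs)) {
    expect_equal(back[[i]]$node_tools, qs[[i]]$node_tools)
    expect_equal(sort_edges(back[[i]]$edges), sort_edges(qs[[i]]$edges))
    expect_equal(back[[i]]$target, qs[[i]]$target)
  }
})
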