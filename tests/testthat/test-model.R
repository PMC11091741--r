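mk_conf <- function(...) model_config(d_t = 4, d_e = 4, ...)

test_that("vectorized propagation matches the scalar loop oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    d_half <- sample(2:4, 1)            # d_c = 2 * d_half <= 8
    mconf <- model_config(d_t = d_half, d_e = d_half)
    params <- init_model_params(5, mconf, seed = rep)
    edges <- random_dag(n, 0.5)
    X <- matrix(rnorm(n * mconf$d_c), n, mconf$d_c)
    conn <- list(a_out = {
      a <- matrix(0, n, n); if (nrow(edges) > 0) a[edges] <- 1; a
    })
    steps <- sample(1:2, 1)
    got <- propagate(X, conn, params, steps = steps)
    want <- oracle_propagate(X, edges, params, steps = steps)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("an isolated node's activation is exactly the bias", {
  mconf <- mk_conf()
  params <- init_model_params(3, mconf, seed = 1)
  params$b <- rep(0, 2 * mconf$d_c)
  X <- matrix(rnorm(mconf$d_c), 1, mconf$d_c)
  conn <- list(a_out = matrix(0, 1, 1))
  got <- propagate(X, conn, params, steps = 1)
  # with zero bias and no edges the GRU sees zero messages: result depends
  # only on U* and the current state
  want <- oracle_propagate(X, matrix(integer(0), ncol = 2), params, 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the gated update interpolates state and candidate", {
  # z = 0.5, v = 0, cand = 2 (pre-gate) => updated state 1
  z <- 0.5; v <- 0; cand <- 2
  expect_equal((1 - z) * v + z * cand, 1)
})

test_that("attention aggregation matches the scalar oracle", {
  set.seed(22)
  for (rep in 1:10) {
    mconf <- mk_conf()
    params <- init_model_params(6, mconf, seed = rep)
    n <- sample(2:5, 1)
    states <- matrix(rnorm((n + 1) * mconf$d_c), n + 1, mconf$d_c)
    r_nodes <- n                       # last real node
    agg <- aggregate_states(states, r_nodes, params, mconf)
    orc <- oracle_attention(states[1:n, , drop = FALSE], states[n, ], params)
    expect_equal(agg$w_g, orc$w_g, tolerance = 1e-6)
    expect_equal(agg$alpha, orc$alpha, tolerance = 1e-6)
    expect_equal(agg$w_l, states[n, ])
  }
})

test_that("single-node attention reduces to one weighted term", {
  mconf <- mk_conf()
  params <- init_model_params(4, mconf, seed = 3)
  s1 <- rnorm(mconf$d_c)
  states <- rbind(s1, rnorm(mconf$d_c))   # node + query
  dimnames(states) <- NULL
  agg <- aggregate_states(states, 1L, params, mconf)
  h <- 1 / (1 + exp(-(drop((params$W1 + params$W2) %*% s1) + params$b_att)))
  a1 <- sum(params$q_vec * h)
  expect_equal(agg$alpha, a1)
  expect_equal(agg$w_g, a1 * s1)
})

test_that("mean pooling of identical states returns that state", {
  mconf <- mk_conf(use_attention = FALSE)
  params <- init_model_params(4, mconf, seed = 4)
  s <- rnorm(mconf$d_c)
  states <- rbind(s, s, s, rnorm(mconf$d_c))   # 3 real + query
  agg <- aggregate_states(states, 3L, params, mconf)
  expect_equal(agg$w_g, s)
  expect_null(agg$alpha)
})

test_that("fusion and compression match direct matrix products", {
  set.seed(23)
  mconf <- mk_conf()
  params <- init_model_params(4, mconf, seed = 5)
  w_l <- rnorm(mconf$d_c); w_g <- rnorm(mconf$d_c)
  fus <- fuse_and_compress(w_l, w_g, params)
  expect_equal(fus$w_s, oracle_fuse(w_l, w_g, params), tolerance = 1e-6)
  # W3 = [I | 0], W4 = I projects out w_l exactly
  p2 <- params
  p2$W3 <- cbind(diag(mconf$d_c), matrix(0, mconf$d_c, mconf$d_c))
  p2$W4 <- diag(mconf$d_c)[seq_len(mconf$d_t), , drop = FALSE]
  expect_equal(fuse_and_compress(w_l, w_g, p2)$w_s, w_l[seq_len(mconf$d_t)])
  expect_equal(fuse_and_compress(rep(0, mconf$d_c), rep(0, mconf$d_c),
                                 params)$w_s, rep(0, mconf$d_t))
})

test_that("scoring excludes the QUERY row and matches softmax closed forms", {
  tabl <- rbind(c(1, 0), c(0, 0), c(5, 5))   # 2 tools + QUERY row
  sc0 <- score_tools(c(0, 0), tabl)
  expect_equal(sc0$yhat, c(0.5, 0.5))
  expect_length(sc0$yhat, 2)
  sc <- score_tools(c(log(2), 0), tabl)
  expect_equal(sc$yhat, c(2 / 3, 1 / 3))
  set.seed(24)
  W <- matrix(rnorm(24), 6, 4)
  w_s <- rnorm(4)
  expect_equal(score_tools(w_s, W)$yhat, oracle_score(w_s, W),
               tolerance = 1e-6)
  expect_equal(sum(score_tools(w_s, W)$yhat), 1)
})

test_that("probabilities sum to one and lie strictly inside (0, 1)", {
  set.seed(25)
  g <- det_grammar()
  mconf <- mk_conf()
  params <- init_model_params(length(g$toolbox$tool_id), mconf, seed = 6)
  desc <- encode_descriptions(g$toolbox, "mock", d_e = 4, seed = 1)
  qs <- corpus_queries(generate_corpus(g, 4), "graph")
  for (q in qs[1:5]) {
    fw <- forward_query(q, params, desc, mconf)
    expect_equal(sum(fw$yhat), 1, tolerance = 1e-12)
    expect_true(all(fw$yhat > 0 & fw$yhat < 1))
  }
})

test_that("the pipeline is equivariant to node relabeling", {
  set.seed(26)
  mconf <- mk_conf()
  u <- 9
  params <- init_model_params(u, mconf, seed = 7)
  desc <- encode_descriptions(
    toolbox(paste0("t", 1:u), paste("desc", 1:u)), "mock", d_e = 4, seed = 2)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    edges <- random_dag(n, 0.5)
    w <- awr("w", sample(u, n, replace = TRUE), edges)
    R <- sample(n, sample(1:2, 1))
    qg <- build_query_graph(w, NA, R)
    y1 <- forward_query(qg, params, desc, mconf)$yhat

    # permute the real nodes of the query graph directly
    m <- length(qg$node_tools)
    perm <- c(sample(m - 1L), m)       # query node stays last
    inv <- order(perm)
    qg2 <- qg
    qg2$node_tools <- qg$node_tools[perm]
    qg2$edges <- cbind(inv[qg$edges[, 1]], inv[qg$edges[, 2]])
    qg2$r_nodes <- inv[qg$r_nodes]
    qg2$last_real_node <- inv[qg$last_real_node]
    y2 <- forward_query(qg2, params, desc, mconf)$yhat
    expect_equal(y1, y2, tolerance = 1e-6)
  }
})

test_that("recommend returns descending probabilities with index tie-break", {
  g <- det_grammar()
  mconf <- mk_conf()
  model <- list(params = init_model_params(30, mconf, seed = 8),
                config = mconf,
                desc = encode_descriptions(g$toolbox, "mock", d_e = 4,
                                           seed = 1),
                toolbox = g$toolbox)
  q <- corpus_queries(generate_corpus(g, 1), "graph")[[1]]
  rec <- recommend(q, model, top_n = 5)
  expect_equal(nrow(rec), 5)
  expect_true(all(diff(rec$probability) <= 0))
  full <- forward_query(q, model$params, model$desc, mconf)$yhat
  expect_equal(rec$probability, sort(full, decreasing = TRUE)[1:5])
  expect_equal(rec$tool_id[1], g$toolbox$tool_id[which.max(full)])
  expect_error(recommend(q, list(params = NULL), 5), "untrained")
})
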