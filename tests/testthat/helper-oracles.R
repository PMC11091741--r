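# Independent scalar-loop oracles for the neural core. These deliberately
# avoid matrix algebra (explicit per-node, per-dimension loops) so they are
# an independent route to the same quantities as the vectorized code.

oracle_propagate <- function(X, edges, params, steps = 1L) {
  n <- nrow(X); d <- ncol(X)
  V <- X
  for (t in seq_len(steps)) {
    Vn <- V
    for (i in seq_len(n)) {
      a <- numeric(2 * d)
      for (k in seq_len(d)) {
        s_in <- 0; s_out <- 0
        if (nrow(edges) > 0) {
          for (e in seq_len(nrow(edges))) {
            if (edges[e, 2] == i) s_in <- s_in + V[edges[e, 1], k]
            if (edges[e, 1] == i) s_out <- s_out + V[edges[e, 2], k]
          }
        }
        a[k] <- s_in
        a[d + k] <- s_out
      }
      a <- a + params$b
      z <- numeric(d); r <- numeric(d); cand <- numeric(d)
      for (k in seq_len(d)) {
        az <- 0; ar <- 0
        for (l in seq_len(2 * d)) {
          az <- az + params$Wz[k, l] * a[l]
          ar <- ar + params$Wr[k, l] * a[l]
        }
        for (l in seq_len(d)) {
          az <- az + params$Uz[k, l] * V[i, l]
          ar <- ar + params$Ur[k, l] * V[i, l]
        }
        z[k] <- 1 / (1 + exp(-az))
        r[k] <- 1 / (1 + exp(-ar))
      }
      for (k in seq_len(d)) {
        ah <- 0
        for (l in seq_len(2 * d)) ah <- ah + params$Wh[k, l] * a[l]
        for (l in seq_len(d)) ah <- ah + params$Uh[k, l] * (r[l] * V[i, l])
        cand[k] <- tanh(ah)
        Vn[i, k] <- (1 - z[k]) * V[i, k] + z[k] * cand[k]
      }
    }
    V <- Vn
  }
  V
}

oracle_attention <- function(S, w_l, params) {
  d <- ncol(S)
  w_g <- numeric(d)
  alpha <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    h <- numeric(d)
    for (k in seq_len(d)) {
      uik <- params$b_att[k]
      for (l in seq_len(d))
        uik <- uik + params$W1[k, l] * w_l[l] + params$W2[k, l] * S[i, l]
      h[k] <- 1 / (1 + exp(-uik))
    }
    alpha[i] <- sum(params$q_vec * h)
    w_g <- w_g + alpha[i] * S[i, ]
  }
  list(alpha = alpha, w_g = w_g)
}

oracle_fuse <- function(w_l, w_g, params) {
  cat_lg <- c(w_l, w_g)
  w_c <- numeric(nrow(params$W3))
  for (k in seq_len(nrow(params$W3)))
    w_c[k] <- sum(params$W3[k, ] * cat_lg)
  w_s <- numeric(nrow(params$W4))
  for (k in seq_len(nrow(params$W4)))
    w_s[k] <- sum(params$W4[k, ] * w_c)
  w_s
}

oracle_score <- function(w_s, table) {
  u <- nrow(table) - 1L
  logits <- numeric(u)
  for (i in seq_len(u)) logits[i] <- sum(table[i, ] * w_s)
  e <- exp(logits - max(logits))
  e / sum(e)
}

oracle_loss_binary <- function(y_hat, target, eps = 1e-7) {
  u <- length(y_hat)
  tot <- 0
  for (i in seq_len(u)) {
    p <- min(max(y_hat[i], eps), 1 - eps)
    yi <- as.numeric(i == target)
    tot <- tot + yi * log(p) + (1 - yi) * log(1 - p)
  }
  -tot / u
}

# brute-force ancestor set: repeated scans until fixpoint
oracle_upstream <- function(n, edges, R) {
  inset <- rep(FALSE, n)
  inset[R] <- TRUE
  repeat {
    changed <- FALSE
    if (nrow(edges) > 0) {
      for (e in seq_len(nrow(edges))) {
        if (inset[edges[e, 2]] && !inset[edges[e, 1]]) {
          inset[edges[e, 1]] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  which(inset)
}

# random small DAG: nodes 1..n, edges only forward (i < j)
random_dag <- function(n, p = 0.4) {
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

random_params <- function(u, mconf, seed) init_model_params(u, mconf, seed)

# tiny Galaxy .ga fixture written in code
write_ga_fixture <- function(path, steps) {
  jsonlite::write_json(
    list(a_galaxy_workflow = "true", name = "fixture",
         steps = steps),
    path, auto_unbox = TRUE, null = "null")
  path
}

make_linear_ga_steps <- function(tool_ids) {
  steps <- list()
  for (i in seq_along(tool_ids)) {
    s <- list(id = i - 1L, type = "tool", tool_id = tool_ids[i],
              input_connections = if (i == 1) structure(list(), names = character(0)) else
                list(input = list(id = i - 2L, output_name = "out")))
    steps[[as.character(i - 1L)]] <- s
  }
  steps
}

# finite-difference gradient of the full query loss wrt one parameter entry
fd_grad <- function(qg, params, desc, mconf, nm, i, eps = 1e-6) {
  f <- function(p) {
    fw <- forward_query(qg, p, desc, mconf)
    compute_loss(fw$yhat, qg$target, mconf$loss)
  }
  pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
  pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
  (f(pp) - f(pm)) / (2 * eps)
}

# small deterministic-grammar fixtures reused across tests
det_grammar <- function(seed = 11) {
  build_grammar(grammar_spec(n_tools = 30, n_categories = 5,
                             n_templates = 5, template_len = c(4, 7),
                             determinism = "deterministic", seed = seed))
}

sort_edges <- function(e) {
  e <- matrix(as.integer(e), ncol = 2)
  colnames(e) <- NULL
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
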