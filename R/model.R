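#' Model configuration
#'
#' Collects the architectural switches and dimensions of the recommender.
#'
#' @param d_t tool-ID embedding dimension (default 64).
#' @param d_e description embedding dimension (default 64 for the mock
#'   backend; 768 for a transformer backend).
#' @param use_nlp include frozen description embeddings as node features
#'   (the NLP component). When off, node features are the tool-ID
#'   embeddings alone and \code{d_c = d_t}.
#' @param use_attention aggregate node states with the attention mechanism;
#'   when off, mean-pooling over real nodes is used instead.
#' @param attention_softmax normalize attention scores with softmax before
#'   pooling. Default \code{FALSE}: raw scores are used as weights, matching
#'   the session-graph attention formulation this model follows.
#' @param prop_steps number of gated propagation rounds (default 1).
#' @param query_token \code{"learned"} (dedicated learnable QUERY embedding
#'   row, default) or \code{"zero"} (query node starts from a zero vector).
#' @param loss \code{"binary"} — binary cross-entropy averaged over the
#'   toolbox (the printed form of the training objective) — or
#'   \code{"categorical"} — standard categorical cross-entropy
#'   \code{-log(yhat[target])}.
#' @return list of class \code{rec_config}; \code{d_c} is derived.
#' @export
model_config <- function(d_t = 64L, d_e = 64L, use_nlp = TRUE,
                         use_attention = TRUE, attention_softmax = FALSE,
                         prop_steps = 1L, query_token = c("learned", "zero"),
                         loss = c("binary", "categorical")) {
  query_token <- match.arg(query_token)
  loss <- match.arg(loss)
  stopifnot(d_t >= 1, d_e >= 1, prop_steps >= 1)
  structure(list(d_t = as.integer(d_t), d_e = as.integer(d_e),
                 use_nlp = use_nlp, use_attention = use_attention,
                 attention_softmax = attention_softmax,
                 prop_steps = as.integer(prop_steps),
                 query_token = query_token,
                 loss = loss,
                 d_c = as.integer(d_t) + if (use_nlp) as.integer(d_e) else 0L),
            class = "rec_config")
}

#' Initialize all learnable parameters
#'
#' Every learnable tensor of the architecture: the tool embedding table
#' (shared between the input layer and the scoring layer — weight tying),
#' the gated-propagation matrices and gate weights, the attention
#' parameters, and the two fusion/compression matrices. All entries are
#' drawn uniformly from \code{[-1/sqrt(d_c), 1/sqrt(d_c)]}.
#'
#' @param u toolbox size.
#' @param config a \code{rec_config}.
#' @param seed integer seed.
#' @return list of class \code{rec_params} with elements \code{Wtool}
#'   ((u+1) x d_t), \code{b} (2 d_c message bias), \code{Wz,Wr,Wh}
#'   (d_c x 2 d_c), \code{Uz,Ur,Uh} (d_c x d_c), \code{q_vec} (d_c),
#'   \code{W1,W2} (d_c x d_c), \code{b_att} (d_c), \code{W3} (d_c x 2 d_c),
#'   \code{W4} (d_t x d_c).
#' @export
init_model_params <- function(u, config, seed = 1L) {
  d_t <- config$d_t; d_c <- config$d_c
  set.seed(seed)
  s <- 1 / sqrt(d_c)
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  p <- list(
    Wtool = matrix(stats::runif((u + 1L) * d_t, -1 / sqrt(d_t), 1 / sqrt(d_t)),
                   u + 1L, d_t),
    b  = stats::runif(2L * d_c, -s, s),
    Wz = ru(d_c, 2L * d_c), Wr = ru(d_c, 2L * d_c), Wh = ru(d_c, 2L * d_c),
    Uz = ru(d_c, d_c), Ur = ru(d_c, d_c), Uh = ru(d_c, d_c),
    q_vec = stats::runif(d_c, -s, s),
    W1 = ru(d_c, d_c), W2 = ru(d_c, d_c),
    b_att = stats::runif(d_c, -s, s),
    W3 = ru(d_c, 2L * d_c),
    W4 = ru(d_t, d_c))
  if (config$query_token == "zero")
    p$Wtool[u + 1L, ] <- 0
  structure(p, class = "rec_params", u = u)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gated graph propagation over node states
#'
#' For each round, every node gathers messages from its graph neighborhood
#' through the 0/1 connectivity blocks — the activation of node i is the
#' concatenation of the summed states of its predecessors (incoming edges)
#' and of its successors (outgoing edges), plus a bias — and then updates
#' its state with a gated recurrent unit: update gate
#' \code{z = sigma(Wz a + Uz v)}, reset gate \code{r = sigma(Wr a + Ur v)},
#' candidate \code{tanh(Wh a + Uh (r * v))}, and
#' \code{v <- (1 - z) * v + z * cand}.
#'
#' @param x \code{n x d_c} initial node states.
#' @param conn connectivity from \code{\link{build_connectivity}}.
#' @param params a \code{rec_params}.
#' @param steps number of propagation rounds (>= 1).
#' @param keep_cache retain per-round intermediates for backpropagation.
#' @return \code{n x d_c} matrix of propagated states; with
#'   \code{keep_cache}, attribute \code{cache} holds the round-by-round
#'   intermediates.
#' @export
propagate <- function(x, conn, params, steps = 1L, keep_cache = FALSE) {
  V <- x
  n <- nrow(V); d_c <- ncol(V)
  a_out <- conn$a_out
  bmat <- matrix(params$b, n, 2L * d_c, byrow = TRUE)
  cache <- if (keep_cache) vector("list", steps) else NULL
  for (t in seq_len(steps)) {
    M <- cbind(crossprod(a_out, V), a_out %*% V)   # [in-messages | out-messages]
    Act <- M + bmat
    Z  <- sigmoid(Act %*% t(params$Wz) + V %*% t(params$Uz))
    Rt <- sigmoid(Act %*% t(params$Wr) + V %*% t(params$Ur))
    RV <- Rt * V
    Cand <- tanh(Act %*% t(params$Wh) + RV %*% t(params$Uh))
    Vnew <- (1 - Z) * V + Z * Cand
    if (!all(is.finite(Vnew))) {
      bad <- which(!is.finite(rowSums(Vnew)))[1]
      stop("non-finite state during propagation at node ", bad)
    }
    if (keep_cache)
      cache[[t]] <- list(V = V, Act = Act, Z = Z, Rt = Rt, RV = RV,
                         Cand = Cand)
    V <- Vnew
  }
  if (keep_cache) attr(V, "cache") <- cache
  V
}

#' Aggregate node states into local and global workflow embeddings
#'
#' The local embedding \code{w_l} is the state of the most recent real tool
#' node (when several steps feed the recommendation point, the mean of their
#' states). The global embedding \code{w_g} pools the real-node states:
#' with attention, each node i receives a scalar score
#' \code{alpha_i = q . sigma(W1 w_l + W2 s_i + b_att)} and
#' \code{w_g = sum_i alpha_i s_i} (raw scores as weights unless softmax
#' normalization is enabled); without attention, \code{w_g} is the plain
#' mean. The query node is masked out of the pooling.
#'
#' @param states \code{n x d_c} propagated node states (query node last).
#' @param r_nodes positions providing the local context.
#' @param params a \code{rec_params}.
#' @param config a \code{rec_config}.
#' @param keep_cache retain intermediates for backpropagation.
#' @return list with \code{w_l}, \code{w_g} (d_c vectors), \code{alpha}
#'   (scores over real nodes, NULL for mean-pooling) and, if requested,
#'   \code{cache}.
#' @export
aggregate_states <- function(states, r_nodes, params, config,
                             keep_cache = FALSE) {
  n <- nrow(states)
  real <- seq_len(n - 1L)                     # query node is position n
  if (length(real) < 1) stop("query graph has no real nodes")
  S <- states[real, , drop = FALSE]
  w_l <- if (length(r_nodes) == 1L) states[r_nodes, ] else
    colMeans(states[r_nodes, , drop = FALSE])
  if (!config$use_attention) {
    return(list(w_l = w_l, w_g = colMeans(S), alpha = NULL,
                cache = if (keep_cache) list(S = S, real = real) else NULL))
  }
  U <- S %*% t(params$W2) +
    matrix(drop(params$W1 %*% w_l) + params$b_att, nrow(S), ncol(S),
           byrow = TRUE)
  H <- sigmoid(U)
  alpha_raw <- drop(H %*% params$q_vec)
  alpha <- if (config$attention_softmax) {
    e <- exp(alpha_raw - max(alpha_raw)); e / sum(e)
  } else alpha_raw
  w_g <- drop(crossprod(S, alpha))
  list(w_l = w_l, w_g = w_g, alpha = alpha,
       cache = if (keep_cache)
         list(S = S, real = real, H = H, alpha_raw = alpha_raw,
              alpha = alpha) else NULL)
}

#' Fuse local and global embeddings and compress to tool space
#'
#' Concatenates \code{[w_l || w_g]}, compresses to \code{d_c} with
#' \code{W3} and projects into the tool-embedding space with \code{W4}.
#' The two matrices are kept distinct (folding them into one performed
#' slightly worse in the lineage this architecture follows, and keeping
#' them separate decouples the workflow dimension from the tool dimension).
#'
#' @param w_l,w_g d_c vectors.
#' @param params a \code{rec_params}.
#' @return list with \code{w_s} (d_t), \code{w_c} (d_c) and \code{cat}
#'   (2 d_c).
#' @export
fuse_and_compress <- function(w_l, w_g, params) {
  cat_lg <- c(w_l, w_g)
  if (length(cat_lg) != ncol(params$W3))
    stop("fusion input dimension mismatch")
  w_c <- drop(params$W3 %*% cat_lg)
  w_s <- drop(params$W4 %*% w_c)
  list(w_s = w_s, w_c = w_c, cat = cat_lg)
}

#' Score every tool against the workflow embedding
#'
#' Each toolbox entry is scored by the inner product of its (tied) embedding
#' row with the compressed workflow embedding; the link function \code{g}
#' (softmax by default) turns scores into a probability vector over the
#' toolbox. The QUERY row is excluded — the blank token is never a
#' candidate.
#'
#' @param w_s d_t workflow embedding.
#' @param table \code{(u+1) x d_t} tool embedding matrix.
#' @param g link function mapping the logit vector to scores
#'   (default softmax).
#' @return list with \code{yhat} (length-u probabilities summing to 1) and
#'   \code{logits}.
#' @export
score_tools <- function(w_s, table, g = softmax_link) {
  u <- nrow(table) - 1L
  logits <- drop(table[seq_len(u), , drop = FALSE] %*% w_s)
  list(yhat = g(logits), logits = logits)
}

#' Softmax link
#' @param z numeric vector of logits.
#' @return probability vector.
#' @export
softmax_link <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Full forward pass for one query graph
#'
#' Embedding lookup, optional dropout, gated propagation, aggregation,
#' fusion/compression and scoring. Used by training (with
#' \code{train = TRUE} and \code{keep_cache = TRUE}) and by
#' \code{\link{recommend}}.
#'
#' @param qg a \code{query_graph}.
#' @param params a \code{rec_params}.
#' @param desc frozen description matrix ((u+1) x d_e) or NULL when the NLP
#'   component is off.
#' @param config a \code{rec_config}.
#' @param train apply dropout (draws from the current RNG stream).
#' @param dropout_embed,dropout_state dropout rates at the two sites:
#'   initial tool-ID embeddings, and node states after propagation.
#' @param keep_cache retain every intermediate needed by
#'   \code{\link{backward_query}}.
#' @return list with \code{yhat}, \code{logits} and (optionally)
#'   \code{cache}.
#' @export
forward_query <- function(qg, params, desc, config, train = FALSE,
                          dropout_embed = 0, dropout_state = 0,
                          keep_cache = FALSE) {
  if (config$use_nlp && is.null(desc))
    stop("config enables the NLP component but no description matrix given")
  conn <- build_connectivity(qg)
  n <- length(qg$node_tools)
  Xt <- embed_tool_ids(qg$node_tools, params$Wtool)
  mask_e <- NULL
  if (train && dropout_embed > 0) {
    mask_e <- matrix(stats::rbinom(n * config$d_t, 1, 1 - dropout_embed),
                     n, config$d_t) / (1 - dropout_embed)
    Xt <- Xt * mask_e
  }
  X <- if (config$use_nlp)
    combine_features(Xt, embed_tool_ids(qg$node_tools, desc)) else Xt
  V <- propagate(X, conn, params, steps = config$prop_steps,
                 keep_cache = keep_cache)
  prop_cache <- attr(V, "cache")
  attr(V, "cache") <- NULL
  mask_s <- NULL
  S_all <- V
  if (train && dropout_state > 0) {
    mask_s <- matrix(stats::rbinom(n * config$d_c, 1, 1 - dropout_state),
                     n, config$d_c) / (1 - dropout_state)
    S_all <- V * mask_s
  }
  agg <- aggregate_states(S_all, qg$r_nodes, params, config,
                          keep_cache = keep_cache)
  fus <- fuse_and_compress(agg$w_l, agg$w_g, params)
  sc <- score_tools(fus$w_s, params$Wtool)
  out <- list(yhat = sc$yhat, logits = sc$logits)
  if (keep_cache)
    out$cache <- list(qg = qg, conn = conn, n = n, mask_e = mask_e,
                      mask_s = mask_s, X = X, V = V, S_all = S_all,
                      prop = prop_cache, agg = agg$cache, w_l = agg$w_l,
                      w_g = agg$w_g, fus = fus, config = config)
  out
}

#' Recommend the next tool for a query
#'
#' Runs the full pipeline and returns the top-n tools ranked by probability
#' (descending), ties broken by ascending toolbox index.
#'
#' @param qg a \code{query_graph} (its \code{target} is ignored).
#' @param model a trained checkpoint from \code{\link{train_model}}, or a
#'   list with \code{params}, \code{config}, \code{desc}, \code{toolbox}.
#' @param top_n number of suggestions (default 5).
#' @return data.frame with \code{rank}, \code{tool_id}, \code{probability}.
#' @export
recommend <- function(qg, model, top_n = 5L) {
  if (is.null(model$params) || is.null(model$config))
    stop("model is untrained or incomplete (no params/config)")
  fw <- forward_query(qg, model$params, model$desc, model$config)
  ord <- order(-fw$yhat, seq_along(fw$yhat))
  top <- utils::head(ord, top_n)
  data.frame(rank = seq_along(top),
             tool_id = model$toolbox$tool_id[top],
             probability = fw$yhat[top])
}
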