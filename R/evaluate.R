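#' Rank of the ground-truth tool in a score vector
#'
#' The 1-based position of the target under descending probability, ties
#' broken by ascending toolbox index (so a tied target at a lower index
#' ranks better than tied competitors at higher indices).
#'
#' @param y_hat probability (or score) vector over the toolbox.
#' @param target toolbox index of the ground truth.
#' @return integer rank in \code{1..u}.
#' @export
rank_of_truth <- function(y_hat, target) {
  p <- y_hat[target]
  1L + sum(y_hat > p) + sum(y_hat == p & seq_along(y_hat) < target)
}

#' Top-k ranking metrics over a set of query records
#'
#' \describe{
#'   \item{HR@1}{fraction of queries whose first recommendation is the
#'     ground truth (rank 1).}
#'   \item{HR@3}{fraction with the ground truth among the first three
#'     (rank <= 3).}
#'   \item{MRR@5}{mean of 1/rank when the rank is at most 5, 0 otherwise.}
#' }
#'
#' @param records data.frame with columns \code{rank} (integer rank of
#'   truth) and optionally \code{input_length}, \code{query_id}.
#' @return list of class \code{eval_result}: \code{records}, \code{hr1},
#'   \code{hr3}, \code{mrr5}, \code{n}.
#' @export
compute_metrics <- function(records) {
  if (is.numeric(records)) records <- data.frame(rank = as.integer(records))
  if (NROW(records) == 0) stop("no records to evaluate")
  r <- records$rank
  structure(list(records = records,
                 hr1 = mean(r == 1L),
                 hr3 = mean(r <= 3L),
                 mrr5 = mean(ifelse(r <= 5L, 1 / r, 0)),
                 n = length(r)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval over %d queries: HR@1=%.4f HR@3=%.4f MRR@5=%.4f>\n",
              x$n, x$hr1, x$hr3, x$mrr5))
  invisible(x)
}

#' Metrics broken down by input query length
#'
#' Input length is the number of real nodes in the query graph (prefix
#' length for the sequence variant). Counts per bucket are reported because
#' sparse buckets make the per-length curves noisy.
#'
#' @param records data.frame with columns \code{rank} and
#'   \code{input_length}.
#' @return data.frame with one row per observed length: \code{input_length},
#'   \code{n}, \code{hr1}, \code{hr3}, \code{mrr5}.
#' @export
metrics_by_length <- function(records) {
  if (is.null(records$input_length))
    stop("records need an input_length column")
  lens <- sort(unique(records$input_length))
  out <- lapply(lens, function(L) {
    m <- compute_metrics(records[records$input_length == L, , drop = FALSE])
    data.frame(input_length = L, n = m$n, hr1 = m$hr1, hr3 = m$hr3,
               mrr5 = m$mrr5)
  })
  do.call(rbind, out)
}

#' Evaluate a trained model over a set of queries
#'
#' Runs the forward pass for every query (no dropout), records the rank of
#' the ground truth, and aggregates the ranking metrics.
#'
#' @param model checkpoint from \code{\link{train_model}} (or a list with
#'   \code{params}, \code{config}, \code{desc}).
#' @param queries list of \code{query_graph} with non-missing targets.
#' @return an \code{eval_result} (see \code{\link{compute_metrics}}).
#' @export
evaluate_model <- function(model, queries) {
  if (length(queries) == 0) stop("no queries to evaluate")
  ranks <- integer(length(queries))
  lens <- integer(length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    if (is.na(q$target)) stop("query ", i, " has no ground-truth target")
    fw <- forward_query(q, model$params, model$desc, model$config)
    ranks[i] <- rank_of_truth(fw$yhat, q$target)
    lens[i] <- q$input_length
  }
  compute_metrics(data.frame(query_id = seq_along(queries), rank = ranks,
                             input_length = lens))
}

#' Evaluate a fixed scoring function over queries
#'
#' Shared harness for non-neural baselines: \code{scorer(qg)} must return a
#' score vector over the toolbox.
#' @param scorer function of a \code{query_graph}.
#' @param queries list of \code{query_graph}.
#' @return an \code{eval_result}.
#' @export
evaluate_scorer <- function(scorer, queries) {
  ranks <- vapply(queries, function(q) rank_of_truth(scorer(q), q$target),
                  integer(1))
  lens <- vapply(queries, function(q) q$input_length, integer(1))
  compute_metrics(data.frame(query_id = seq_along(queries), rank = ranks,
                             input_length = lens))
}

#' Bigram-frequency baseline
#'
#' Classic last-tool transition-frequency recommender: from the training
#' queries, count how often each tool follows each "most recent" tool, and
#' score candidates by those counts (global tool frequency as fallback for
#' unseen contexts). Serves as the floor any learned model must beat.
#'
#' @param train_queries list of \code{query_graph} with targets.
#' @param u toolbox size.
#' @return scorer function usable with \code{\link{evaluate_scorer}}.
#' @export
bigram_baseline <- function(train_queries, u) {
  counts <- matrix(0, u, u)      # counts[last, next]
  global <- numeric(u)
  for (q in train_queries) {
    last_tools <- q$node_tools[q$r_nodes]
    global[q$target] <- global[q$target] + 1
    for (lt in last_tools)
      if (lt != QUERY_TOOL) counts[lt, q$target] <- counts[lt, q$target] + 1
  }
  function(qg) {
    last_tools <- qg$node_tools[qg$r_nodes]
    s <- numeric(u)
    for (lt in last_tools) if (lt != QUERY_TOOL) s <- s + counts[lt, ]
    if (sum(s) == 0) s <- global
    s / max(sum(s), 1)
  }
}
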