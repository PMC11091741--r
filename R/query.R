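#' Build a graph query from a workflow prefix
#'
#' The model answers "which tool comes next after the steps in \code{R}?".
#' A query graph is the upstream closure of the user-selected preceding
#' steps \code{R} (all of their ancestors, plus \code{R} itself), with a
#' blank query node \code{q} appended and directed edges from every step of
#' \code{R} into \code{q}. The tool replacing \code{q} is the prediction
#' target; during training it is the tool actually invoked at
#' \code{target_step}.
#'
#' Real nodes keep the workflow's relative step order; the query node is
#' always the last position and carries the sentinel \code{\link{QUERY_TOOL}}
#' index. \code{r_nodes} records the in-query positions of \code{R}: these
#' provide the "most recent tool" context used for the local workflow
#' embedding (averaged when \code{R} has several steps).
#'
#' @param w an \code{awr}.
#' @param target_step step id holding the ground-truth tool, or \code{NA} at
#'   pure inference time.
#' @param R integer vector of step ids whose outputs feed the recommended
#'   tool; must be non-empty and must not contain \code{target_step}.
#' @return object of class \code{query_graph}: \code{node_tools} (toolbox
#'   index per node, query node last with sentinel 0), \code{edges}
#'   (two-column matrix over node positions), \code{r_nodes},
#'   \code{last_real_node} (position of the largest step id in \code{R}),
#'   \code{input_length} (number of real nodes), \code{target} (toolbox
#'   index or NA), \code{steps} (original step ids of the real nodes).
#' @export
build_query_graph <- function(w, target_step = NA, R) {
  R <- as.integer(R)
  if (length(R) == 0) stop("R must contain at least one preceding step")
  if (!is.na(target_step) && target_step %in% R)
    stop("R must not contain the target step itself")
  n <- n_steps(w)
  if (any(R < 1L | R > n)) stop("R references a non-existent step")

  closure <- upstream_closure(w, R)
  nodes <- sort(closure)                       # stable: step-id order
  pos <- integer(n)
  pos[nodes] <- seq_along(nodes)
  q <- length(nodes) + 1L

  cn <- w$connections
  keep <- cn[, 1] %in% nodes & cn[, 2] %in% nodes
  edges <- cbind(pos[cn[keep, 1]], pos[cn[keep, 2]])
  edges <- rbind(edges, cbind(pos[R], q))
  edges <- unique(matrix(as.integer(edges), ncol = 2))

  target <- if (is.na(target_step)) NA_integer_ else
    w$tool_indices[target_step]
  structure(
    list(node_tools = c(w$tool_indices[nodes], QUERY_TOOL),
         edges = edges,
         r_nodes = pos[sort(R)],
         last_real_node = pos[max(R)],
         input_length = length(nodes),
         target = target,
         steps = nodes),
    class = "query_graph")
}

#' @export
print.query_graph <- function(x, ...) {
  cat(sprintf("<query_graph: %d real nodes + q, %d edges, target=%s>\n",
              x$input_length, nrow(x$edges),
              ifelse(is.na(x$target), "?", x$target)))
  invisible(x)
}

# All ancestors of the steps in R, plus R itself (reverse reachability).
upstream_closure <- function(w, R) {
  cn <- w$connections
  seen <- rep(FALSE, n_steps(w))
  seen[R] <- TRUE
  frontier <- R
  while (length(frontier) > 0) {
    if (nrow(cn) == 0) break
    preds <- unique(cn[cn[, 2] %in% frontier, 1])
    preds <- preds[!seen[preds]]
    seen[preds] <- TRUE
    frontier <- preds
  }
  which(seen)
}

#' Build a sequence (path) query from a tool-sequence prefix
#'
#' The sequence variant consumes linear tool sequences: the prefix is
#' represented as a path graph and \code{R} is automatically the most recent
#' step. Produces the same \code{query_graph} structure as
#' \code{\link{build_query_graph}} applied to a path workflow with
#' \code{R = last step}, so the two model variants share one code path.
#'
#' @param tool_indices integer vector, toolbox indices of the prefix in
#'   order.
#' @param target toolbox index of the ground truth (or NA).
#' @return a \code{query_graph}.
#' @export
build_sequence_query <- function(tool_indices, target = NA_integer_) {
  k <- length(tool_indices)
  if (k < 1) stop("prefix must contain at least one step")
  edges <- if (k > 1) cbind(seq_len(k - 1L), 2:k) else
    matrix(integer(0), ncol = 2)
  edges <- rbind(edges, c(k, k + 1L))
  structure(
    list(node_tools = c(as.integer(tool_indices), QUERY_TOOL),
         edges = matrix(as.integer(edges), ncol = 2),
         r_nodes = k,
         last_real_node = k,
         input_length = k,
         target = as.integer(target),
         steps = seq_len(k)),
    class = "query_graph")
}

#' Extract training / evaluation queries from a workflow
#'
#' Splits a full workflow iteratively into prefix queries, one recommendation
#' point per stage of construction.
#'
#' Graph mode: one query per step that has at least one predecessor — the
#' target is that step, \code{R} is its set of direct predecessors, and the
#' prefix is the upstream closure (so there is exactly one query per
#' ground-truth node). Steps with no predecessors yield no query because
#' \code{R} must be non-empty.
#'
#' Sequence mode: the workflow is linearized by the deterministic
#' topological order of \code{\link{topological_order}} and each proper
#' prefix predicts its successor (\code{L - 1} queries for a length-L
#' sequence); exact duplicate (prefix, target) pairs within one workflow are
#' collapsed, duplicates across workflows are kept.
#'
#' @param w an \code{awr}.
#' @param mode \code{"graph"} or \code{"sequence"}.
#' @return list of \code{query_graph}.
#' @export
extract_prefix_queries <- function(w, mode = c("graph", "sequence")) {
  mode <- match.arg(mode)
  if (mode == "graph") {
    targets <- which(vapply(seq_len(n_steps(w)),
                            function(s) length(step_predecessors(w, s)) > 0,
                            logical(1)))
    return(lapply(targets, function(s)
      build_query_graph(w, s, step_predecessors(w, s))))
  }
  ord <- topological_order(w)
  tools <- w$tool_indices[ord]
  L <- length(tools)
  if (L < 2) return(list())
  qs <- lapply(seq_len(L - 1L), function(k)
    build_sequence_query(tools[seq_len(k)], tools[k + 1L]))
  sig <- vapply(qs, function(q)
    paste(paste(q$node_tools, collapse = ","), q$target, sep = "->"),
    character(1))
  qs[!duplicated(sig)]
}

#' Connectivity matrix of a query graph
#'
#' The propagation layer consumes the adjacency of the query graph as the
#' horizontal concatenation of an outgoing and an incoming block,
#' \code{A = [A_out | A_in]}, with entries exactly 0 or 1 (no degree
#' normalization) and \code{A_in = t(A_out)}.
#'
#' @param qg a \code{query_graph}.
#' @return list with \code{a_out}, \code{a_in} (n x n 0/1 matrices, n
#'   including the query node) and \code{A} (n x 2n combined view).
#' @export
build_connectivity <- function(qg) {
  n <- length(qg$node_tools)
  a_out <- matrix(0, n, n)
  if (nrow(qg$edges) > 0) a_out[qg$edges] <- 1
  a_in <- t(a_out)
  list(a_out = a_out, a_in = a_in, A = cbind(a_out, a_in))
}

#' Serialize / read a query set (JSON Lines)
#'
#' One query per line: node tool indices, edges, r_nodes, last_real_node,
#' target.
#' @param queries list of \code{query_graph}.
#' @param path file path.
#' @export
write_queries_jsonl <- function(queries, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (q in queries) {
    rec <- list(node_tools = q$node_tools,
                edges = if (nrow(q$edges) == 0) list() else
                  lapply(seq_len(nrow(q$edges)), function(k) q$edges[k, ]),
                r_nodes = q$r_nodes,
                last_real_node = q$last_real_node,
                target = q$target)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_queries_jsonl
#' @export
read_queries_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    edges <- rec$edges
    edges <- if (is.null(edges) || length(edges) == 0)
      matrix(integer(0), ncol = 2) else
      matrix(as.integer(as.matrix(edges)), ncol = 2)
    structure(
      list(node_tools = as.integer(rec$node_tools),
           edges = edges,
           r_nodes = as.integer(rec$r_nodes),
           last_real_node = as.integer(rec$last_real_node),
           input_length = sum(as.integer(rec$node_tools) != QUERY_TOOL),
           target = if (is.null(rec$target)) NA_integer_ else
             as.integer(rec$target),
           steps = seq_len(sum(as.integer(rec$node_tools) != QUERY_TOOL))),
      class = "query_graph")
  })
}
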