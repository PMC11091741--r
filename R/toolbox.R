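#' @keywords internal
"_PACKAGE"

#' Sentinel tool index carried by the blank query node
#'
#' Inside a query graph the blank query node does not reference a toolbox
#' entry; it carries this sentinel. At embedding time the sentinel is mapped
#' to the dedicated QUERY row (row \code{u + 1}) of the tool embedding table.
#' @export
QUERY_TOOL <- 0L

#' Construct a toolbox
#'
#' A toolbox is the fixed catalogue of candidate tools. Each tool is a
#' \code{<tool_id, description>} pair; its position in the toolbox is the
#' index used for one-hot encoding and embedding lookup. Once a model has
#' been trained against a toolbox the ordering must not change (the
#' index-to-embedding binding would silently break); treat the object as
#' immutable from that point on.
#'
#' @param tool_ids character vector of unique tool identifiers.
#' @param descriptions character vector of free-text tool summaries
#'   (recycled empty strings if omitted).
#' @return An object of class \code{toolbox}: list with \code{tool_id},
#'   \code{description} (parallel character vectors) and \code{lookup}
#'   (named integer map tool_id -> index).
#' @export
toolbox <- function(tool_ids, descriptions = NULL) {
  tool_ids <- as.character(tool_ids)
  if (anyDuplicated(tool_ids))
    stop("tool_id values must be unique within a toolbox")
  if (is.null(descriptions)) descriptions <- rep("", length(tool_ids))
  if (length(descriptions) != length(tool_ids))
    stop("descriptions must match tool_ids in length")
  lookup <- seq_along(tool_ids)
  names(lookup) <- tool_ids
  structure(
    list(tool_id = tool_ids, description = as.character(descriptions),
         lookup = lookup),
    class = "toolbox")
}

#' Number of tools in a toolbox
#' @param x a \code{toolbox}.
#' @export
length.toolbox <- function(x) length(x$tool_id)

#' @export
print.toolbox <- function(x, ...) {
  cat(sprintf("<toolbox of %d tools>\n", length(x$tool_id)))
  invisible(x)
}

#' Look up toolbox indices for tool ids
#'
#' @param tb a \code{toolbox}.
#' @param tool_ids character vector.
#' @param frozen if \code{TRUE}, unknown ids are an error; otherwise they are
#'   appended to the toolbox (growable mode).
#' @return list with \code{index} (integer vector) and \code{toolbox} (the
#'   possibly grown toolbox).
#' @export
toolbox_index <- function(tb, tool_ids, frozen = TRUE) {
  idx <- unname(tb$lookup[tool_ids])
  if (anyNA(idx)) {
    unknown <- unique(tool_ids[is.na(idx)])
    if (frozen)
      stop("unknown tool id(s) against frozen toolbox: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    tb <- toolbox(c(tb$tool_id, unknown),
                  c(tb$description, rep("", length(unknown))))
    idx <- unname(tb$lookup[tool_ids])
  }
  list(index = idx, toolbox = tb)
}

#' Read / write a toolbox as TSV
#'
#' Plain-text interchange format: tab-separated columns \code{tool_id} and
#' \code{description}, with a header row.
#' @param path file path.
#' @return \code{read_toolbox}: a \code{toolbox}.
#' @export
read_toolbox <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("tool_id", "description") %in% names(df)))
    stop("toolbox TSV needs columns tool_id, description")
  toolbox(df$tool_id, df$description)
}

#' @rdname read_toolbox
#' @param tb a \code{toolbox} to write.
#' @export
write_toolbox <- function(tb, path) {
  utils::write.table(
    data.frame(tool_id = tb$tool_id, description = tb$description),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stable content hash of a toolbox
#'
#' Used to refuse mixing a checkpoint with a different toolbox. Not
#' cryptographic: a position-weighted polynomial hash over the id strings.
#' @param tb a \code{toolbox}.
#' @return character scalar.
#' @export
toolbox_hash <- function(tb) {
  h <- 0
  m <- 2^31 - 1
  for (i in seq_along(tb$tool_id)) {
    for (code in utf8ToInt(tb$tool_id[i])) h <- (h * 131 + code) %% m
    h <- (h * 131 + i) %% m
  }
  sprintf("tb%d-%d", length(tb$tool_id), h)
}

#' Construct an abstract workflow representation (AWR)
#'
#' A workflow is a DAG of tool invocations: ordered steps (each pointing to a
#' toolbox index; the same tool may be invoked several times) plus directed
#' data-flow connections between steps. Step ids are normalized to
#' \code{1..n} in reading order; original ids can be kept in
#' \code{provenance}.
#'
#' @param workflow_id character id.
#' @param tool_indices integer vector, toolbox index per step.
#' @param connections two-column integer matrix (from, to) over step ids, or
#'   an empty matrix / NULL for a connection-free workflow.
#' @param provenance optional list of metadata (e.g. original step ids).
#' @param validate check the DAG invariant (default TRUE).
#' @return object of class \code{awr}.
#' @export
awr <- function(workflow_id, tool_indices, connections = NULL,
                provenance = NULL, validate = TRUE) {
  tool_indices <- as.integer(tool_indices)
  n <- length(tool_indices)
  if (n < 1) stop("a workflow needs at least one step")
  if (is.null(connections) || NROW(connections) == 0) {
    connections <- matrix(integer(0), ncol = 2)
  } else {
    connections <- matrix(as.integer(as.matrix(connections)), ncol = 2)
  }
  colnames(connections) <- c("from", "to")
  w <- structure(
    list(workflow_id = as.character(workflow_id),
         tool_indices = tool_indices,
         connections = connections,
         provenance = provenance),
    class = "awr")
  if (validate) validate_awr(w)
  w
}

#' Validate the DAG invariants of a workflow
#'
#' Checks that every connection endpoint references an existing step and
#' that the connection relation is acyclic.
#' @param w an \code{awr}.
#' @return \code{w}, invisibly; stops on violation.
#' @export
validate_awr <- function(w) {
  n <- length(w$tool_indices)
  cn <- w$connections
  if (nrow(cn) > 0) {
    if (any(cn < 1L) || any(cn > n))
      stop("connection endpoint references a non-existent step")
    if (any(cn[, 1] == cn[, 2]))
      stop("workflow connections contain a self-loop (cycle)")
    g <- igraph::graph_from_edgelist(cn, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("workflow connections contain a cycle")
  }
  invisible(w)
}

#' @export
print.awr <- function(x, ...) {
  cat(sprintf("<awr '%s': %d steps, %d connections>\n",
              x$workflow_id, length(x$tool_indices), nrow(x$connections)))
  invisible(x)
}

#' Number of steps in a workflow
#' @param w an \code{awr}.
#' @export
n_steps <- function(w) length(w$tool_indices)

#' Deterministic topological ordering of workflow steps
#'
#' Kahn's algorithm with ties broken by ascending (normalized) step id, so a
#' DAG always linearizes to the same sequence. Used to turn graph workflows
#' into prefix sequences.
#' @param w an \code{awr} (or anything with \code{tool_indices} and
#'   \code{connections}).
#' @return integer vector of step ids in topological order.
#' @export
topological_order <- function(w) {
  n <- length(w$tool_indices)
  cn <- w$connections
  indeg <- integer(n)
  if (nrow(cn) > 0)
    for (k in seq_len(nrow(cn))) indeg[cn[k, 2]] <- indeg[cn[k, 2]] + 1L
  out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail) > 0) {
    v <- min(avail)                      # smallest step id first
    avail <- setdiff(avail, v)
    out <- c(out, v)
    if (nrow(cn) > 0) {
      succ <- cn[cn[, 1] == v, 2]
      for (s in succ) {
        indeg[s] <- indeg[s] - 1L
        if (indeg[s] == 0L) avail <- c(avail, s)
      }
    }
  }
  if (length(out) != n) stop("cycle detected during topological sort")
  out
}

# direct predecessors / successors of a step
step_predecessors <- function(w, step) {
  cn <- w$connections
  if (nrow(cn) == 0) integer(0) else sort(unique(cn[cn[, 2] == step, 1]))
}
step_successors <- function(w, step) {
  cn <- w$connections
  if (nrow(cn) == 0) integer(0) else sort(unique(cn[cn[, 1] == step, 2]))
}
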