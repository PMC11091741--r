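#' Read a Galaxy workflow export (.ga)
#'
#' Parses the JSON workflow format exported by the Galaxy platform into an
#' abstract workflow representation. Steps that do not invoke a tool
#' (\code{data_input}, \code{data_collection_input}, \code{parameter_input})
#' are dropped and the connections through them contracted (each predecessor
#' of a dropped step is wired to each of its successors). Subworkflow steps
#' are skipped with a warning rather than expanded.
#'
#' @param path path to a \code{.ga} JSON file.
#' @param tb a \code{toolbox}; unknown tools are appended when
#'   \code{frozen = FALSE} (the default) and rejected otherwise. \code{NULL}
#'   starts an empty growable toolbox.
#' @param frozen logical; refuse tools absent from \code{tb}.
#' @param strip_version drop a trailing \code{"/<version>"} path segment from
#'   Galaxy tool ids (ToolShed ids embed the version as the last segment), so
#'   tool identity is version-insensitive. Default \code{FALSE}: the full id
#'   string is the identity key.
#' @return list with \code{awr} (the workflow) and \code{toolbox} (possibly
#'   grown).
#' @examples
#' \dontrun{
#' res <- read_galaxy_workflow("workflow.ga")
#' res$awr
#' }
#' @export
read_galaxy_workflow <- function(path, tb = NULL, frozen = FALSE,
                                 strip_version = FALSE) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed .ga JSON in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(js$steps) || length(js$steps) == 0)
    stop("no steps in .ga file '", path, "'")
  if (is.null(tb)) tb <- toolbox(character(0))

  step_keys <- names(js$steps)
  ord <- order(suppressWarnings(as.numeric(step_keys)))
  step_keys <- step_keys[ord]
  steps <- js$steps[ord]

  get_tool_id <- function(s) {
    tid <- s$tool_id
    type <- if (is.null(s$type)) "tool" else s$type
    if (type %in% c("data_input", "data_collection_input", "parameter_input"))
      return(NA_character_)
    if (type == "subworkflow" || identical(type, "pause")) {
      warning("skipping non-tool step of type '", type, "'")
      return(NA_character_)
    }
    if (is.null(tid) || !nzchar(tid)) return(NA_character_)
    tid <- as.character(tid)
    if (strip_version && grepl("/", tid, fixed = TRUE))
      tid <- sub("/[^/]*$", "", tid)
    tid
  }

  tool_ids <- vapply(steps, get_tool_id, character(1))
  # edges in original key space: input_connections: {input: {id:, ...} | [..]}
  edges <- matrix(integer(0), ncol = 2)
  key_pos <- seq_along(step_keys)
  names(key_pos) <- step_keys
  for (i in seq_along(steps)) {
    ics <- steps[[i]]$input_connections
    if (is.null(ics) || length(ics) == 0) next
    for (ic in ics) {
      conns <- if (!is.null(ic$id) || !is.null(ic[["output_name"]])) list(ic) else ic
      for (cc in conns) {
        if (is.null(cc$id)) next
        from_key <- as.character(cc$id)
        j <- key_pos[from_key]
        if (is.na(j)) next
        edges <- rbind(edges, c(j, i))
      }
    }
  }
  edges <- unique(edges)

  keep <- which(!is.na(tool_ids))
  if (length(keep) == 0) stop("no tool steps in .ga file '", path, "'")
  edges <- contract_dropped(edges, seq_along(tool_ids), keep)

  res <- toolbox_index(tb, tool_ids[keep], frozen = frozen)
  wid <- if (!is.null(js$name) && nzchar(js$name)) js$name else basename(path)
  w <- awr(workflow_id = wid,
           tool_indices = res$index,
           connections = edges,
           provenance = list(path = path, step_keys = step_keys[keep]))
  list(awr = w, toolbox = res$toolbox)
}

# Remove nodes not in `keep` from an edge list over `nodes`, reconnecting
# predecessors of each dropped node to its successors, then relabel the kept
# nodes to 1..length(keep) preserving order.
contract_dropped <- function(edges, nodes, keep) {
  drop <- setdiff(nodes, keep)
  for (d in drop) {
    if (nrow(edges) == 0) break
    preds <- edges[edges[, 2] == d, 1]
    succs <- edges[edges[, 1] == d, 2]
    edges <- edges[edges[, 1] != d & edges[, 2] != d, , drop = FALSE]
    if (length(preds) && length(succs))
      edges <- rbind(edges, as.matrix(expand.grid(from = preds, to = succs)))
    edges <- unique(edges)
  }
  if (nrow(edges) == 0) return(matrix(integer(0), ncol = 2))
  relabel <- integer(max(nodes))
  relabel[keep] <- seq_along(keep)
  out <- cbind(relabel[edges[, 1]], relabel[edges[, 2]])
  out <- out[out[, 1] != out[, 2], , drop = FALSE]
  unique(out)
}

#' Read a directory or list of .ga files into a corpus
#'
#' @param paths character vector of \code{.ga} paths, or a directory.
#' @inheritParams read_galaxy_workflow
#' @return list with \code{corpus} (list of \code{awr}) and \code{toolbox}.
#' @export
read_galaxy_corpus <- function(paths, tb = NULL, frozen = FALSE,
                               strip_version = FALSE) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.ga$", full.names = TRUE)
  if (is.null(tb)) tb <- toolbox(character(0))
  corpus <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    res <- read_galaxy_workflow(paths[i], tb, frozen = frozen,
                                strip_version = strip_version)
    corpus[[i]] <- res$awr
    tb <- res$toolbox
  }
  list(corpus = corpus, toolbox = tb)
}

#' Read / write the native corpus format (JSON Lines)
#'
#' One workflow per line: \code{workflow_id}, \code{tools} (tool_id strings
#' by step) and \code{edges} (list of [from, to] 1-based step positions).
#' Round-tripping a corpus through this format is the identity.
#'
#' @param path JSONL file path.
#' @param tb toolbox used to resolve tool ids; grown unless \code{frozen}.
#' @param frozen refuse unknown tool ids.
#' @return list with \code{corpus} and \code{toolbox}.
#' @export
read_corpus_jsonl <- function(path, tb = NULL, frozen = FALSE) {
  if (is.null(tb)) tb <- toolbox(character(0))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  corpus <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    res <- toolbox_index(tb, as.character(rec$tools), frozen = frozen)
    tb <- res$toolbox
    edges <- rec$edges
    if (is.null(edges) || length(edges) == 0) {
      edges <- matrix(integer(0), ncol = 2)
    } else {
      edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
    }
    corpus[[i]] <- awr(rec$workflow_id, res$index, edges)
  }
  list(corpus = corpus, toolbox = tb)
}

#' @rdname read_corpus_jsonl
#' @param corpus list of \code{awr} objects to write.
#' @export
write_corpus_jsonl <- function(corpus, tb, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (w in corpus) {
    rec <- list(workflow_id = w$workflow_id,
                tools = tb$tool_id[w$tool_indices],
                edges = if (nrow(w$connections) == 0) list() else
                  lapply(seq_len(nrow(w$connections)),
                         function(k) w$connections[k, ]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Filter a workflow corpus
#'
#' Applies the two corpus hygiene rules used before training: discard
#' workflows outside a step-count band (very long workflows are rare and
#' distort training), and de-duplicate workflows with identical tool
#' invocations, keeping the first instance encountered.
#'
#' The de-duplication signature is, by default, the ordered tool-index list
#' by step id plus the sorted connection list, so two differently wired
#' workflows over the same tool sequence both survive. Set
#' \code{signature = "tools"} to collapse on the tool list alone.
#'
#' @param corpus list of \code{awr}.
#' @param min_steps,max_steps inclusive step-count band (defaults 2 and 50).
#' @param dedup apply de-duplication (default TRUE).
#' @param signature \code{"wiring"} (tools + connections) or \code{"tools"}.
#' @return filtered list of \code{awr}. Idempotent.
#' @export
filter_corpus <- function(corpus, min_steps = 2L, max_steps = 50L,
                          dedup = TRUE, signature = c("wiring", "tools")) {
  signature <- match.arg(signature)
  stopifnot(min_steps >= 1, max_steps >= min_steps)
  keep <- vapply(corpus, function(w) {
    n <- n_steps(w)
    n >= min_steps && n <= max_steps
  }, logical(1))
  corpus <- corpus[keep]
  if (!dedup || length(corpus) == 0) return(corpus)
  sigs <- vapply(corpus, function(w) {
    s <- paste(w$tool_indices, collapse = ",")
    if (signature == "wiring" && nrow(w$connections) > 0) {
      cn <- w$connections[order(w$connections[, 1], w$connections[, 2]), ,
                          drop = FALSE]
      s <- paste(s, paste(cn[, 1], cn[, 2], sep = ">", collapse = ","),
                 sep = "|")
    } else if (signature == "wiring") {
      s <- paste0(s, "|")
    }
    s
  }, character(1))
  corpus[!duplicated(sigs)]
}

#' Summary statistics of a corpus
#'
#' Workflow count, distinct tool count, and max / mean / median step counts
#' (the columns usually reported for workflow collections).
#' @param corpus list of \code{awr}.
#' @param tb the toolbox (for the registered tool count).
#' @return one-row data.frame.
#' @export
corpus_stats <- function(corpus, tb = NULL) {
  ns <- vapply(corpus, n_steps, integer(1))
  used <- unique(unlist(lapply(corpus, function(w) w$tool_indices)))
  data.frame(
    workflows = length(corpus),
    tools_used = length(used),
    tools_registered = if (is.null(tb)) NA_integer_ else length(tb$tool_id),
    max_steps = if (length(ns)) max(ns) else 0L,
    avg_steps = if (length(ns)) round(mean(ns), 1) else NA_real_,
    med_steps = if (length(ns)) stats::median(ns) else NA_real_)
}
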