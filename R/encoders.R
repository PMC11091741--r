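#' Initialize the learnable tool-ID embedding table
#'
#' One row per tool plus a dedicated QUERY row (row \code{u + 1}) used for
#' the blank query node. Looking a tool up by index is exactly the product
#' of its one-hot vector with this matrix. Rows are drawn uniformly from
#' \code{[-1/sqrt(d_t), 1/sqrt(d_t)]}, the customary initialization for
#' embedding-plus-GRU recommendation models.
#'
#' @param u toolbox size.
#' @param d_t embedding dimension (default 64).
#' @param seed integer RNG seed.
#' @return \code{(u+1) x d_t} numeric matrix.
#' @export
init_tool_embeddings <- function(u, d_t = 64L, seed = 1L) {
  set.seed(seed)
  s <- 1 / sqrt(d_t)
  matrix(stats::runif((u + 1L) * d_t, -s, s), nrow = u + 1L, ncol = d_t)
}

#' Look up tool-ID embeddings
#'
#' Row \code{i} of the result is the embedding of \code{indices[i]}; the
#' sentinel \code{\link{QUERY_TOOL}} (0) resolves to the QUERY row
#' \code{u + 1}.
#'
#' @param indices integer vector of toolbox indices (0 = query node).
#' @param table \code{(u+1) x d_t} embedding matrix.
#' @return \code{length(indices) x d_t} matrix.
#' @export
embed_tool_ids <- function(indices, table) {
  u1 <- nrow(table)
  rows <- ifelse(indices == QUERY_TOOL, u1, indices)
  if (any(rows < 1L | rows > u1))
    stop("tool index out of range for embedding table")
  table[rows, , drop = FALSE]
}

#' Frozen description embeddings for a toolbox
#'
#' Each tool's free-text description is mapped to a fixed vector by a
#' sentence-encoder backend; the matrix is frozen during training (no
#' gradient flows into it) and the QUERY row is all zeros.
#'
#' Backends:
#' \describe{
#'   \item{\code{"mock"}}{Deterministic, dependency-free encoder: the
#'     description is lowercased, stripped of punctuation and tokenized on
#'     whitespace; every token is hashed to a seeded Gaussian vector and the
#'     token vectors are summed and L2-normalized. Identical descriptions
#'     therefore collide to identical vectors, and descriptions sharing
#'     vocabulary have high cosine similarity — the property the model
#'     exploits. Empty descriptions map to the zero vector.}
#'   \item{\code{"transformer"}}{Placeholder for a frozen biomedical
#'     sentence-transformer (768-dimensional). Not bundled: calling it
#'     raises an error instructing to use \code{"mock"} or to supply a
#'     pre-computed matrix via \code{precomputed}.}
#' }
#'
#' @param tb a \code{toolbox}.
#' @param backend \code{"mock"} or \code{"transformer"}.
#' @param d_e embedding dimension (default 64 for the mock; a transformer
#'   backend would fix it at 768).
#' @param seed seed for the mock token hashing.
#' @param precomputed optional \code{(u+1) x d_e} matrix to use verbatim
#'   (e.g. loaded from a cache produced elsewhere).
#' @param cache_dir optional directory; the matrix is stored as TSV plus a
#'   JSON manifest keyed by backend, dimension and toolbox hash, and reused
#'   when the key matches.
#' @return \code{(u+1) x d_e} matrix of class \code{description_matrix}
#'   (attribute \code{backend}).
#' @export
encode_descriptions <- function(tb, backend = c("mock", "transformer"),
                                d_e = 64L, seed = 1L, precomputed = NULL,
                                cache_dir = NULL) {
  backend <- match.arg(backend)
  u <- length(tb$tool_id)
  if (!is.null(precomputed)) {
    stopifnot(nrow(precomputed) == u + 1L)
    return(structure(precomputed, backend = "precomputed"))
  }
  key <- sprintf("%s-d%d-s%d-%s", backend, d_e, seed, toolbox_hash(tb))
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(key, ".tsv"))
    if (file.exists(f)) {
      m <- as.matrix(utils::read.table(f, sep = "\t"))
      dimnames(m) <- NULL
      return(structure(m, backend = backend))
    }
  }
  if (backend == "transformer")
    stop("the transformer description backend is not bundled (it requires ",
         "a local sentence-transformer model); use backend = \"mock\" or ",
         "pass a pre-computed matrix via `precomputed`")
  m <- matrix(0, u + 1L, d_e)
  for (i in seq_len(u))
    m[i, ] <- mock_sentence_vector(tb$description[i], d_e, seed)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(m, file.path(cache_dir, paste0(key, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(backend = backend, d_e = d_e, seed = seed,
                              toolbox_hash = toolbox_hash(tb)),
                         file.path(cache_dir, paste0(key, ".json")),
                         auto_unbox = TRUE)
  }
  structure(m, backend = backend)
}

# deterministic bag-of-tokens sentence vector
mock_sentence_vector <- function(text, d_e, seed) {
  toks <- mock_tokenize(text)
  if (length(toks) == 0) return(numeric(d_e))
  v <- numeric(d_e)
  for (tk in toks) v <- v + mock_token_vector(tk, d_e, seed)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

mock_tokenize <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9 ]", " ", text)
  toks <- strsplit(trimws(text), "[ ]+")[[1]]
  toks[nzchar(toks)]
}

# token -> reproducible Gaussian vector via a polynomial string hash that
# seeds R's RNG (restored afterwards)
mock_token_vector <- function(token, d_e, seed) {
  h <- seed %% 2147483647
  for (code in utf8ToInt(token)) h <- (h * 131 + code) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(h))
  stats::rnorm(d_e)
}

#' Combine tool-ID and description features
#'
#' Horizontal concatenation \code{x = [x_t || x_e]}; the combined node
#' feature dimension is \code{d_c = d_t + d_e}. With the NLP component
#' disabled the description block is omitted and \code{d_c = d_t}.
#'
#' @param x_t \code{n x d_t} tool-ID embeddings.
#' @param x_e \code{n x d_e} description embeddings, or NULL to disable.
#' @return \code{n x d_c} matrix.
#' @export
combine_features <- function(x_t, x_e = NULL) {
  if (is.null(x_e)) return(x_t)
  if (nrow(x_t) != nrow(x_e)) stop("x_t and x_e row counts differ")
  cbind(x_t, x_e)
}
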