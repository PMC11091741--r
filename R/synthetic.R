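#' Specification of a synthetic workflow grammar
#'
#' Seeded generator of toolboxes and workflow corpora with controllable
#' predictability, used to train and test every other module without
#' external data. Tools are partitioned into categories; each category owns
#' a small keyword vocabulary, and a tool's description is its category
#' keywords plus one tool-specific token — so tools of the same category
#' have high mock-embedding similarity, giving the NLP component genuine
#' signal. Workflows are sampled by walking pipeline templates whose slots
#' each draw a tool from a category.
#'
#' Modes:
#' \describe{
#'   \item{deterministic}{every template slot is bound to one fixed tool, so
#'     the successor of any prefix is unique and known by construction
#'     (function-recovery testbed).}
#'   \item{stochastic}{slots draw uniformly from their category; with
#'     probability \code{noise_prob} a slot's tool is replaced by a uniform
#'     draw from the whole toolbox.}
#' }
#' With \code{two_back = TRUE}, templates are chains of fork motifs: the
#' spine forks into a \emph{signal} step and a dead-end side branch (like a
#' QC step whose report feeds nothing downstream), and only the signal step
#' feeds the following step, whose tool is a deterministic map of the
#' signal tool. The side the signal lands on is randomized per workflow, so
#' in linear step order the informative tool sits one or two positions back
#' at random — graph context (the upstream closure, which excludes the dead
#' end) is strictly more informative than last-tool context.
#'
#' @param n_tools toolbox size (default 30).
#' @param n_categories number of tool categories (default 5).
#' @param n_templates number of pipeline templates (default 5).
#' @param template_len length-2 integer range of linear template lengths.
#' @param branching_prob probability that an internal slot of a sampled
#'   workflow forks into two parallel same-category nodes.
#' @param noise_prob probability of substituting a slot's tool with a
#'   uniformly random tool (stochastic mode).
#' @param skew within-category tool-draw skew: draw probability is
#'   proportional to \code{rank^(-skew)} with a fixed per-category ranking.
#'   0 (default) is uniform; larger values concentrate usage on a few
#'   common tools and leave a tail of rare tools whose ID embeddings see
#'   little training signal — the regime where frozen description
#'   embeddings earn their keep.
#' @param generic_prob probability of inserting an uninformative
#'   "pass-through" step (drawn from the last category, reserved as the
#'   generic pool) after an internal slot of a linear template. The next
#'   real slot still follows the template, so context must look past the
#'   generic step — the situation the attention mechanism exists for.
#' @param determinism \code{"deterministic"} or \code{"stochastic"}.
#' @param two_back build diamond-motif templates with two-back dependencies.
#' @param n_blocks number of diamond motifs per template when
#'   \code{two_back}.
#' @param seed grammar seed; the grammar (categories, templates, slot
#'   bindings, maps) is a pure function of the spec.
#' @return list of class \code{grammar_spec}.
#' @export
grammar_spec <- function(n_tools = 30L, n_categories = 5L, n_templates = 5L,
                         template_len = c(4L, 8L), branching_prob = 0,
                         noise_prob = 0, skew = 0, generic_prob = 0,
                         determinism = c("deterministic", "stochastic"),
                         two_back = FALSE, n_blocks = 2L, seed = 1L) {
  determinism <- match.arg(determinism)
  stopifnot(n_tools >= n_categories, n_categories >= 1,
            branching_prob >= 0, branching_prob <= 1,
            noise_prob >= 0, noise_prob <= 1, skew >= 0,
            generic_prob >= 0, generic_prob <= 1)
  structure(list(n_tools = as.integer(n_tools),
                 n_categories = as.integer(n_categories),
                 n_templates = as.integer(n_templates),
                 template_len = as.integer(template_len),
                 branching_prob = branching_prob, noise_prob = noise_prob,
                 skew = skew, generic_prob = generic_prob,
                 determinism = determinism, two_back = two_back,
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "grammar_spec")
}

#' Materialize a grammar from its spec
#'
#' Builds the toolbox (with category-keyword descriptions), the category
#' partition and the templates. Deterministic given the spec.
#'
#' @param spec a \code{grammar_spec}.
#' @return list of class \code{grammar}: \code{spec}, \code{toolbox},
#'   \code{categories} (integer per tool), \code{cat_tools} (list of tool
#'   indices per category), \code{templates}.
#' @export
build_grammar <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_tools
  k <- spec$n_categories
  categories <- sort(rep_len(seq_len(k), n))
  cat_tools <- split(seq_len(n), categories)
  tool_ids <- sprintf("tool%03d_c%d", seq_len(n), categories)
  descriptions <- vapply(seq_len(n), function(i) {
    c_i <- categories[i]
    paste(c(sprintf("cat%dkw%d", c_i, 1:3), sprintf("unique%03d", i)),
          collapse = " ")
  }, character(1))
  tb <- toolbox(tool_ids, descriptions)

  templates <- if (spec$two_back)
    build_two_back_templates(spec, cat_tools) else
    build_linear_templates(spec, cat_tools, categories)

  structure(list(spec = spec, toolbox = tb, categories = categories,
                 cat_tools = cat_tools, templates = templates),
            class = "grammar")
}

# Linear templates: slot i = one category; deterministic mode also binds one
# fixed tool per slot, with distinct first tools across templates so every
# prefix identifies its template.
build_linear_templates <- function(spec, cat_tools, categories) {
  # deterministic templates get distinct fixed heads so every prefix
  # identifies its template; with generic insertions enabled the last
  # category is reserved as the generic pool
  usable <- if (spec$generic_prob > 0)
    seq_len(max(spec$n_categories - 1L, 1L)) else seq_len(spec$n_categories)
  first_tools <- sample(spec$n_tools,
                        min(spec$n_templates, spec$n_tools))
  lapply(seq_len(spec$n_templates), function(j) {
    L <- sample(seq(spec$template_len[1], spec$template_len[2]), 1)
    cats <- sample(usable, L, replace = TRUE)
    slots <- vector("list", L)
    if (spec$determinism == "deterministic") {
      f1 <- first_tools[((j - 1L) %% length(first_tools)) + 1L]
      slots[[1]] <- list(type = "fixed", tool = f1, cat = categories[f1])
      for (s in seq_len(L)[-1])
        slots[[s]] <- list(type = "fixed",
                           tool = sample(cat_tools[[cats[s]]], 1),
                           cat = cats[s])
    } else {
      for (s in seq_len(L)) slots[[s]] <- list(type = "cat", cat = cats[s])
    }
    edges <- if (L > 1) cbind(seq_len(L - 1L), 2:L) else
      matrix(integer(0), ncol = 2)
    list(slots = slots, edges = edges, kind = "linear")
  })
}

# skewed within-category draw: probability proportional to rank^(-skew)
# with the category's fixed index order as the ranking
draw_cat_tool <- function(grammar, cat) {
  pool <- grammar$cat_tools[[cat]]
  s <- grammar$spec$skew
  if (s <= 0) return(pool[sample.int(length(pool), 1)])
  wts <- seq_along(pool)^(-s)
  pool[sample.int(length(pool), 1, prob = wts)]
}

# Branching templates with two-back dependencies:
#   start -> [spine -> {signal, side-branch} ; signal -> next]+
# Each block forks the spine into a signal step and a dead-end side branch
# (think of a QC or report step whose output feeds nothing downstream); only
# the signal step feeds the following "next" step, whose tool is
# map[signal tool]. Which of the two fork positions carries the signal is
# decided per sampled workflow, so in linear step order the signal sits one
# or two positions back at random while the graph's upstream closure always
# isolates it exactly.
build_two_back_templates <- function(spec, cat_tools) {
  k <- spec$n_categories
  distractor_cat <- k
  signal_cats <- seq_len(max(k - 1L, 1L))
  lapply(seq_len(spec$n_templates), function(j) {
    start_tool <- sample(spec$n_tools, 1)
    slots <- list(list(type = "fixed", tool = start_tool))
    blocks <- list()
    for (b in seq_len(spec$n_blocks)) {
      sc <- sample(signal_cats, 1)
      mc <- sample(signal_cats, 1)
      sig_tools <- cat_tools[[sc]]
      merge_tools <- cat_tools[[mc]]
      map <- sample(merge_tools, length(sig_tools),
                    replace = length(merge_tools) < length(sig_tools))
      names(map) <- as.character(sig_tools)
      x <- length(slots) + 1L
      y <- x + 1L
      z <- x + 2L
      slots[[x]] <- list(type = "branch", cat = sc)
      slots[[y]] <- list(type = "branch", cat = distractor_cat)
      slots[[z]] <- list(type = "map", src = c(x, y), map = map)
      blocks[[b]] <- list(prev = if (b == 1) 1L else blocks[[b - 1L]]$z,
                          x = x, y = y, z = z, sig_cat = sc,
                          dis_cat = distractor_cat, map = map)
    }
    list(slots = slots, blocks = blocks, kind = "two_back")
  })
}

#' Generate the toolbox of a grammar
#'
#' Convenience accessor: builds the grammar and returns its toolbox.
#' @param spec a \code{grammar_spec} or a built \code{grammar}.
#' @return a \code{toolbox}.
#' @export
generate_toolbox <- function(spec) {
  g <- if (inherits(spec, "grammar")) spec else build_grammar(spec)
  g$toolbox
}

#' Sample a workflow corpus from a grammar
#'
#' Each workflow picks a template uniformly and walks its slots in
#' topological order: fixed slots yield their bound tool, category slots
#' draw uniformly from their category, map slots apply the template's
#' deterministic successor map to the tool chosen at their source slot.
#' With probability \code{noise_prob} a non-fixed slot's tool is replaced by
#' a uniform draw from the toolbox; with probability \code{branching_prob}
#' an internal slot of a linear template forks into two parallel
#' same-category nodes.
#'
#' @param grammar a \code{grammar} (or a \code{grammar_spec}, built on the
#'   fly).
#' @param n_workflows number of workflows to sample.
#' @param seed sampling seed (defaults to \code{spec$seed + 1}).
#' @return list of \code{awr}.
#' @export
generate_corpus <- function(grammar, n_workflows, seed = NULL) {
  if (inherits(grammar, "grammar_spec")) grammar <- build_grammar(grammar)
  spec <- grammar$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  n_tools <- spec$n_tools
  corpus <- vector("list", n_workflows)
  for (w in seq_len(n_workflows)) {
    tmpl <- grammar$templates[[sample(length(grammar$templates), 1)]]
    L <- length(tmpl$slots)
    tools <- integer(L)
    maybe_noise <- function(tool) {
      if (spec$noise_prob > 0 && stats::runif(1) < spec$noise_prob)
        sample(n_tools, 1) else tool
    }
    if (tmpl$kind == "two_back") {
      tools[1] <- tmpl$slots[[1]]$tool
      edges <- matrix(integer(0), ncol = 2)
      for (bl in tmpl$blocks) {
        sig <- sample(grammar$cat_tools[[bl$sig_cat]], 1)
        dis <- sample(grammar$cat_tools[[bl$dis_cat]], 1)
        sig_pos <- if (stats::runif(1) < 0.5) bl$x else bl$y
        dis_pos <- if (sig_pos == bl$x) bl$y else bl$x
        tools[sig_pos] <- maybe_noise(sig)
        tools[dis_pos] <- maybe_noise(dis)
        tools[bl$z] <- maybe_noise(unname(bl$map[as.character(sig)]))
        # fork off the spine; only the signal side feeds the next step
        edges <- rbind(edges, c(bl$prev, bl$x), c(bl$prev, bl$y),
                       c(sig_pos, bl$z))
      }
      corpus[[w]] <- awr(sprintf("wf%05d", w), tools, edges)
      next
    } else {
      for (s in seq_len(L)) {     # slots are listed in topological order
        sl <- tmpl$slots[[s]]
        tools[s] <- switch(sl$type,
          fixed = sl$tool,
          cat = draw_cat_tool(grammar, sl$cat))
        if (sl$type != "fixed") tools[s] <- maybe_noise(tools[s])
      }
    }
    if (spec$generic_prob > 0) {
      # interleave uninformative pass-through steps from the generic pool;
      # the next real slot still follows the template
      gen_cat <- spec$n_categories
      seq_tools <- integer(0)
      for (s in seq_len(L)) {
        seq_tools <- c(seq_tools, tools[s])
        if (s < L && stats::runif(1) < spec$generic_prob)
          seq_tools <- c(seq_tools, maybe_noise(draw_cat_tool(grammar,
                                                             gen_cat)))
      }
      m <- length(seq_tools)
      edges <- if (m > 1) cbind(seq_len(m - 1L), 2:m) else
        matrix(integer(0), ncol = 2)
      corpus[[w]] <- awr(sprintf("wf%05d", w), seq_tools, edges)
      next
    }
    edges <- tmpl$edges
    if (tmpl$kind == "linear" && spec$branching_prob > 0 && L >= 3) {
      for (s in 2:(L - 1L)) {
        if (stats::runif(1) < spec$branching_prob) {
          newpos <- length(tools) + 1L
          sl <- tmpl$slots[[s]]
          cat_s <- if (!is.null(sl$cat)) sl$cat else
            grammar$categories[tools[s]]
          tools <- c(tools, sample(grammar$cat_tools[[cat_s]], 1))
          edges <- rbind(edges, c(s - 1L, newpos), c(newpos, s + 1L))
        }
      }
    }
    corpus[[w]] <- awr(sprintf("wf%05d", w), tools, edges)
  }
  corpus
}

#' Ground-truth successor table of a deterministic grammar
#'
#' For deterministic linear grammars every prefix of a template has exactly
#' one correct successor; the table maps the comma-joined tool-index prefix
#' to that successor. Used as the oracle when checking that a trained model
#' recovers the grammar.
#'
#' @param grammar a deterministic \code{grammar}.
#' @return named integer vector: names are prefix keys
#'   (\code{"t1,t2,..."}), values the successor tool index.
#' @export
successor_table <- function(grammar) {
  if (inherits(grammar, "grammar_spec")) grammar <- build_grammar(grammar)
  if (grammar$spec$determinism != "deterministic" || grammar$spec$two_back)
    stop("successor tables are defined for deterministic linear grammars")
  out <- integer(0)
  for (tmpl in grammar$templates) {
    tools <- vapply(tmpl$slots, function(s) s$tool, integer(1))
    for (k in seq_len(length(tools) - 1L)) {
      key <- paste(tools[seq_len(k)], collapse = ",")
      out[key] <- tools[k + 1L]
    }
  }
  out
}

#' Closed-form Bayes-optimal HR@1 of a grammar
#'
#' The best achievable HR@1 of any predictor, from the grammar's mixing
#' probabilities: a fixed or map slot is predictable exactly (up to noise
#' substitution); a category slot only up to its within-category draw, whose
#' best single guess is the heaviest tool under the skew (\code{1/m} when
#' uniform). With generic insertions, generic steps enter with their
#' expected frequency. Averaged over all non-root slots of all templates
#' with equal template weights (queries are one per non-root slot).
#'
#' @param grammar a \code{grammar}.
#' @return scalar in (0, 1].
#' @export
bayes_hr1 <- function(grammar) {
  if (inherits(grammar, "grammar_spec")) grammar <- build_grammar(grammar)
  spec <- grammar$spec
  u <- spec$n_tools
  top_p <- function(cat) {
    m <- length(grammar$cat_tools[[cat]])
    if (spec$skew <= 0) 1 / m else {
      w <- seq_len(m)^(-spec$skew)
      max(w) / sum(w)
    }
  }
  noisy <- function(base) (1 - spec$noise_prob) * base + spec$noise_prob / u
  p_slot <- function(sl) {
    if (sl$type == "fixed") return(1)
    noisy(switch(sl$type,
                 map = 1,
                 branch = top_p(sl$cat),
                 cat = top_p(sl$cat)))
  }
  vals <- unlist(lapply(grammar$templates, function(tmpl) {
    v <- vapply(tmpl$slots[-1], p_slot, numeric(1))
    if (spec$generic_prob > 0) {
      # expected generic insertions per workflow: one possible slot after
      # each non-final template position
      n_gen <- spec$generic_prob * (length(tmpl$slots) - 1L)
      v <- c(v, rep(noisy(top_p(spec$n_categories)), round(n_gen)))
    }
    v
  }))
  mean(vals)
}
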