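#' Training configuration
#'
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay applied to the learning rate.
#' @param lr_decay_every apply the decay every this many epochs.
#' @param l2 L2 penalty coefficient added to the gradients.
#' @param batch_size mini-batch size (gradients averaged within a batch).
#' @param epochs number of passes over the training queries.
#' @param dropout_embed dropout rate on initial tool-ID embeddings.
#' @param dropout_state dropout rate on node states after propagation.
#' @param variant \code{"graph"} (prefix-graph queries) or
#'   \code{"sequence"} (linearized prefix-sequence queries).
#' @param seed run seed; every source of randomness (parameter init, split
#'   shuffling, batch order, dropout) flows from it.
#' @param patience stop early after this many evaluations without
#'   improvement in validation MRR@5 (default Inf: run all epochs).
#' @param eval_every evaluate on the validation split every this many
#'   epochs.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay_factor = 0.8,
                         lr_decay_every = 5L, l2 = 1e-5, batch_size = 32L,
                         epochs = 30L, dropout_embed = 0.1,
                         dropout_state = 0.1,
                         variant = c("graph", "sequence"), seed = 1L,
                         patience = Inf, eval_every = 1L) {
  variant <- match.arg(variant)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            lr_decay_factor > 0, lr_decay_factor <= 1,
            dropout_embed >= 0, dropout_embed < 1,
            dropout_state >= 0, dropout_state < 1,
            epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 l2 = l2, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 dropout_embed = dropout_embed,
                 dropout_state = dropout_state,
                 variant = variant, seed = as.integer(seed),
                 patience = patience, eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Split a corpus into train / validation / test sets
#'
#' The split is over whole workflows — every prefix query extracted from a
#' workflow lives in exactly one set — with a seeded shuffle, then a
#' partition at the given fractions (defaults 0.8 / 0.1 / 0.1).
#'
#' @param corpus list of \code{awr}.
#' @param fractions length-3 numeric summing to 1.
#' @param seed shuffle seed.
#' @return list of class \code{split_plan} with integer index vectors
#'   \code{train}, \code{val}, \code{test}, plus \code{fractions},
#'   \code{seed}.
#' @export
make_splits <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(corpus)
  if (n < 10) warning("corpus has fewer than 10 workflows; splits will be tiny")
  set.seed(seed)
  ord <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_val <- min(n_val, n - n_tr)
  structure(list(train = sort(ord[seq_len(n_tr)]),
                 val = sort(ord[n_tr + seq_len(n_val)]),
                 test = sort(ord[setdiff(seq_len(n), seq_len(n_tr + n_val))]),
                 fractions = fractions, seed = as.integer(seed)),
            class = "split_plan")
}

#' Extract all prefix queries from a set of workflows
#'
#' @param corpus list of \code{awr}.
#' @param variant \code{"graph"} or \code{"sequence"}.
#' @return flat list of \code{query_graph}.
#' @export
corpus_queries <- function(corpus, variant = c("graph", "sequence")) {
  variant <- match.arg(variant)
  mode <- if (variant == "graph") "graph" else "sequence"
  unlist(lapply(corpus, extract_prefix_queries, mode = mode),
         recursive = FALSE)
}

#' Train a recommendation model
#'
#' Mini-batch Adam with L2 penalty and stepped learning-rate decay; dropout
#' at exactly two sites (initial tool-ID embeddings, node states after the
#' propagation layer). The validation split is scored every
#' \code{eval_every} epochs and the parameters of the best validation
#' MRR@5 epoch are returned.
#'
#' @param corpus filtered list of \code{awr}.
#' @param tb the \code{toolbox} the corpus is indexed against.
#' @param tconf a \code{train_config}.
#' @param mconf a \code{rec_config} from \code{\link{model_config}}.
#' @param desc frozen description matrix; built with the mock backend when
#'   NULL and the NLP component is on.
#' @param splits optional \code{split_plan}; derived from the run seed when
#'   NULL.
#' @param verbose print per-epoch progress.
#' @return checkpoint of class \code{rec_checkpoint}: \code{params} (best
#'   epoch), \code{config}, \code{train_config}, \code{desc},
#'   \code{toolbox}, \code{toolbox_hash}, \code{splits}, \code{log}
#'   (per-epoch data.frame), \code{best_epoch}, \code{seed}.
#' @export
train_model <- function(corpus, tb, tconf = train_config(),
                        mconf = model_config(), desc = NULL, splits = NULL,
                        verbose = FALSE) {
  u <- length(tb$tool_id)
  if (u < 2) stop("toolbox too small to rank")
  if (is.null(splits)) splits <- make_splits(corpus, seed = tconf$seed)
  if (mconf$use_nlp && is.null(desc))
    desc <- encode_descriptions(tb, "mock", d_e = mconf$d_e, seed = tconf$seed)

  train_q <- corpus_queries(corpus[splits$train], tconf$variant)
  val_q <- corpus_queries(corpus[splits$val], tconf$variant)
  if (length(train_q) == 0) stop("no training queries extracted")

  params <- init_model_params(u, mconf, seed = tconf$seed)
  state <- NULL
  best <- list(mrr5 = -Inf, params = params, epoch = 0L)
  bad_evals <- 0L
  log <- vector("list", tconf$epochs)

  for (epoch in seq_len(tconf$epochs)) {
    lr <- tconf$learning_rate *
      tconf$lr_decay_factor^((epoch - 1L) %/% tconf$lr_decay_every)
    ord <- sample.int(length(train_q))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = tconf$batch_size)) {
      idx <- ord[start:min(start + tconf$batch_size - 1L, length(ord))]
      grads <- NULL
      bl <- 0
      for (qi in idx) {
        q <- train_q[[qi]]
        fw <- forward_query(q, params, desc, mconf, train = TRUE,
                            dropout_embed = tconf$dropout_embed,
                            dropout_state = tconf$dropout_state,
                            keep_cache = TRUE)
        bw <- backward_query(fw, q$target, params)
        bl <- bl + bw$loss
        grads <- if (is.null(grads)) bw$grads else add_grads(grads, bw$grads)
      }
      scale <- 1 / length(idx)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * scale
      up <- adam_step(params, grads, state, lr = lr, l2 = tconf$l2)
      params <- up$params
      state <- up$state
      ep_loss <- ep_loss + bl / length(idx)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    if (!is.finite(ep_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)

    val <- NULL
    if (epoch %% tconf$eval_every == 0L && length(val_q) > 0) {
      val <- evaluate_model(list(params = params, desc = desc,
                                 config = mconf), val_q)
      if (val$mrr5 > best$mrr5) {
        best <- list(mrr5 = val$mrr5, params = params, epoch = epoch)
        bad_evals <- 0L
      } else {
        bad_evals <- bad_evals + 1L
      }
    }
    log[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss,
      val_hr1 = if (is.null(val)) NA_real_ else val$hr1,
      val_hr3 = if (is.null(val)) NA_real_ else val$hr3,
      val_mrr5 = if (is.null(val)) NA_real_ else val$mrr5)
    if (verbose)
      message(sprintf("epoch %3d loss %.4f val_mrr5 %s", epoch, ep_loss,
                      ifelse(is.null(val), "-", sprintf("%.4f", val$mrr5))))
    if (bad_evals > tconf$patience) break
  }
  log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  if (best$epoch == 0L) best <- list(mrr5 = NA_real_, params = params,
                                     epoch = nrow(log))
  structure(list(params = best$params, config = mconf, train_config = tconf,
                 desc = desc, toolbox = tb, toolbox_hash = toolbox_hash(tb),
                 splits = splits, log = log, best_epoch = best$epoch,
                 seed = tconf$seed),
            class = "rec_checkpoint")
}

#' @export
print.rec_checkpoint <- function(x, ...) {
  cat(sprintf(
    "<checkpoint: u=%d d_c=%d variant=%s best_epoch=%d (%d epochs logged)>\n",
    length(x$toolbox$tool_id), x$config$d_c, x$train_config$variant,
    x$best_epoch, nrow(x$log)))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints are single-file archives of all parameter arrays plus the
#' toolbox hash, configuration snapshot and seed. Size scales with toolbox
#' size (the embedding table dominates), not with corpus size.
#' @param ckpt a \code{rec_checkpoint}.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Random-search hyperparameter tuning
#'
#' Samples \code{n_trials} configurations from the search space, trains each
#' and keeps the one with the best validation MRR@5. The sampling backend is
#' deliberately simple (seeded random search); a model-based optimizer can
#' be slotted in by replacing the sampler.
#'
#' @param corpus,tb,mconf as in \code{\link{train_model}}.
#' @param base a \code{train_config} supplying epochs, variant and seed.
#' @param space list of sampling ranges: \code{lr} (log-uniform bounds),
#'   \code{decay_factor}, \code{decay_every}, \code{l2} (log-uniform),
#'   \code{batch} (choices), \code{dropout} (bounds).
#' @param n_trials number of sampled configurations (default 10).
#' @return list with \code{best} (train_config), \code{best_mrr5},
#'   \code{trials} (data.frame of sampled values and objectives).
#' @export
tune_hyperparameters <- function(corpus, tb, base = train_config(),
                                 mconf = model_config(),
                                 space = list(lr = c(1e-4, 1e-2),
                                              decay_factor = c(0.3, 0.9),
                                              decay_every = c(3L, 10L),
                                              l2 = c(1e-6, 1e-3),
                                              batch = c(32L, 64L, 128L),
                                              dropout = c(0, 0.5)),
                                 n_trials = 10L) {
  stopifnot(n_trials >= 1)
  set.seed(base$seed)
  draws <- data.frame(
    lr = exp(stats::runif(n_trials, log(space$lr[1]), log(space$lr[2]))),
    decay_factor = stats::runif(n_trials, space$decay_factor[1],
                                space$decay_factor[2]),
    decay_every = sample(seq(space$decay_every[1], space$decay_every[2]),
                         n_trials, replace = TRUE),
    l2 = exp(stats::runif(n_trials, log(space$l2[1]), log(space$l2[2]))),
    batch = sample(space$batch, n_trials, replace = TRUE),
    dropout = stats::runif(n_trials, space$dropout[1], space$dropout[2]))
  objective <- numeric(n_trials)
  best <- NULL
  for (i in seq_len(n_trials)) {
    tc <- train_config(learning_rate = draws$lr[i],
                       lr_decay_factor = draws$decay_factor[i],
                       lr_decay_every = draws$decay_every[i],
                       l2 = draws$l2[i], batch_size = draws$batch[i],
                       epochs = base$epochs,
                       dropout_embed = draws$dropout[i],
                       dropout_state = draws$dropout[i],
                       variant = base$variant, seed = base$seed,
                       patience = base$patience,
                       eval_every = base$eval_every)
    ck <- train_model(corpus, tb, tc, mconf)
    objective[i] <- max(ck$log$val_mrr5, na.rm = TRUE)
    if (is.null(best) || objective[i] > best$mrr5)
      best <- list(config = tc, mrr5 = objective[i])
    set.seed(base$seed + i)   # decouple next trial from training RNG use
  }
  draws$val_mrr5 <- objective
  list(best = best$config, best_mrr5 = best$mrr5, trials = draws)
}

#' Train an ensemble over independent random splits
#'
#' Trains \code{k} models with derived seeds, each on its own random
#' train/val/test split, evaluates each on its test split, and reports
#' per-run metrics plus their mean and standard deviation — the protocol
#' used to report headline numbers with split-to-split spread.
#'
#' @param corpus,tb,tconf,mconf as in \code{\link{train_model}}.
#' @param k ensemble size (evaluation protocol default 20; desk-scale
#'   default 5).
#' @param keep_models retain the k checkpoints (memory-heavy; default
#'   FALSE).
#' @return list with \code{per_run} (data.frame seed/hr1/hr3/mrr5),
#'   \code{summary} (mean and sd per metric), optionally \code{models}.
#' @export
train_ensemble <- function(corpus, tb, tconf = train_config(),
                           mconf = model_config(), k = 5L,
                           keep_models = FALSE) {
  stopifnot(k >= 1)
  runs <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (i in seq_len(k)) {
    seed_i <- (tconf$seed + 1000L * i) %% .Machine$integer.max
    tc <- tconf
    tc$seed <- as.integer(seed_i)
    sp <- make_splits(corpus, seed = tc$seed)
    ck <- train_model(corpus, tb, tc, mconf, splits = sp)
    test_q <- corpus_queries(corpus[sp$test], tc$variant)
    ev <- evaluate_model(ck, test_q)
    runs[[i]] <- data.frame(run = i, seed = tc$seed, n_test = ev$n,
                            hr1 = ev$hr1, hr3 = ev$hr3, mrr5 = ev$mrr5)
    if (keep_models) models[[i]] <- ck
  }
  per_run <- do.call(rbind, runs)
  summary <- data.frame(
    metric = c("hr1", "hr3", "mrr5"),
    mean = c(mean(per_run$hr1), mean(per_run$hr3), mean(per_run$mrr5)),
    sd = c(stats::sd(per_run$hr1), stats::sd(per_run$hr3),
           stats::sd(per_run$mrr5)))
  out <- list(per_run = per_run, summary = summary)
  if (keep_models) out$models <- models
  out
}
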