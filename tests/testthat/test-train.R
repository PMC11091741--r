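test_that("binary cross-entropy over the toolbox matches closed forms", {
  expect_equal(compute_loss(c(0.5, 0.5), 1, "binary"), log(2))
  # (near) one-hot prediction on the target: loss collapses to ~0
  expect_lt(compute_loss(c(1 - 1e-9, 1e-9), 1, "binary"), 1e-5)
  expect_equal(compute_loss(c(0.25, 0.75), 2, "categorical"), -log(0.75))
  set.seed(31)
  for (rep in 1:20) {
    u <- sample(3:12, 1)
    y <- stats::runif(u); y <- y / sum(y)
    t <- sample(u, 1)
    expect_equal(compute_loss(y, t, "binary"), oracle_loss_binary(y, t),
                 tolerance = 1e-6)
  }
  expect_error(compute_loss(c(0.4, 0.6), 3), "out of toolbox range")
})

test_that("backprop matches finite-difference gradients on a 4-node query", {
  set.seed(32)
  u <- 7
  for (loss in c("binary", "categorical")) {
    mconf <- model_config(d_t = 3, d_e = 3, loss = loss, prop_steps = 1)
    params <- init_model_params(u, mconf, seed = 33)
    desc <- matrix(rnorm((u + 1) * 3), u + 1, 3); desc[u + 1, ] <- 0
    w <- awr("x", c(2, 5, 3, 2), rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
    qg <- build_query_graph(w, target_step = 4, R = c(2, 3))
    expect_equal(mconf$d_c, 6)
    expect_equal(qg$input_length, 3)   # 3 upstream nodes + query node
    fw <- forward_query(qg, params, desc, mconf, keep_cache = TRUE)
    bw <- backward_query(fw, qg$target, params)
    checked <- 0
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        fd <- fd_grad(qg, params, desc, mconf, nm, i)
        an <- bw$grads[[nm]][i]
        if (abs(fd - an) > 1e-8)
          expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
        checked <- checked + 1
      }
    }
    expect_gte(checked, 10)
  }
})

test_that("gradient flows to the embedding table but not to descriptions", {
  g <- det_grammar()
  tb <- g$toolbox
  mconf <- model_config(d_t = 8, d_e = 8)
  tconf <- train_config(epochs = 1, seed = 41, batch_size = 8)
  desc <- encode_descriptions(tb, "mock", d_e = 8, seed = 41)
  desc0 <- unclass(desc) + 0
  ck <- train_model(generate_corpus(g, 20), tb, tconf, mconf, desc = desc)
  p0 <- init_model_params(30, mconf, seed = 41)
  expect_false(isTRUE(all.equal(ck$params$Wtool, p0$Wtool)))
  expect_identical(unclass(ck$desc), desc0)   # frozen, bitwise
})

test_that("splits are workflow-level, disjoint, exhaustive and seeded", {
  corpus <- lapply(1:100, function(i) awr(paste0("w", i), c(1, 2),
                                          rbind(c(1, 2))))
  sp <- make_splits(corpus, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:100)
  sp2 <- make_splits(corpus, seed = 5)
  expect_identical(sp, sp2)
  expect_error(make_splits(corpus, fractions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_warning(make_splits(corpus[1:5], seed = 1), "fewer than 10")
})

test_that("training loss decreases on a deterministic grammar", {
  g <- det_grammar(13)
  corpus <- generate_corpus(g, 50)
  mconf <- model_config(d_t = 16, d_e = 16)
  tconf <- train_config(epochs = 10, seed = 42, batch_size = 16,
                        dropout_embed = 0, dropout_state = 0)
  ck <- train_model(corpus, g$toolbox, tconf, mconf)
  expect_equal(nrow(ck$log), 10)
  # clear downward trend over the first epochs
  expect_lt(ck$log$train_loss[10], ck$log$train_loss[1])
  expect_lt(min(ck$log$train_loss), 0.9 * ck$log$train_loss[1])
})

test_that("two runs with the same seed are bitwise identical", {
  g <- det_grammar(14)
  corpus <- generate_corpus(g, 20)
  mconf <- model_config(d_t = 8, d_e = 8)
  tconf <- train_config(epochs = 3, seed = 9, batch_size = 8)
  ck1 <- train_model(corpus, g$toolbox, tconf, mconf)
  ck2 <- train_model(corpus, g$toolbox, tconf, mconf)
  expect_identical(ck1$params, ck2$params)
  expect_identical(ck1$log, ck2$log)
  # and dropout makes trajectories differ from the dropout-free run
  tconf0 <- tconf; tconf0$dropout_embed <- 0; tconf0$dropout_state <- 0
  ck3 <- train_model(corpus, g$toolbox, tconf0, mconf)
  expect_false(identical(ck1$params$Wtool, ck3$params$Wtool))
})

test_that("ensemble summary matches a recomputed mean and sd", {
  g <- det_grammar(15)
  corpus <- generate_corpus(g, 20)
  mconf <- model_config(d_t = 8, d_e = 8)
  tconf <- train_config(epochs = 2, seed = 3, batch_size = 8)
  ens <- train_ensemble(corpus, g$toolbox, tconf, mconf, k = 2)
  expect_equal(nrow(ens$per_run), 2)
  expect_equal(ens$summary$mean[ens$summary$metric == "hr1"],
               mean(ens$per_run$hr1))
  expect_equal(ens$summary$sd[ens$summary$metric == "mrr5"],
               stats::sd(ens$per_run$mrr5))
})

test_that("random search returns the argmax of its trials", {
  g <- det_grammar(16)
  corpus <- generate_corpus(g, 15)
  mconf <- model_config(d_t = 4, d_e = 4)
  base <- train_config(epochs = 2, seed = 2, batch_size = 8)
  tuned <- tune_hyperparameters(corpus, g$toolbox, base, mconf, n_trials = 3)
  expect_equal(nrow(tuned$trials), 3)
  expect_equal(tuned$best_mrr5, max(tuned$trials$val_mrr5))
  expect_equal(tuned$best$learning_rate,
               tuned$trials$lr[which.max(tuned$trials$val_mrr5)])
})

test_that("checkpoints survive a save/load round trip", {
  g <- det_grammar(17)
  corpus <- generate_corpus(g, 15)
  ck <- train_model(corpus, g$toolbox,
                    train_config(epochs = 1, seed = 4, batch_size = 8),
                    model_config(d_t = 4, d_e = 4))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  expect_identical(ck2$params, ck$params)
  expect_identical(ck2$toolbox_hash, ck$toolbox_hash)
})

test_that("the categorical loss form also recovers the deterministic grammar", {
  g <- det_grammar(101)
  corpus <- generate_corpus(g, 50)
  ck <- train_model(corpus, g$toolbox,
                    train_config(learning_rate = 3e-3, epochs = 200,
                                 seed = 11, batch_size = 32,
                                 dropout_embed = 0, dropout_state = 0,
                                 patience = 10, eval_every = 2),
                    model_config(d_t = 16, d_e = 16, loss = "categorical"))
  tr <- evaluate_model(ck, corpus_queries(corpus[ck$splits$train], "graph"))
  expect_gte(tr$hr1, 0.95)
  expect_lte(nrow(ck$log), 200)
})
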