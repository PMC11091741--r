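# nexttool

Session-based recommendation of the next tool to append to a bioinformatics
workflow-in-progress.

Workflow platforms such as Galaxy offer thousands of tools, and knowing
which one can sensibly follow the steps already assembled is the hard part
of building a pipeline. `nexttool` models the workflow-in-progress as a
directed acyclic graph of tool invocations (steps *S*, data-flow
connections *C*) and ranks every tool in a fixed toolbox *T* by its
probability of being the next step after a user-chosen set *R* of preceding
steps:

```
P = model(w = (S, C), R, T),    recommendation = T[argmax(P)]
```

The model is a gated graph neural network in the session-recommendation
lineage:

1. **Node features** — each node gets `x = [x_t || x_e]`: a learnable
   tool-ID embedding `x_t = t_ind × W_tool` plus a frozen description
   sentence embedding `x_e` (the NLP component).
2. **Propagation** — message passing over the 0/1 connectivity
   `A = [A_out | A_in]` with a GRU update per node (update gate `z`, reset
   gate `r`, candidate `tanh(W_h a + U_h (r ⊙ v))`).
3. **Aggregation** — a local embedding `w_l` (state of the most recent
   tool node) and a global embedding from attention scores
   `α_i = qᵀσ(W1 w_l + W2 s_i + b)`, pooled as `w_g = Σ α_i s_i`.
4. **Fusion and scoring** — `w_s = W4 W3 [w_l || w_g]` is scored against
   the *same* embedding table (weight tying):
   `ŷ = softmax(W_tool × w_s)`; the top-5 tools are shown by default.

Training minimizes cross-entropy (the toolbox-averaged binary form by
default, standard categorical form behind a switch) with mini-batch Adam,
L2 penalty, stepped learning-rate decay, and dropout on initial embeddings
and post-propagation states. Evaluation reports HR@1, HR@3 and MRR@5
(1/rank if the truth ranks ≤ 5, else 0), optionally broken down by input
query length. Forward and backward passes are hand-derived matrix calculus,
verified in the test suite against scalar loop oracles and finite
differences.

Two variants share one code path: the **graph** variant consumes the
upstream closure of `R` with a blank query node appended (`R → q`), the
**sequence** variant linearizes the prefix into a path with `R` = the most
recent step.

## Worked example

Everything runs on seeded synthetic corpora — no downloads. A
deterministic workflow grammar (30 tools in 5 categories, 5 linear pipeline
templates with one fixed tool per slot) has a unique correct successor for
every prefix, so a model that works must recover it:

```r
library(nexttool)

g      <- build_grammar(grammar_spec(n_tools = 30, n_categories = 5,
                                     n_templates = 5, template_len = c(4, 7),
                                     determinism = "deterministic", seed = 101))
corpus <- generate_corpus(g, 50)
ck     <- train_model(corpus, g$toolbox,
                      train_config(learning_rate = 3e-3, epochs = 200,
                                   seed = 11, batch_size = 32,
                                   dropout_embed = 0, dropout_state = 0,
                                   patience = 10, eval_every = 2),
                      model_config(d_t = 16, d_e = 16))

evaluate_model(ck, corpus_queries(corpus[ck$splits$test], "graph"))
#> <eval over 21 queries: HR@1=1.0000 HR@3=1.0000 MRR@5=1.0000>

q <- corpus_queries(corpus[ck$splits$test], "graph")[[1]]
recommend(q, ck, top_n = 3)
#>   rank    tool_id probability
#> 1    1 tool019_c4 0.990424365
#> 2    2 tool027_c5 0.003654318
#> 3    3 tool015_c3 0.002759425
```

HR@1 = 1 means the grammar's true successor ranked first for every held-out
query; the `recommend()` table is the top-n display a user would see, with
the probability mass concentrated on the unique correct next tool.

Galaxy users can build corpora from real workflow exports instead:
`read_galaxy_workflow("wf.ga")` parses the `.ga` JSON (dropping data-input
steps and contracting their connections), `filter_corpus()` applies the
standard hygiene rules (2–50 steps, de-duplication), and the
`inst/scripts/nexttool` script wraps prepare/train/evaluate/recommend for
shell use.

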