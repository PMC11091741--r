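---
title: "Recommending the next tool in a bioinformatics workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending the next tool in a bioinformatics workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nexttool)
```

## The problem

Platforms such as Galaxy expose thousands of tools, and assembling them into
an analysis pipeline requires knowing which tool can sensibly follow the
steps already in place. `nexttool` treats this as a *session-based
recommendation* problem: the only context is the workflow-in-progress
itself — no user history, no external annotation. Given an incomplete
workflow and the set of steps `R` whose outputs will feed the next tool, the
model returns a probability for every tool in a fixed toolbox and displays
the top-ranked candidates.

A workflow is held as an abstract workflow representation (AWR): an ordered
list of steps, each invoking one tool from the toolbox (repeat invocations
allowed), plus directed data-flow connections forming a DAG. Two model
variants share one implementation: the graph variant consumes the upstream
closure of `R` as a graph query with a blank query node appended (edges
`R -> q`), while the sequence variant linearizes the prefix into a path and
takes `R` to be the most recent step. A path query with `R = {last}` is
byte-identical between the two variants, which is tested.

## The model

Each node's initial feature vector is the concatenation
`x = [x_t || x_e]` of

* a learnable tool-ID embedding `x_t` (row of the table `W_tool`, one row
  per tool plus a dedicated QUERY row for the blank node), and
* a frozen description sentence embedding `x_e` (the NLP component;
  dropped entirely when the component is ablated).

A gated graph neural network then runs `prop_steps` rounds of message
passing over the 0/1 connectivity `A = [A_out | A_in]`: node `i`'s
activation is the concatenation of its predecessors' and successors' summed
states plus a bias, and a GRU (update gate, reset gate, tanh candidate)
folds that activation into the node state. One propagation round is the
default: queries are small (tens of nodes) and a single round already gives
every node its direct neighborhood, matching the session-graph lineage this
architecture follows; the printed candidate-state expression in that
lineage has inconsistent sub/superscripts, and the implementation uses the
standard GRU candidate `tanh(W_h a + U_h (r * v))` — the configuration
records exactly this form.

States are pooled into a workflow embedding in two parts. The *local*
embedding `w_l` is the state of the most recent real tool node; when
several steps feed the recommendation point the mean of their states is
used (the symmetric choice; the formulation itself only fixes the
single-predecessor case). The *global* embedding applies attention scores
`alpha_i = q . sigma(W1 w_l + W2 s_i + b)` and pools `w_g = sum alpha_i
s_i`. The raw scores are used as weights — no softmax — matching the
attention of the session-graph formulation; a configuration flag enables
softmax normalization for experiments. The query node is masked out of
pooling. The mean-pooling ablation replaces attention with a plain mean.

`[w_l || w_g]` is compressed by `W3` and projected to tool space by `W4`
(two separate matrices — folding them into one is slightly worse and would
force the workflow dimension to equal the tool dimension). Scores are inner
products with the *same* `W_tool` rows used at the input (weight tying),
softmaxed over the toolbox with the QUERY row excluded. Ranking is by
descending probability with ascending-index tie-break, top-5 shown by
default.

## Training

The default loss is binary cross-entropy averaged over the toolbox with a
one-hot target — the printed form of this architecture's objective —
applied to the softmax outputs. Because that pairing is unusual (it is
plausibly a typographic conflation of the categorical form), the standard
categorical cross-entropy `-log(yhat[target])` is available behind a
configuration switch and both forms are exercised by the tests. Logs are
clamped at `1e-7`. Gradients for the whole stack are hand-derived
reverse-mode matrix calculus, verified against central finite differences.

Optimization is mini-batch Adam with L2 penalty and stepped learning-rate
decay. Dropout is applied at exactly two sites: the initial tool-ID
embeddings, and the node states after propagation. Splits are made over
whole workflows (80/10/10 by default) *before* prefix-query extraction, so
no workflow leaks across sets; the parameters of the epoch with the best
validation MRR@5 are kept. Hyperparameter search is a seeded random search
over the documented ranges (learning rate 1e-4..1e-2 log-uniform, decay
factor 0.3..0.9 every 3..10 epochs, L2 1e-6..1e-3, batch 32/64/128,
dropout 0..0.5); those ranges are repository choices, as is the tool-ID
dimension default `d_t = 64` (the lineage uses ~100; 64 keeps desk scale).
Ensembles retrain over `k` independent random splits with derived seeds and
report mean and standard deviation per metric. All randomness flows from
the single run seed; two runs with equal configuration are bitwise
identical.

## Description embeddings

A production deployment would embed tool descriptions with a frozen
biomedical sentence transformer (768-dimensional). That backend is a
pluggable interface here and is not bundled; the package ships a
deterministic mock encoder that lowercases, strips punctuation, hashes each
token of the description to a seeded Gaussian vector, and L2-normalizes the
token sum. The property the model actually exploits — descriptions sharing
vocabulary map to nearby vectors, identical descriptions collide exactly —
is preserved, tested, and sufficient for the synthetic corpora below. The
matrix is frozen: training asserts it is bitwise unchanged.

## Synthetic corpora and what they show

Real workflow corpora are scraped from public Galaxy servers and are out of
scope here; the generator emulates their shape (toolbox of tens to
hundreds of tools, DAG workflows of 2–50 steps with branching and repeat
invocations, short descriptions whose similarity tracks co-usage) with a
seeded grammar:

* **Deterministic grammar** (30 tools, 5 categories, 5 linear templates of
  4–7 steps, one fixed tool per slot, distinct template heads): every
  prefix has exactly one correct successor, emitted as a table. A model
  that recovers the grammar must rank that successor first; the acceptance
  suite trains on 50 sampled workflows and requires HR@1 >= 0.95 on
  training queries and >= 0.9 held out. This is a function-recovery test:
  it shows the forward/backward/optimizer loop works end to end, not that
  real corpora are this predictable.
* **Two-back fork grammar** (30 tools, 3 templates of two fork motifs, 150
  workflows, 20% noise): the spine forks into a *signal* step and a
  dead-end side branch — think of a QC step whose report feeds nothing —
  and only the signal feeds the next step, whose tool is a fixed map of
  the signal tool. The side the signal lands on is randomized per
  workflow. The graph query's upstream closure therefore always isolates
  the signal exactly, while the linearized prefix keeps the dead end and
  has it as the most recent step half the time. This is the controlled
  setting for the graph-vs-sequence comparison (3 seeds, HR@1), with a
  bigram frequency recommender over linearized sequences as the floor.
* **Skewed category grammar** (72 tools in 6 categories, 100 workflows):
  within-category tool draws follow a Zipf-like skew, so each category has
  a tail of rare tools whose ID embeddings see almost no training — the
  regime in which frozen description embeddings (which place every
  category member near its common siblings) earn their keep; and
  uninformative "generic" pass-through steps are interleaved at random,
  the situation the attention mechanism exists to down-weight. Ablations
  (full model, NLP-only with mean pooling, attention-only without
  descriptions) are compared on mean MRR@5 over 5 seeds. At this scale the
  removal of descriptions costs clearly more than the removal of
  attention; the increment of attention *on top of* descriptions is
  smaller than seed-to-seed spread, consistent with it being the smallest
  effect in this architecture family, and five desk-scale seeds cannot
  reliably resolve it.

Desk-scale problem sizes (tens of tools, 50–150 workflows, embedding
dimensions 16) were chosen so the full suite trains in minutes on one CPU;
they are stated here as the package's reference conditions. What passing
shows is correctness and directional behavior of the architecture — not
the headline accuracy on real Galaxy corpora, which depends on external
data and a transformer encoder.

## Numerical and degenerate-case choices

* Epsilon `1e-7` inside loss logs; non-finite propagation states abort
  with the offending node index.
* Ties in rankings break by ascending toolbox index, making evaluation
  deterministic.
* A workflow step with no predecessors yields no graph-mode query (`R`
  must be non-empty); sequence linearization is Kahn's algorithm with
  smallest-step-id tie-break, so it is reproducible.
* De-duplication of corpora keys on the tool list *plus* sorted
  connections by default (two differently wired workflows over the same
  tools both survive); a flag collapses on tool lists alone.
* The query node's embedding is a learned row by default; a configuration
  option initializes it from zeros instead.
* Checkpoint files store all parameter arrays plus the toolbox hash;
  loading against a corpus with a different toolbox hash is refused.

## Known limitations

* The mock description encoder captures vocabulary overlap, not meaning:
  paraphrased descriptions with disjoint vocabulary get unrelated vectors.
* Training is single-threaded R; it is sized for desk-scale corpora, not
  for tens of thousands of workflows.
* Tool parameters/configurations, multi-target queries and mid-workflow
  insertion are out of scope; recommendations always append after `R`.
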