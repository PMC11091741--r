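Package: nexttool
Title: Next-Tool Recommendation for Bioinformatics Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Session-based recommendation of the next tool to append to a
    bioinformatics workflow-in-progress. A workflow is represented as a
    directed acyclic graph of tool invocations; a gated graph neural
    network propagates tool-embedding features along the data-flow edges,
    an attention mechanism pools node states into a workflow embedding,
    and every tool in the toolbox is scored by similarity of its
    embedding to the compressed workflow representation. Includes readers
    for Galaxy '.ga' workflow exports, corpus filtering and splitting,
    a frozen description-embedding backend with a deterministic mock,
    training with the Adam optimizer, top-k ranking metrics (hit rate,
    mean reciprocal rank), and seeded synthetic workflow grammars for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
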