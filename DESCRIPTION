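Package: netsieve
Title: Condition-Specific Sub-Network Inference from Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers from a genome-wide typed interaction network the sparsest
    sub-network that best connects a list of genes prioritized by a
    differential-expression experiment. Edges of the mixed (partly directed)
    interactome receive presence probabilities derived from the log fold
    changes of their endpoint genes under a normal model; mode-valid acyclic
    paths between list genes (upstream regulatory mode or downstream pathway
    mode) are enumerated and the k most likely are retained per gene pair;
    the probability that a gene stays connected within a candidate sub-network
    is computed exactly over the retained paths; and a greedy hill-climbing
    search maximizes total connectivity minus a per-edge sparsity cost.
    Includes readers and writers for tab-delimited networks, expression tables,
    gene lists, SIF and JSON exports, hypergeometric term enrichment from GAF
    annotations, and a synthetic-scenario generator with planted regulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
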