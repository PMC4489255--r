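# Fixtures are built in code; no data files.

# A probabilistic network with hand-set edge probabilities, bypassing the
# expression model.
toy_pnet <- function(edges, probs) {
  stopifnot(nrow(edges) == length(probs))
  edges$directed <- as.logical(edges$directed)
  edges$prob <- probs
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(
    list(nodes = nodes, edges = edges,
         node_scores = stats::setNames(rep(0.5, length(nodes)), nodes),
         stats = netsieve::expression_stats(0, 1)),
    class = c("prob_network", "interaction_network")
  )
}

toy_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(from = r[[1]], to = r[[2]], type = r[[3]],
               directed = as.logical(as.integer(r[[4]])),
               stringsAsFactors = FALSE)
  }))
}

# Random typed mixed graph with uniform edge probabilities, for property
# tests against the exhaustive oracles.
random_pnet <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  from <- sample(nodes, 3 * n_edges, replace = TRUE)
  to <- sample(nodes, 3 * n_edges, replace = TRUE)
  type <- sample(c("pd", "pp", "met", "srna"), 3 * n_edges, replace = TRUE)
  keep <- from != to & !duplicated(paste(from, to, type))
  e <- data.frame(from = from[keep], to = to[keep], type = type[keep],
                  stringsAsFactors = FALSE)[seq_len(min(n_edges, sum(keep))), ]
  e$directed <- e$type %in% c("pd", "met", "srna")
  toy_pnet(e, round(stats::runif(nrow(e)), 3))
}

# Fake path records carrying only edge indices (all the probability code
# needs).
edge_path <- function(...) list(edges = c(...))

write_lines <- function(lines, name = "fixture.txt") {
  path <- withr::local_tempfile(fileext = paste0("-", name),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small scenario spec that keeps unit tests fast.
small_spec <- function(seed, ...) {
  netsieve::scenario_spec(n_genes = 50, n_regulators = 1,
                          targets_per_regulator = 6, n_pd = 25, n_pp = 30,
                          n_met = 12, seed = seed, ...)
}
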