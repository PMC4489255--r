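#' Infer the sub-network best connecting a gene list
#'
#' The package's central fitting function. Given a typed interactome, a
#' differential-expression table and a list of genes of interest, it
#' (1) converts the network into a probabilistic network whose edge presence
#' probabilities reflect the differential expression of the edge endpoints,
#' (2) enumerates mode-valid acyclic paths between list genes and retains
#' the k most likely per ordered gene pair, (3) evaluates candidate
#' sub-networks by the exact probability that each list gene stays connected
#' through its retained paths, penalized by a per-edge cost, and
#' (4) maximizes this objective by greedy hill climbing.
#'
#' In `"upstream"` mode the inferred sub-network describes the regulatory
#' mechanism upstream of the expression response: paths climb against edge
#' direction to a common regulator and descend to the end gene, with
#' regulatory first and last edges. In `"downstream"` mode paths follow edge
#' direction, recovering (in)activated pathways. Decreasing `cost` grows the
#' inferred sub-network; see [cost_sweep()] for an ordered series.
#'
#' @param network An `interaction_network` from [read_network()], or a file
#'   path to a 4-column network TSV.
#' @param expression Named numeric vector of log fold changes, or a file
#'   path readable by [read_expression()].
#' @param genes Character vector of gene identifiers, or a file path
#'   readable by [read_gene_list()].
#' @param mode `"upstream"` or `"downstream"`.
#' @param cost Nonnegative per-edge cost in the objective.
#' @param path_length Maximum path length in edges, in \[2, 5\].
#' @param k Retained best paths, in \[5, 50\].
#' @param regulatory_types Interaction types accepted as regulatory terminal
#'   edges in upstream mode.
#' @param k_scope `"pair"` or `"start"`; see [run_config()].
#' @param stats Optional `expression_stats` overriding the normal fit.
#' @return A `subnet_fit` object with components `subnetwork` (selected
#'   edges), `objective`, `connectivity` (per start gene), `network` (the
#'   probabilistic network), `pathset`, `trace`, `config`, `expression` and
#'   `gene_list`. Methods: `print`, `summary`, `plot`.
#' @examples
#' sc <- generate_scenario(scenario_spec(n_genes = 40, n_regulators = 1,
#'                                       targets_per_regulator = 6,
#'                                       n_pd = 20, n_pp = 25, n_met = 10,
#'                                       seed = 7))
#' fit <- infer_subnetwork(sc$paths$network, sc$paths$expression,
#'                         sc$paths$genelist, mode = "upstream", cost = 0.01)
#' fit
#' @export
infer_subnetwork <- function(network, expression, genes, mode, cost,
                             path_length = 4L, k = 10L,
                             regulatory_types = c("pd", "srna"),
                             k_scope = "pair", stats = NULL) {
  cl <- match.call()
  if (is.character(network) && length(network) == 1L) {
    network <- read_network(network)
  }
  if (is.character(expression) && length(expression) == 1L &&
      file.exists(expression)) {
    expression <- read_expression(expression)
  }
  if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
    genes <- read_gene_list(genes)
  }
  config <- run_config(mode = mode, cost = cost,
                       max_path_length = path_length, k = k,
                       regulatory_types = regulatory_types,
                       k_scope = k_scope)
  pnet <- if (is.null(stats)) {
    build_probabilistic_network(network, expression)
  } else {
    build_probabilistic_network(network, expression, stats)
  }
  pathset <- k_best_paths(pnet, genes, config)
  result <- greedy_optimize(pathset, pnet, config)
  conn <- vapply(pathset$paths, function(p) {
    connectivity(p, result$subnetwork$idx, pnet)
  }, numeric(1))
  structure(
    list(subnetwork = result$subnetwork, objective = result$objective,
         connectivity = conn, network = pnet, pathset = pathset,
         trace = result$trace, universe = result$universe, config = config,
         expression = expression, gene_list = pathset$genes, call = cl),
    class = "subnet_fit"
  )
}

#' @export
print.subnet_fit <- function(x, ...) {
  cat("Inferred sub-network (", x$config$mode, " mode, cost ",
      format(x$config$cost), ")\n", sep = "")
  cat("  ", nrow(x$subnetwork$edges), " edges, ",
      length(unique(c(x$subnetwork$edges$from, x$subnetwork$edges$to))),
      " nodes; ", sum(x$connectivity > 0), " of ", length(x$gene_list),
      " list genes connected\n", sep = "")
  cat(sprintf("  objective %.4f = connectivity %.4f - penalty %.4f\n",
              x$objective$total, x$objective$connectivity_term,
              x$objective$penalty_term))
  invisible(x)
}

#' @export
summary.subnet_fit <- function(object, ...) {
  e <- object$subnetwork$edges
  deg <- sort(table(c(e$from, e$to)), decreasing = TRUE)
  out <- list(
    mode = object$config$mode,
    cost = object$config$cost,
    n_edges = nrow(e),
    n_nodes = length(unique(c(e$from, e$to))),
    edge_types = if (nrow(e)) table(e$type) else table(character(0)),
    n_list_genes = length(object$gene_list),
    n_connected = sum(object$connectivity > 0),
    connectivity = sort(object$connectivity, decreasing = TRUE),
    objective = object$objective,
    hubs = utils::head(deg, 5L),
    n_moves = nrow(object$trace)
  )
  class(out) <- "summary.subnet_fit"
  out
}

#' @export
print.summary.subnet_fit <- function(x, ...) {
  cat("Sub-network inference summary (", x$mode, " mode, cost ",
      format(x$cost), ")\n", sep = "")
  cat("  Selected:", x$n_edges, "edges over", x$n_nodes, "nodes in",
      x$n_moves, "greedy moves\n")
  if (x$n_edges) {
    cat("  Edge types:",
        paste(names(x$edge_types), as.integer(x$edge_types), sep = "=",
              collapse = ", "), "\n")
  }
  cat("  List genes connected:", x$n_connected, "of", x$n_list_genes, "\n")
  print(x$objective)
  if (length(x$hubs)) {
    cat("  Highest-degree nodes:",
        paste(names(x$hubs), as.integer(x$hubs), sep = ":",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot an inferred sub-network
#'
#' Draws the selected sub-network with node color encoding the direction and
#' strength of differential expression (red over-, green under-expressed,
#' grey unmeasured), edge line type encoding the interaction type and arrows
#' marking directed edges. Requires the igraph package.
#'
#' @param x A `subnet_fit`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return Invisibly, the igraph object.
#' @export
plot.subnet_fit <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  e <- x$subnetwork$edges
  if (nrow(e) == 0L) {
    plot.new()
    text(0.5, 0.5, "empty sub-network")
    return(invisible(NULL))
  }
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to", "type", "directed", "prob")], directed = TRUE)
  lfc <- x$expression[igraph::V(g)$name]
  pal <- function(v) {
    if (is.na(v)) return("grey80")
    s <- max(-1, min(1, v / 3))
    if (s >= 0) grDevices::rgb(1, 1 - s, 1 - s) else grDevices::rgb(1 + s, 1, 1 + s)
  }
  igraph::V(g)$color <- vapply(lfc, pal, character(1))
  types <- sort(unique(e$type))
  igraph::E(g)$lty <- match(igraph::E(g)$type, types)
  igraph::E(g)$arrow.mode <- ifelse(igraph::E(g)$directed, 2L, 0L)
  igraph::plot.igraph(g, vertex.size = 9, vertex.label.cex = 0.7,
                      edge.arrow.size = 0.4, ...)
  invisible(g)
}
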