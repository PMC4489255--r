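#' Run configuration for sub-network inference
#'
#' Bundles the parameters governing a run: the run mode, the per-edge
#' sparsity cost, the maximum path length, the number of retained best paths
#' and the set of interaction types counted as regulatory.
#'
#' Two run modes exist. In *downstream* mode paths follow the natural
#' direction of the network, recovering pathways activated by the listed
#' genes. In *upstream* mode a path first runs against edge direction from
#' the start gene up to a common regulator and then forward down to the end
#' gene, and its first and last edges must be regulatory interactions; such
#' paths describe a shared regulatory mechanism for both terminal genes.
#'
#' The path length is bounded between 2 and 5 interactions (default 4) and
#' the number of retained paths k between 5 and 50 (default 10); values
#' outside these ranges are rejected.
#'
#' @param mode `"upstream"` or `"downstream"`.
#' @param cost Nonnegative per-edge cost x_c in the objective.
#' @param max_path_length Maximum path length in edges, in \[2, 5\].
#' @param k Number of most-likely paths retained, in \[5, 50\].
#' @param regulatory_types Interaction-type labels treated as regulatory
#'   (terminal-edge requirement of upstream mode).
#' @param k_scope `"pair"` keeps the k best paths per ordered (start, end)
#'   gene pair; `"start"` keeps the k best per start gene over all ends.
#' @return A validated `run_config` object.
#' @examples
#' run_config("upstream", cost = 0.01)
#' @export
run_config <- function(mode, cost, max_path_length = 4L, k = 10L,
                       regulatory_types = c("pd", "srna"),
                       k_scope = c("pair", "start")) {
  cfg <- structure(
    list(mode = mode, cost = cost, max_path_length = max_path_length,
         k = k, regulatory_types = regulatory_types,
         k_scope = match.arg(k_scope)),
    class = "run_config"
  )
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Fills defaults (path length 4, k 10, regulatory types `pd`/`srna`) and
#' enforces the permitted ranges: path length in \[2, 5\], k in \[5, 50\],
#' cost >= 0, and a nonempty regulatory type set in upstream mode.
#'
#' @param config A `run_config` or a bare list with at least `mode` and
#'   `cost`.
#' @return The validated `run_config`.
#' @export
validate_config <- function(config) {
  if (is.null(config$mode) || !config$mode %in% c("upstream", "downstream")) {
    stop("mode must be 'upstream' or 'downstream'")
  }
  if (is.null(config$cost) || !is.numeric(config$cost) ||
      length(config$cost) != 1L || !is.finite(config$cost) ||
      config$cost < 0) {
    stop("cost must be a single nonnegative number")
  }
  if (is.null(config$max_path_length)) config$max_path_length <- 4L
  if (is.null(config$k)) config$k <- 10L
  if (is.null(config$regulatory_types)) {
    config$regulatory_types <- c("pd", "srna")
  }
  if (is.null(config$k_scope)) config$k_scope <- "pair"
  l <- config$max_path_length
  if (!is.numeric(l) || length(l) != 1L || l != as.integer(l) ||
      l < 2L || l > 5L) {
    stop("max_path_length must be an integer in [2, 5] (got ", l, ")")
  }
  config$max_path_length <- as.integer(l)
  k <- config$k
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 5L || k > 50L) {
    stop("k must be an integer in [5, 50] (got ", k, ")")
  }
  config$k <- as.integer(k)
  if (config$mode == "upstream" && length(config$regulatory_types) == 0L) {
    stop("upstream mode requires a nonempty set of regulatory edge types")
  }
  if (!config$k_scope %in% c("pair", "start")) {
    stop("k_scope must be 'pair' or 'start'")
  }
  structure(config, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Run config: %s mode, cost %.4g, path length <= %d, k = %d (%s)\n",
    x$mode, x$cost, x$max_path_length, x$k,
    if (x$k_scope == "pair") "per gene pair" else "per start gene"))
  if (x$mode == "upstream") {
    cat("Regulatory edge types:",
        paste(x$regulatory_types, collapse = ", "), "\n")
  }
  invisible(x)
}

# Construct a path record. `edges` are integer row indices into
# network$edges; `forward[i]` says whether edge i was traversed from its
# stored source to its stored target.
make_path <- function(nodes, edges, forward, prob) {
  list(nodes = nodes, edges = edges, forward = forward, prob = prob,
       start = nodes[[1L]], end = nodes[[length(nodes)]])
}

#' Is a path valid under the run mode?
#'
#' Pure predicate over a structurally well-formed path. In downstream mode
#' every directed edge must be traversed forward (undirected edges are free).
#' In upstream mode there must exist a split point m (1 <= m <= length - 1)
#' such that every edge up to m is undirected or traversed against its stored
#' direction and every edge after m is undirected or traversed forward, and
#' additionally the first and last edges must be of a regulatory interaction
#' type. Both segments are required to be nonempty, so the path apex is a
#' genuine common regulator and a bare direct edge does not qualify.
#'
#' @param path A path record as produced by the enumeration functions: list
#'   with `nodes`, `edges` (indices into `network$edges`) and `forward`
#'   (traversal orientation per edge).
#' @param config A `run_config`.
#' @param network The `prob_network` (or `interaction_network`) the path's
#'   edge indices refer to.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_path <- function(path, config, network) {
  len <- length(path$edges)
  if (len < 2L || len > config$max_path_length) return(FALSE)
  if (anyDuplicated(path$nodes)) return(FALSE)
  directed <- network$edges$directed[path$edges]
  forward <- path$forward
  if (config$mode == "downstream") {
    return(all(!directed | forward))
  }
  # upstream: prefix-capable = undirected or traversed against direction,
  # suffix-capable = undirected or traversed forward
  types <- network$edges$type[path$edges]
  if (!(types[1L] %in% config$regulatory_types) ||
      !(types[len] %in% config$regulatory_types)) {
    return(FALSE)
  }
  a <- !directed | !forward
  b <- !directed | forward
  # last index that must sit in the prefix / first that must sit in the suffix
  j <- if (any(!b)) max(which(!b)) else 0L
  i0 <- if (any(!a)) min(which(!a)) else len + 1L
  max(j, 1L) <= min(i0 - 1L, len - 1L)
}

# Per-node adjacency of the mixed graph: for node v, integer matrix-free
# list with edge index, neighbor and orientation of each incident traversal.
# Directed edges appear in both directions (reverse traversals are needed by
# the upstream mode and by the exhaustive oracle).
build_adjacency <- function(network) {
  e <- network$edges
  n <- nrow(e)
  ends <- c(e$from, e$to)
  adj_edge <- rep.int(seq_len(n), 2L)
  adj_to <- c(e$to, e$from)
  adj_fwd <- rep(c(TRUE, FALSE), each = n)
  split_idx <- split(seq_along(ends), ends)
  lapply(split_idx, function(i) {
    list(edge = adj_edge[i], to = adj_to[i], forward = adj_fwd[i])
  })
}

#' Exhaustively enumerate mode-valid paths from one gene
#'
#' Depth-first enumeration of *all* acyclic paths of length at most
#' `config$max_path_length` from `start` to any member of `targets` (other
#' than `start` itself) that satisfy [is_valid_path()]. No pruning beyond
#' simplicity and length is applied, so this is the brute-force reference for
#' the k-best search; intended for small graphs and testing.
#'
#' @param network A `prob_network`.
#' @param start Start gene (must be a network node).
#' @param targets Character vector of end genes.
#' @param config A `run_config`.
#' @return List of path records, in discovery order.
#' @export
enumerate_valid_paths <- function(network, start, targets, config) {
  config <- validate_config(config)
  if (!start %in% network$nodes) {
    stop("start gene '", start, "' is not in the network")
  }
  adj <- build_adjacency(network)
  probs <- network$edges$prob
  targets <- setdiff(targets, start)
  out <- vector("list", 64L); n_out <- 0L
  recurse <- function(nodes, edges, forward) {
    v <- nodes[length(nodes)]
    a <- adj[[v]]
    if (is.null(a)) return()
    for (i in seq_along(a$edge)) {
      w <- a$to[[i]]
      if (w %in% nodes) next
      nodes2 <- c(nodes, w)
      edges2 <- c(edges, a$edge[[i]])
      forward2 <- c(forward, a$forward[[i]])
      if (w %in% targets) {
        p <- make_path(nodes2, edges2, forward2, prod(probs[edges2]))
        if (is_valid_path(p, config, network)) {
          n_out <<- n_out + 1L
          out[[n_out]] <<- p
        }
      }
      if (length(edges2) < config$max_path_length) {
        recurse(nodes2, edges2, forward2)
      }
    }
  }
  recurse(start, integer(0), logical(0))
  out[seq_len(n_out)]
}

# Sort paths by decreasing probability; ties broken by the lexicographic
# order of the node sequence so results are reproducible.
sort_paths <- function(paths) {
  if (length(paths) <= 1L) return(paths)
  prob <- vapply(paths, `[[`, numeric(1), "prob")
  keys <- vapply(paths, function(p) paste(p$nodes, collapse = "\x1f"),
                 character(1))
  paths[order(-prob, keys, method = "radix")]
}

# Truncate a sorted per-start path list to k per (start, end) pair or k per
# start gene, depending on scope.
truncate_paths <- function(paths, k, scope) {
  if (length(paths) == 0L) return(paths)
  if (scope == "start") return(paths[seq_len(min(k, length(paths)))])
  ends <- vapply(paths, `[[`, character(1), "end")
  keep <- unlist(lapply(split(seq_along(paths), ends), function(i) {
    i[seq_len(min(k, length(i)))]
  }), use.names = FALSE)
  paths[sort(keep)]
}

# Mode-aware pruned DFS used by k_best_paths. Equivalent by construction to
# filtering the exhaustive enumeration: the pruning rules only cut branches
# no valid completion can extend (downstream: a backward directed traversal;
# upstream: a non-regulatory or forward-directed first edge, or a backward
# directed traversal after the path has committed to its forward segment).
collect_paths_from <- function(network, adj, start, targets, config) {
  probs <- network$edges$prob
  types <- network$edges$type
  directed <- network$edges$directed
  upstream <- config$mode == "upstream"
  reg <- config$regulatory_types
  maxlen <- config$max_path_length
  out <- vector("list", 64L); n_out <- 0L
  recurse <- function(nodes, edges, forward, committed) {
    v <- nodes[length(nodes)]
    a <- adj[[v]]
    if (is.null(a)) return()
    depth <- length(edges)
    for (i in seq_along(a$edge)) {
      ei <- a$edge[[i]]; w <- a$to[[i]]; fwd <- a$forward[[i]]
      if (w %in% nodes) next
      if (upstream) {
        if (depth == 0L) {
          # first edge sits in the against-direction prefix and must be
          # regulatory
          if (!(types[ei] %in% reg)) next
          if (directed[ei] && fwd) next
        } else if (committed && directed[ei] && !fwd) {
          next
        }
      } else if (directed[ei] && !fwd) {
        next
      }
      committed2 <- committed || (directed[ei] && fwd)
      nodes2 <- c(nodes, w)
      edges2 <- c(edges, ei)
      forward2 <- c(forward, fwd)
      len <- depth + 1L
      if (len >= 2L && w %in% targets) {
        ok <- TRUE
        if (upstream) {
          # terminal edge must be regulatory and able to close the forward
          # segment (the prefix up to it is valid by construction)
          ok <- types[ei] %in% reg && (!directed[ei] || fwd)
        }
        if (ok) {
          n_out <<- n_out + 1L
          out[[n_out]] <<- make_path(nodes2, edges2, forward2,
                                     prod(probs[edges2]))
        }
      }
      if (len < maxlen) recurse(nodes2, edges2, forward2, committed2)
    }
  }
  recurse(start, integer(0), logical(0), FALSE)
  out[seq_len(n_out)]
}

#' Retain the k most likely mode-valid paths between list genes
#'
#' For every ordered pair (A, Y) of distinct gene-list members present in the
#' network, finds all mode-valid acyclic paths of bounded length from A to Y
#' and keeps the `k` with the highest probability (ties broken by the
#' lexicographic order of the node sequence). The retained set is the
#' tractable stand-in for full connectedness: the probability that A remains
#' connected is later evaluated over these paths only.
#'
#' List genes absent from the network are dropped with a warning. Paths of
#' probability zero are legal and retained; a zero-probability edge simply
#' kills any path through it.
#'
#' @param network A `prob_network`.
#' @param gene_list Character vector of gene identifiers.
#' @param config A `run_config`.
#' @return A `path_set`: list with `paths` (named list, start gene ->
#'   sorted list of path records), `genes` (effective gene list) and
#'   `config`.
#' @export
k_best_paths <- function(network, gene_list, config) {
  config <- validate_config(config)
  stopifnot(inherits(network, "prob_network"))
  gene_list <- unique(gene_list)
  present <- gene_list %in% network$nodes
  if (any(!present)) {
    warning(sum(!present), " gene-list member(s) not in the network; dropped")
  }
  genes <- gene_list[present]
  if (length(genes) == 0L) stop("no gene-list members present in the network")
  adj <- build_adjacency(network)
  paths <- lapply(genes, function(A) {
    p <- collect_paths_from(network, adj, A, setdiff(genes, A), config)
    truncate_paths(sort_paths(p), config$k, config$k_scope)
  })
  names(paths) <- genes
  structure(list(paths = paths, genes = genes, config = config),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  n <- vapply(x$paths, length, integer(1))
  cat("Retained path set:", sum(n), "paths for", length(x$genes),
      "start genes (k =", x$config$k, "per",
      if (x$config$k_scope == "pair") "gene pair" else "start gene", ")\n")
  invisible(x)
}
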