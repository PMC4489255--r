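#' Probability of a single path
#'
#' A path is present when all of its edges are present; under independent
#' edge events its probability is the product of its edge probabilities.
#'
#' @param path A path record (see [k_best_paths()]).
#' @param network The `prob_network` the path's edge indices refer to.
#' @return Probability in \[0, 1\].
#' @export
path_probability <- function(path, network) {
  idx <- path$edges
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(network$edges))) {
    stop("path references an unknown edge")
  }
  prod(network$edges$prob[idx])
}

#' Restrict a path set to a sub-network
#'
#' Keeps exactly the paths all of whose edges belong to the sub-network;
#' paths valid in the full probabilistic network can become invalid in a
#' sub-network that lacks one of their edges.
#'
#' @param paths List of path records.
#' @param subnetwork A `subnetwork` object, or an integer vector of edge
#'   indices.
#' @return The surviving subset of `paths`.
#' @export
restrict_paths <- function(paths, subnetwork) {
  idx <- if (inherits(subnetwork, "subnetwork")) subnetwork$idx
         else as.integer(subnetwork)
  if (length(paths) == 0L) return(paths)
  keep <- vapply(paths, function(p) all(p$edges %in% idx), logical(1))
  paths[keep]
}

#' Exact probability that at least one path is present
#'
#' Computes P(union of path events) where each path event is "all edges of
#' the path are present" and each physical edge is one independent Bernoulli
#' variable shared across every path that uses it. Sharing matters: two
#' paths through a common edge are positively correlated, so the naive
#' independent-paths formula overstates the union.
#'
#' The computation is exact over the supplied paths; duplicated paths cannot
#' change the result. Edge-disjoint groups of paths are split into
#' independent factors; within a group the union is evaluated by Shannon
#' expansion, conditioning on the edge shared by the most paths, with closed
#' forms for pairs and for fully disjoint families.
#'
#' @param paths List of path records.
#' @param network The `prob_network` providing edge probabilities.
#' @return Probability in \[0, 1\]; 0 for an empty path list.
#' @seealso [brute_force_union()] for the exponential reference
#'   implementation.
#' @export
union_probability <- function(paths, network) {
  sets <- lapply(paths, function(p) sort(unique(p$edges)))
  union_prob_sets(sets, network$edges$prob)
}

# Core union computation over integer edge-index sets: compiled Shannon
# expansion with independent-component factoring (src/union_prob.cpp).
# Duplicate or absorbed (superset) path events are harmless: they reach the
# empty-set base case without contributing.
union_prob_sets <- function(sets, probs) {
  if (length(sets) == 0L) return(0)
  if (any(lengths(sets) == 0L)) return(1)  # empty conjunction is certain
  .union_prob_shannon(sets, probs)
}

#' Brute-force union probability by edge-state enumeration
#'
#' Reference implementation of [union_probability()]: enumerates all 2^m
#' states of the m edges involved in the paths and sums the probability of
#' every state in which at least one path is fully present. Exponential by
#' construction; refuses more than 20 involved edges.
#'
#' @inheritParams union_probability
#' @return Probability in \[0, 1\].
#' @export
brute_force_union <- function(paths, network) {
  if (length(paths) == 0L) return(0)
  sets <- lapply(paths, function(p) sort(unique(p$edges)))
  if (any(lengths(sets) == 0L)) return(1)
  edges <- sort(unique(unlist(sets)))
  m <- length(edges)
  if (m > 20L) stop("oracle scale exceeded: ", m, " involved edges (max 20)")
  p <- network$edges$prob[edges]
  pos <- lapply(sets, function(s) match(s, edges))
  # state s (bit i set = edge i present) has probability prob_state[s + 1],
  # built edge by edge; a path is present when its mask is contained in s
  prob_state <- 1
  for (pe in p) prob_state <- c(prob_state * (1 - pe), prob_state * pe)
  states <- 0:(2^m - 1)
  covered <- rep(FALSE, 2^m)
  for (s in pos) {
    mask <- sum(bitwShiftL(1L, s - 1L))
    covered <- covered | (bitwAnd(states, mask) == mask)
  }
  sum(prob_state[covered])
}

#' Connectivity of a start gene within a sub-network
#'
#' The probability that the start gene remains connected to at least one
#' other list gene inside the sub-network: the exact union probability of
#' its retained paths after restriction to the sub-network's edges. Equals 0
#' when no retained path survives.
#'
#' @param paths Retained path records for one start gene (all starting at
#'   that gene).
#' @param subnetwork A `subnetwork` or integer vector of edge indices.
#' @param network The `prob_network`.
#' @return Probability in \[0, 1\].
#' @export
connectivity <- function(paths, subnetwork, network) {
  union_probability(restrict_paths(paths, subnetwork), network)
}
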