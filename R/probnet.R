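#' Fit the normal model of log fold changes
#'
#' Log fold changes across the experiment are modelled as draws from a single
#' normal distribution N(mu, sigma); a gene's evidence of differential
#' expression is then how far into the tails its value falls. The fit uses
#' all genes in the expression table (not only those present in the network)
#' with the sample (n-1) standard deviation.
#'
#' @param expression Named numeric vector of log fold changes, as returned by
#'   [read_expression()], with at least two distinct values.
#' @return An `expression_stats` object: list with `mu` and `sigma`.
#' @examples
#' fit_expression_stats(c(a = -1, b = 1, c = 0.5))
#' @export
fit_expression_stats <- function(expression) {
  vals <- as.numeric(expression)
  if (length(vals) < 2L) stop("need at least 2 expression values to fit")
  if (any(!is.finite(vals))) stop("non-finite log fold change in expression")
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate expression distribution: standard deviation is 0")
  }
  expression_stats(mean(vals), sigma)
}

#' Construct expression statistics directly
#'
#' Useful when mu and sigma are known (e.g. quoted summary statistics) rather
#' than refitted from data.
#'
#' @param mu Mean log fold change.
#' @param sigma Standard deviation of log fold changes; must be positive.
#' @return An `expression_stats` object.
#' @export
expression_stats <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("degenerate expression distribution: sigma must be > 0")
  structure(list(mu = mu, sigma = sigma), class = "expression_stats")
}

#' @export
print.expression_stats <- function(x, ...) {
  cat(sprintf("Normal model of log fold changes: mu = %.4g, sigma = %.4g\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Differential-expression score of a gene
#'
#' The score is the two-tailed evidence that a gene's log fold change `d` is
#' extreme under the fitted normal model: `|1 - 2 * Phi(d; mu, sigma)|`,
#' where Phi is the normal CDF. It equals 0 at `d = mu`, increases strictly
#' with `|d - mu|`, and tends to 1 for strongly differential genes. It is
#' equivalent to one minus the two-tailed normal p-value of the z-transformed
#' value, so it is invariant under affine rescaling of the expression data.
#'
#' @param d Numeric vector of log fold changes.
#' @param stats An `expression_stats` object.
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' s <- expression_stats(-0.036, 1.255)
#' gene_score(-2.80, s)
#' @export
gene_score <- function(d, stats) {
  stopifnot(inherits(stats, "expression_stats"))
  if (any(!is.finite(d))) stop("non-finite log fold change")
  abs(1 - 2 * stats::pnorm(d, mean = stats$mu, sd = stats$sigma))
}

#' Presence probability of an edge
#'
#' The probability that an interaction is (in)active in the assessed condition
#' is the product of the differential-expression scores of the genes at its
#' two endpoints. It is symmetric in its arguments and lies in \[0, 1\].
#'
#' @param score_a,score_b Endpoint scores in \[0, 1\] (vectorized).
#' @return Numeric vector of edge probabilities.
#' @export
edge_probability <- function(score_a, score_b) {
  if (any(score_a < 0 | score_a > 1 | score_b < 0 | score_b > 1,
          na.rm = FALSE) || anyNA(score_a) || anyNA(score_b)) {
    stop("scores must lie in [0, 1]")
  }
  score_a * score_b
}

#' Convert an interaction network into a probabilistic network
#'
#' Assigns every edge of the network a presence probability: the product of
#' the differential-expression scores ([gene_score()]) of its endpoints under
#' the normal model fitted to the expression table. Genes absent from the
#' expression table receive the uninformative score 0.5, so an edge between
#' two unmeasured genes has probability 0.25.
#'
#' @param network An `interaction_network` from [read_network()].
#' @param expression Named numeric vector of log fold changes.
#' @param stats Optional `expression_stats`; fitted from `expression` when
#'   omitted. Passing quoted summary statistics reproduces published worked
#'   examples exactly.
#' @return A `prob_network` object: the network plus `node_scores` (named
#'   numeric) and an edge `prob` column.
#' @export
build_probabilistic_network <- function(network, expression,
                                        stats = fit_expression_stats(expression)) {
  stopifnot(inherits(network, "interaction_network"))
  if (nrow(network$edges) == 0L) stop("network has no edges")
  measured <- intersect(network$nodes, names(expression))
  n_missing <- length(network$nodes) - length(measured)
  if (n_missing > 0L) {
    message(n_missing, " of ", length(network$nodes),
            " network genes have no expression value; score set to 0.5")
  }
  scores <- stats::setNames(rep(0.5, length(network$nodes)), network$nodes)
  scores[measured] <- gene_score(expression[measured], stats)
  edges <- network$edges
  edges$prob <- edge_probability(scores[edges$from], scores[edges$to])
  structure(
    list(nodes = network$nodes, edges = edges, node_scores = scores,
         stats = stats),
    class = c("prob_network", "interaction_network")
  )
}

#' @export
print.prob_network <- function(x, ...) {
  cat("Probabilistic interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat(sprintf("Edge presence probability: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$edges$prob), min(x$edges$prob),
              max(x$edges$prob)))
  invisible(x)
}

#' Construct a sub-network
#'
#' A sub-network is an edge subset of a probabilistic network; it is the unit
#' the optimizer scores and the object written out by [write_sif()] and
#' [write_result_json()].
#'
#' @param network A `prob_network`.
#' @param edge_idx Integer indices into `network$edges` (deduplicated,
#'   stored sorted).
#' @return A `subnetwork` object: the selected edge table plus the index set.
#' @export
subnetwork <- function(network, edge_idx = integer(0)) {
  stopifnot(inherits(network, "prob_network"))
  edge_idx <- sort(unique(as.integer(edge_idx)))
  if (length(edge_idx) &&
      (min(edge_idx) < 1L || max(edge_idx) > nrow(network$edges))) {
    stop("edge index out of range for this network")
  }
  structure(
    list(edges = network$edges[edge_idx, , drop = FALSE], idx = edge_idx),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Sub-network:", nrow(x$edges), "edges,",
      length(unique(c(x$edges$from, x$edges$to))), "nodes\n")
  invisible(x)
}

# Edge table of a subnetwork-like object (subnetwork, subnet_fit, or a bare
# edge data frame with from/to/type columns).
subnetwork_edges <- function(x) {
  if (inherits(x, "subnet_fit")) x <- x$subnetwork
  if (inherits(x, "subnetwork")) return(x$edges)
  if (is.data.frame(x)) {
    stopifnot(all(c("from", "to", "type") %in% names(x)))
    if (is.null(x$directed)) x$directed <- NA
    return(x)
  }
  stop("expected a subnetwork, subnet_fit or edge data frame")
}
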