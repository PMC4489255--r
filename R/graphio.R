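#' Read a typed interaction network
#'
#' Parses a tab-delimited interaction network file into an
#' `interaction_network` object. Each non-comment line must have four
#' tab-separated fields: source node, target node, interaction type and a
#' directedness flag (`1` directed, `0` undirected). Lines starting with `#`
#' and blank lines are skipped.
#'
#' Interactomes are mixed graphs: nodes are biological entities (genes,
#' proteins, RNAs) and each edge carries the molecular layer it belongs to
#' (e.g. `"pd"` protein-DNA, `"pp"` protein-protein, `"met"` metabolic,
#' `"srna"` small RNA). Directedness is stored per edge because it depends on
#' both the interaction type and the available evidence.
#'
#' Duplicate (source, target, type) triples are collapsed to one edge with a
#' warning; parallel edges that differ in type are kept, as they represent
#' distinct molecular layers. Self-loops are dropped with a warning: paths are
#' acyclic by definition, so a self-loop can never participate in one.
#'
#' @param path Path to a 4-column tab-separated network file.
#' @return An object of class `interaction_network`: a list with elements
#'   `nodes` (character vector) and `edges` (data frame with columns `from`,
#'   `to`, `type`, `directed`).
#' @seealso [write_network()], [build_probabilistic_network()]
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\tpd\t1", "B\tC\tpp\t0"), f)
#' net <- read_network(f)
#' net$edges
#' @export
read_network <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no edges: network file '", path, "' contains no data lines")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1L]
    stop("malformed network line ", lineno[bad], ": expected 4 tab-separated ",
         "fields (source, target, type, directed), got ", nf[bad])
  }
  m <- matrix(trimws(unlist(fields)), ncol = 4L, byrow = TRUE)
  if (any(m[, 1L] == "" | m[, 2L] == "" | m[, 3L] == "")) {
    bad <- which(m[, 1L] == "" | m[, 2L] == "" | m[, 3L] == "")[1L]
    stop("malformed network line ", lineno[bad], ": empty field")
  }
  if (!all(m[, 4L] %in% c("0", "1"))) {
    bad <- which(!m[, 4L] %in% c("0", "1"))[1L]
    stop("malformed network line ", lineno[bad],
         ": directed flag must be 0 or 1, got '", m[bad, 4L], "'")
  }
  edges <- data.frame(
    from = m[, 1L], to = m[, 2L], type = m[, 3L],
    directed = m[, 4L] == "1",
    stringsAsFactors = FALSE
  )
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) rejected (paths are acyclic)")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no edges: all lines were self-loops")
  key <- paste(edges$from, edges$to, edges$type, sep = "\t")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate edge triple(s) collapsed to single edges")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  new_interaction_network(edges)
}

#' @keywords internal
new_interaction_network <- function(edges) {
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges),
    class = "interaction_network"
  )
}

#' Write a typed interaction network
#'
#' Inverse of [read_network()]: writes one `source<TAB>target<TAB>type<TAB>flag`
#' line per edge, in the network's stored edge order.
#'
#' @param network An `interaction_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  writeLines(paste(e$from, e$to, e$type, as.integer(e$directed), sep = "\t"),
             path)
  invisible(path)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  tab <- table(x$edges$type, ifelse(x$edges$directed, "directed", "undirected"))
  print(tab)
  invisible(x)
}

#' Read a differential-expression table
#'
#' Parses a 2-column tab-separated file of gene identifier and log fold
#' change (log2 scale) into a named numeric vector. A single header line is
#' tolerated (detected by a non-numeric second field on the first line).
#' If a gene appears more than once the later value overwrites the earlier
#' one with a warning.
#'
#' @param path Path to the expression file.
#' @return Named numeric vector of log fold changes, one entry per gene.
#' @examples
#' f <- tempfile()
#' writeLines(c("nhaA\t-2.80", "nhaR\t-2.00"), f)
#' read_expression(f)
#' @export
read_expression <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty expression file '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("malformed expression line ", lineno[bad],
         ": expected 2 tab-separated fields")
  }
  genes <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
  raw <- vapply(fields, function(f) trimws(f[[2L]]), character(1))
  vals <- suppressWarnings(as.numeric(raw))
  # header tolerance: first line only, non-numeric second field
  if (is.na(vals[1L]) && length(vals) > 1L) {
    genes <- genes[-1L]; raw <- raw[-1L]; vals <- vals[-1L]
    lineno <- lineno[-1L]
  }
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop("non-numeric log fold change '", raw[bad[1L]],
         "' on expression line ", lineno[bad[1L]])
  }
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)),
            " duplicate gene id(s) in expression table; later values kept")
    keep <- !duplicated(genes, fromLast = TRUE)
    genes <- genes[keep]; vals <- vals[keep]
  }
  stats::setNames(vals, genes)
}

#' Read a gene list
#'
#' One gene identifier per line; duplicates are removed preserving first
#' occurrence order, blank and whitespace-only lines are skipped. Gene
#' identifiers are treated as case-sensitive exact strings; no symbol mapping
#' is attempted.
#'
#' @param path Path to the gene-list file.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list '", path, "'")
  unique(lines)
}

#' Write a sub-network in SIF format
#'
#' Writes the Cytoscape Simple Interaction Format: one
#' `source<TAB>type<TAB>target` line per edge, in deterministic lexicographic
#' order. An empty sub-network yields a valid empty file.
#'
#' @param subnetwork A `subnetwork` object (see [subnetwork()]), or a
#'   `subnet_fit` from [infer_subnetwork()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(subnetwork, path) {
  e <- subnetwork_edges(subnetwork)
  lines <- if (nrow(e)) sort(paste(e$from, e$type, e$to, sep = "\t")) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write an inferred sub-network as JSON
#'
#' Serializes the sub-network together with per-node scores and log fold
#' changes and per-edge presence probabilities, for downstream visualization.
#' The structure round-trips through [read_result_json()].
#'
#' @param subnetwork A `subnetwork` object or a `subnet_fit`.
#' @param node_scores Named numeric vector of node scores covering every node
#'   of the sub-network (taken from the fit when a `subnet_fit` is given).
#' @param lfc Named numeric vector of log fold changes; nodes missing from it
#'   are recorded with `NA`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(subnetwork, node_scores = NULL, lfc = NULL,
                              path) {
  if (inherits(subnetwork, "subnet_fit")) {
    if (is.null(node_scores)) node_scores <- subnetwork$network$node_scores
    if (is.null(lfc)) lfc <- subnetwork$expression
    subnetwork <- subnetwork$subnetwork
  }
  e <- subnetwork_edges(subnetwork)
  nodes <- sort(unique(c(e$from, e$to, attr(subnetwork, "extra_nodes"))))
  if (is.null(node_scores)) node_scores <- numeric(0)
  missing_scores <- setdiff(nodes, names(node_scores))
  if (length(missing_scores)) {
    stop("missing node score(s) for: ", paste(missing_scores, collapse = ", "))
  }
  node_df <- data.frame(
    id = nodes,
    score = as.numeric(node_scores[nodes]),
    lfc = if (is.null(lfc)) rep(NA_real_, length(nodes))
          else as.numeric(lfc[nodes]),
    stringsAsFactors = FALSE
  )
  edge_df <- data.frame(
    source = e$from, target = e$to, type = e$type, directed = e$directed,
    probability = if (is.null(e$prob)) rep(NA_real_, nrow(e)) else e$prob,
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(list(nodes = node_df, edges = edge_df), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read back a JSON result file
#'
#' @param path Path written by [write_result_json()].
#' @return List with `nodes` and `edges` data frames.
#' @export
read_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$nodes) == 0L) {
    x$nodes <- data.frame(id = character(0), score = numeric(0),
                          lfc = numeric(0))
  }
  if (length(x$edges) == 0L) {
    x$edges <- data.frame(source = character(0), target = character(0),
                          type = character(0), directed = logical(0),
                          probability = numeric(0))
  }
  x
}

# readLines with explicit encoding; keeps warnings about missing final EOL out
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  readLines(path, warn = FALSE, encoding = "UTF-8")
}
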