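#' Read a GAF 2.x annotation file
#'
#' Parses a Gene Ontology Annotation File into a term -> gene-set map.
#' Lines starting with `!` are comments. Data lines must have at least 15
#' tab-separated columns; the gene symbol is taken from column 3 and the
#' term identifier from column 5. Rows whose qualifier (column 4) contains
#' `NOT` are skipped, as they assert the absence of an annotation.
#'
#' @param path Path to the GAF file.
#' @return An `annotation_map`: list with `terms` (named list of character
#'   gene sets) and `names` (named character vector of term names, taken
#'   from column 10 when informative).
#' @export
read_gaf <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*(!|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("GAF file contains no annotation rows")
    return(structure(list(terms = list(), names = character(0)),
                     class = "annotation_map"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L)) {
    bad <- which(nf < 15L)[1L]
    stop("malformed GAF line ", lineno[bad], ": expected >= 15 columns, got ",
         nf[bad])
  }
  gene <- vapply(fields, `[[`, character(1), 3L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  name <- vapply(fields, `[[`, character(1), 10L)
  drop <- grepl("(^|\\|)NOT(\\||$)", qualifier)
  gene <- gene[!drop]; term <- term[!drop]; name <- name[!drop]
  if (length(gene) == 0L) {
    warning("all GAF rows carry a NOT qualifier; no annotations retained")
    return(structure(list(terms = list(), names = character(0)),
                     class = "annotation_map"))
  }
  terms <- lapply(split(gene, term), function(g) sort(unique(g)))
  term_names <- vapply(split(name, term), `[[`, character(1), 1L)
  structure(list(terms = terms, names = term_names),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", length(x$terms), "terms,",
      length(unique(unlist(x$terms))), "annotated genes\n")
  invisible(x)
}

#' Hypergeometric term enrichment of a sub-network
#'
#' Tests every annotation term represented in the sub-network for
#' overrepresentation against the background gene universe, using the
#' hypergeometric upper tail P(X >= k) where k genes of the n-gene
#' sub-network carry the term, K genes of the N-gene background carry it.
#' Terms with no sub-network gene are not reported. Raw p-values are
#' corrected with Benjamini-Hochberg across all tested terms.
#'
#' The background defaults to all genes of the loaded interaction network:
#' the sub-network is drawn from the network, so the network is the sampling
#' frame. Annotations are used as given; no ontology-graph propagation is
#' performed.
#'
#' @param subnetwork_genes Character vector of sub-network gene identifiers
#'   (must be contained in `background`).
#' @param background Character vector: the gene universe.
#' @param annotations An `annotation_map` from [read_gaf()].
#' @return Data frame with columns `term`, `name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, sorted by increasing p-value.
#' @export
enrich_terms <- function(subnetwork_genes, background, annotations) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background gene universe")
  subnetwork_genes <- unique(subnetwork_genes)
  if (!all(subnetwork_genes %in% background)) {
    stop("sub-network genes must be a subset of the background")
  }
  N <- length(background)
  n <- length(subnetwork_genes)
  rows <- lapply(names(annotations$terms), function(t) {
    members <- intersect(annotations$terms[[t]], background)
    K <- length(members)
    k <- length(intersect(members, subnetwork_genes))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    nm <- annotations$names[[t]]
    data.frame(term = t, name = if (is.null(nm) || is.na(nm)) "" else nm,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param enrichment Data frame from [enrich_terms()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
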