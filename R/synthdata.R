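#' Specification of a synthetic inference scenario
#'
#' Defines a self-contained synthetic data set emulating the inputs of a
#' sub-network inference run: a mixed typed interactome with planted
#' regulator hubs, a differential-expression table in which the planted
#' regulators' targets are strongly differential, a gene list selected by an
#' absolute log-fold-change cutoff, and a small annotation file grouping
#' each regulon into a term.
#'
#' Defaults describe the reference scenario used throughout the test suite:
#' 200 genes, 2 planted regulators with 20 targets each, target effect size
#' 3.0 (in absolute log2 fold change, sign alternating per regulator) over
#' unit background noise, and a gene list of all genes with |log fold
#' change| above 1.5. The background interactome is an Erdos-Renyi-style
#' mixed graph of 120 protein-DNA, 160 protein-protein and 60 metabolic
#' edges (average degree about 3.8), over which the planted
#' regulator-to-target protein-DNA edges are laid.
#'
#' @param n_genes Number of genes.
#' @param n_regulators Number of planted regulator hubs.
#' @param targets_per_regulator Targets wired to each regulator.
#' @param effect_size Mean |log2 fold change| of planted targets; > 0.
#' @param noise_sd Standard deviation of all log fold changes; > 0.
#' @param n_pd,n_pp,n_met Background edge counts per interaction type
#'   (protein-DNA directed, protein-protein undirected, metabolic directed).
#' @param lfc_cutoff Absolute log-fold-change threshold for gene-list
#'   membership.
#' @param seed Integer seed fixing all randomness of the scenario.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(n_genes = 200L, n_regulators = 2L,
                          targets_per_regulator = 20L, effect_size = 3,
                          noise_sd = 1, n_pd = 120L, n_pp = 160L,
                          n_met = 60L, lfc_cutoff = 1.5, seed = 1L) {
  spec <- structure(
    list(n_genes = as.integer(n_genes),
         n_regulators = as.integer(n_regulators),
         targets_per_regulator = as.integer(targets_per_regulator),
         effect_size = effect_size, noise_sd = noise_sd,
         n_pd = as.integer(n_pd), n_pp = as.integer(n_pp),
         n_met = as.integer(n_met), lfc_cutoff = lfc_cutoff,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
  counts <- with(spec, c(n_genes, n_regulators, targets_per_regulator,
                         n_pd, n_pp, n_met))
  if (any(counts <= 0L)) stop("all scenario counts must be positive")
  if (spec$effect_size <= 0) stop("effect_size must be > 0")
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0")
  if (spec$lfc_cutoff <= 0) stop("lfc_cutoff must be > 0")
  needed <- spec$n_regulators * (1L + spec$targets_per_regulator)
  if (needed > spec$n_genes) {
    stop("infeasible scenario: ", needed, " regulator/target genes but only ",
         spec$n_genes, " genes")
  }
  max_pairs <- spec$n_genes * (spec$n_genes - 1L)
  if (spec$n_pd + spec$n_met > max_pairs || spec$n_pp > max_pairs %/% 2L) {
    stop("infeasible scenario: more edges requested than node pairs")
  }
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d genes, %d regulators x %d targets, effect %.2g,",
    x$n_genes, x$n_regulators, x$targets_per_regulator, x$effect_size),
    sprintf("noise %.2g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic scenario bundle
#'
#' Builds the scenario described by a [scenario_spec()] and writes its four
#' files in the package's standard formats: `network.tsv` (4-column typed
#' network), `expression.tsv` (gene, log fold change), `genelist.txt` (one
#' gene per line) and `annotations.gaf` (GAF 2.2 with one term per planted
#' regulon). Fully reproducible: the same spec (including seed) yields
#' byte-identical files. The caller's random-number state is preserved.
#'
#' Planted structure: each regulator gains directed protein-DNA edges to its
#' targets; target log fold changes are drawn from Normal(s * effect,
#' noise) with the sign s alternating per regulator, background genes from
#' Normal(0, noise). The gene list collects all genes whose |log fold
#' change| exceeds the cutoff, so with the default effect/noise/cutoff most
#' planted targets (and some background genes) are listed.
#'
#' @param spec A `scenario_spec`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the four file `paths`, the ground `truth`
#'   (`regulators`, `targets` per regulator, `lfc`) and the `spec`.
#' @export
generate_scenario <- function(spec = scenario_spec(), dir = tempfile("scenario")) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  regulators <- sample(genes, spec$n_regulators)
  pool <- setdiff(genes, regulators)
  targets <- list()
  for (i in seq_len(spec$n_regulators)) {
    targets[[regulators[i]]] <- sample(pool, spec$targets_per_regulator)
    pool <- setdiff(pool, targets[[regulators[i]]])
  }

  planted <- do.call(rbind, lapply(regulators, function(r) {
    data.frame(from = r, to = targets[[r]], type = "pd", directed = TRUE,
               stringsAsFactors = FALSE)
  }))

  sample_edges <- function(n, type, directed) {
    # rejection-sample distinct ordered pairs without self loops
    out <- data.frame(from = character(0), to = character(0))
    while (nrow(out) < n) {
      need <- 2L * (n - nrow(out)) + 8L
      cand <- data.frame(from = sample(genes, need, replace = TRUE),
                         to = sample(genes, need, replace = TRUE),
                         stringsAsFactors = FALSE)
      cand <- cand[cand$from != cand$to, , drop = FALSE]
      out <- rbind(out, cand)
      key <- if (directed) paste(out$from, out$to)
             else paste(pmin(out$from, out$to), pmax(out$from, out$to))
      out <- out[!duplicated(key), , drop = FALSE]
    }
    out <- out[seq_len(n), , drop = FALSE]
    out$type <- type
    out$directed <- directed
    out
  }
  bg <- rbind(sample_edges(spec$n_pd, "pd", TRUE),
              sample_edges(spec$n_pp, "pp", FALSE),
              sample_edges(spec$n_met, "met", TRUE))
  edges <- rbind(planted, bg)
  key <- paste(edges$from, edges$to, edges$type, sep = "\t")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL

  lfc <- stats::rnorm(spec$n_genes, 0, spec$noise_sd)
  names(lfc) <- genes
  for (i in seq_len(spec$n_regulators)) {
    sgn <- if (i %% 2L == 1L) 1 else -1
    tg <- targets[[regulators[i]]]
    lfc[tg] <- stats::rnorm(length(tg), sgn * spec$effect_size, spec$noise_sd)
  }
  gene_list <- genes[abs(lfc) > spec$lfc_cutoff]
  if (length(gene_list) == 0L) {
    stop("scenario produced an empty gene list; raise effect_size or lower ",
         "lfc_cutoff")
  }

  paths <- list(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    genelist = file.path(dir, "genelist.txt"),
    gaf = file.path(dir, "annotations.gaf")
  )
  writeLines(paste(edges$from, edges$to, edges$type,
                   as.integer(edges$directed), sep = "\t"), paths$network)
  writeLines(paste(genes, sprintf("%.6f", lfc), sep = "\t"),
             paths$expression)
  writeLines(gene_list, paths$genelist)
  writeLines(make_gaf_lines(regulators, targets), paths$gaf)

  invisible(list(paths = paths,
                 truth = list(regulators = regulators, targets = targets,
                              lfc = lfc, gene_list = gene_list),
                 spec = spec))
}

# GAF 2.2 lines: one synthetic term per planted regulon covering the
# regulator and its targets.
make_gaf_lines <- function(regulators, targets) {
  header <- "!gaf-version: 2.2"
  rows <- unlist(lapply(seq_along(regulators), function(i) {
    r <- regulators[i]
    term <- sprintf("GO:%07d", i)
    members <- c(r, targets[[r]])
    vapply(members, function(g) {
      paste("SYNTH", g, g, "involved_in", term, "SYNTH:0001", "IEA", "",
            "P", sprintf("regulon of %s (synthetic)", r), "", "protein",
            "taxon:0", "20260101", "SYNTH", sep = "\t")
    }, character(1))
  }), use.names = FALSE)
  c(header, rows)
}
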