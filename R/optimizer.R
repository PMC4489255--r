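#' Objective value of a candidate sub-network
#'
#' The score of a sub-network S trades off connectivity against size:
#' the sum over start genes of the probability that the gene stays connected
#' to another list gene within S, minus a constant cost per selected edge.
#' The connectivity term lies in \[0, |L|\] for a gene list L; the penalty is
#' `cost * |S|` in edges.
#'
#' @param subnetwork A `subnetwork`, or an integer vector of edge indices.
#' @param pathset A `path_set` from [k_best_paths()], computed on the same
#'   probabilistic network.
#' @param network The `prob_network`.
#' @param config A `run_config` (supplies the cost).
#' @return An `objective_value`: list with `connectivity_term`,
#'   `penalty_term` and `total`.
#' @export
subnet_objective <- function(subnetwork, pathset, network, config) {
  config <- validate_config(config)
  idx <- if (inherits(subnetwork, "subnetwork")) subnetwork$idx
         else sort(unique(as.integer(subnetwork)))
  conn <- sum(vapply(pathset$paths, function(p) {
    connectivity(p, idx, network)
  }, numeric(1)))
  penalty <- config$cost * length(idx)
  structure(
    list(connectivity_term = conn, penalty_term = penalty,
         total = conn - penalty),
    class = "objective_value"
  )
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("Objective: %.6g (connectivity %.6g - penalty %.6g)\n",
              x$total, x$connectivity_term, x$penalty_term))
  invisible(x)
}

# Gains below this are treated as zero so floating-point noise cannot make
# the climber cycle.
GAIN_TOL <- 1e-12

#' Greedy hill-climbing selection of the optimal sub-network
#'
#' Maximizes the objective by hill climbing from the empty edge set over the
#' candidate universe U, the union of edges appearing on any retained path
#' (edges on no retained path can only add penalty without connectivity, so
#' excluding them is lossless). Each iteration evaluates all single-edge
#' additions from U and removals from the current set and applies the move
#' with the largest strictly positive gain (ties broken toward additions and
#' then by the lexicographically smallest edge). Because the shortest path
#' has two edges, a single addition from the empty set can never complete a
#' path; when no single-edge move improves, the climber therefore also
#' considers adding all missing edges of one retained path at once, and
#' stops only when no single-edge and no whole-path move has positive gain.
#'
#' The returned sub-network is a local optimum: no single-edge addition or
#' removal (nor any whole-path addition) strictly improves its objective.
#' Its objective is always nonnegative since the empty set scores zero.
#'
#' @inheritParams subnet_objective
#' @return An `optimization_result`: list with `subnetwork`, `objective`,
#'   `trace` (data frame of applied moves), `universe` (candidate edge
#'   indices) and `config`.
#' @export
greedy_optimize <- function(pathset, network, config) {
  config <- validate_config(config)
  stopifnot(inherits(pathset, "path_set"))
  cost <- config$cost
  probs <- network$edges$prob
  edge_keys <- paste(network$edges$from, network$edges$to,
                     network$edges$type, sep = "\t")

  genes <- pathset$genes
  # flat path table over all start genes
  path_sets <- unlist(lapply(pathset$paths, function(pl) {
    lapply(pl, function(p) sort(unique(p$edges)))
  }), recursive = FALSE, use.names = FALSE)
  path_gene <- rep(genes, vapply(pathset$paths, length, integer(1)))
  n_paths <- length(path_sets)
  universe <- sort(unique(unlist(path_sets, use.names = FALSE)))
  trace <- list()
  if (length(universe) == 0L) {
    warning("no retained paths: candidate edge universe is empty")
    return(finish_result(integer(0), pathset, network, config, trace,
                         universe))
  }

  # incidence maps: edge -> path ids (env keyed by edge index), gene -> ids
  pid_by_edge <- new.env(hash = TRUE, parent = emptyenv())
  flat_edges <- unlist(path_sets, use.names = FALSE)
  flat_pid <- rep.int(seq_len(n_paths), lengths(path_sets))
  grp_by_edge <- split(flat_pid, flat_edges)
  for (k in names(grp_by_edge)) assign(k, grp_by_edge[[k]], envir = pid_by_edge)
  paths_of_edge <- function(e) pid_by_edge[[as.character(e)]]

  n_edges <- nrow(network$edges)
  inS <- rep(FALSE, n_edges)
  # per-path count of edges still missing from S; survivors have miss == 0
  miss <- lengths(path_sets)
  surv_by_gene <- stats::setNames(
    replicate(length(genes), integer(0), simplify = FALSE), genes)
  conn <- stats::setNames(numeric(length(genes)), genes)

  union_of <- function(ids) {
    if (length(ids) == 0L) return(0)
    union_prob_sets(path_sets[ids], probs)
  }

  # per-gene memo of connectivity deltas, keyed by the (small) set of paths
  # whose survival the move changes; reset when the gene is touched
  delta_envs <- stats::setNames(
    replicate(length(genes), new.env(hash = TRUE, parent = emptyenv()),
              simplify = FALSE), genes)
  gene_delta <- function(g, grp, adding) {
    env <- delta_envs[[g]]
    key <- paste(if (adding) "+" else "-", paste(grp, collapse = ","))
    val <- env[[key]]
    if (is.null(val)) {
      ids2 <- if (adding) c(surv_by_gene[[g]], grp)
              else setdiff(surv_by_gene[[g]], grp)
      val <- union_of(ids2) - conn[[g]]
      assign(key, val, envir = env)
    }
    val
  }

  # gain of toggling one edge
  eval_edge <- function(e) {
    adding <- !inS[e]
    pids <- paths_of_edge(e)
    if (adding) {
      changed <- pids[miss[pids] == 1L]
      base_gain <- -cost
    } else {
      changed <- pids[miss[pids] == 0L]
      base_gain <- cost
    }
    if (length(changed) == 0L) return(base_gain)
    delta <- 0
    for (grp in split(changed, path_gene[changed])) {
      g <- path_gene[grp[1L]]
      if (adding && conn[[g]] >= 1 - 1e-13) next  # no headroom left
      delta <- delta + gene_delta(g, grp, adding)
    }
    base_gain + delta
  }

  # gain of adding all missing edges of candidate path set s; a path
  # survives in S + new iff all of its missing edges lie in new, i.e. its
  # count of edges in new equals its miss count
  eval_path <- function(s) {
    new <- s[!inS[s]]
    hits <- tabulate(unlist(lapply(new, paths_of_edge), use.names = FALSE),
                     nbins = n_paths)
    newly <- which(hits > 0L & hits == miss)
    if (length(newly) == 0L) {
      return(list(gain = -cost * length(new), new = new))
    }
    delta <- 0
    for (grp in split(newly, path_gene[newly])) {
      g <- path_gene[grp[1L]]
      if (conn[[g]] >= 1 - 1e-13) next
      delta <- delta + gene_delta(g, grp, TRUE)
    }
    list(gain = delta - cost * length(new), new = new)
  }

  apply_change <- function(edges_on = integer(0), edges_off = integer(0)) {
    for (e in edges_on) {
      inS[e] <<- TRUE
      pids <- paths_of_edge(e)
      miss[pids] <<- miss[pids] - 1L
      done <- pids[miss[pids] == 0L]
      for (p in done) {
        g <- path_gene[p]
        surv_by_gene[[g]] <<- sort(c(surv_by_gene[[g]], p))
      }
    }
    for (e in edges_off) {
      inS[e] <<- FALSE
      pids <- paths_of_edge(e)
      lost <- pids[miss[pids] == 0L]
      miss[pids] <<- miss[pids] + 1L
      for (p in lost) {
        g <- path_gene[p]
        surv_by_gene[[g]] <<- setdiff(surv_by_gene[[g]], p)
      }
    }
    touched <- unique(path_gene[unlist(lapply(c(edges_on, edges_off),
                                              paths_of_edge),
                                       use.names = FALSE)])
    for (g in touched) {
      conn[g] <<- union_of(surv_by_gene[[g]])
      delta_envs[[g]] <<- new.env(hash = TRUE, parent = emptyenv())
    }
    touched
  }

  # unique candidate path edge sets for the escape move, in a stable order
  set_keys <- vapply(path_sets, paste, character(1), collapse = ",")
  cand_sets <- path_sets[!duplicated(set_keys)]
  cand_keys <- vapply(cand_sets, function(s) {
    paste(edge_keys[s], collapse = "\x1f")
  }, character(1))
  o <- order(cand_keys, method = "radix")
  cand_sets <- cand_sets[o]; cand_keys <- cand_keys[o]
  cand_genes <- lapply(cand_sets, function(s) {
    unique(path_gene[unique(unlist(lapply(s, paths_of_edge),
                                   use.names = FALSE))])
  })
  path_gain_cache <- rep(NA_real_, length(cand_sets))

  # cached single-edge gains, invalidated when a move touches a gene whose
  # retained paths use the edge (a move can only change an edge's gain
  # through the miss counts of its paths or the connectivity of their start
  # genes, and both imply a touched gene)
  gain_cache <- stats::setNames(rep(NA_real_, length(universe)),
                                as.character(universe))
  genes_by_edge <- lapply(universe, function(e) {
    unique(path_gene[paths_of_edge(e)])
  })
  names(genes_by_edge) <- as.character(universe)
  invalidate <- function(touched) {
    stale <- vapply(genes_by_edge, function(gs) any(gs %in% touched),
                    logical(1))
    gain_cache[stale] <<- NA_real_
    stale_p <- vapply(cand_genes, function(gs) any(gs %in% touched),
                      logical(1))
    path_gain_cache[stale_p] <<- NA_real_
  }

  best_edge_move <- function() {
    best <- list(gain = GAIN_TOL, kind = "", edges = integer(0), key = "")
    for (i in seq_along(universe)) {
      e <- universe[i]
      gain <- gain_cache[[i]]
      if (is.na(gain)) {
        gain <- eval_edge(e)
        gain_cache[[i]] <<- gain
      }
      kind <- if (inS[e]) "drop" else "add"
      if (gain > best$gain + GAIN_TOL ||
          (gain > best$gain - GAIN_TOL &&
           better_tie(kind, edge_keys[e], best))) {
        best <- list(gain = gain, kind = kind, edges = e,
                     key = edge_keys[e])
      }
    }
    best
  }

  best_path_move <- function() {
    best <- list(gain = GAIN_TOL, kind = "", edges = integer(0), key = "")
    for (i in seq_along(cand_sets)) {
      s <- cand_sets[[i]]
      n_new <- sum(!inS[s])
      if (n_new == 0L) next
      gain <- path_gain_cache[i]
      if (is.na(gain)) {
        # headroom bound: affected genes gain at most their distance to 1
        if (sum(1 - conn[cand_genes[[i]]]) <= cost * n_new + GAIN_TOL) {
          path_gain_cache[i] <<- -Inf
          next
        }
        ev <- eval_path(s)
        gain <- ev$gain
        path_gain_cache[i] <<- gain
      } else if (gain <= best$gain - GAIN_TOL) {
        next
      }
      if (gain > best$gain + GAIN_TOL ||
          (gain > best$gain - GAIN_TOL &&
           better_tie("path", cand_keys[i], best))) {
        best <- list(gain = gain, kind = "path",
                     edges = {ss <- cand_sets[[i]]; ss[!inS[ss]]},
                     key = cand_keys[i])
      }
    }
    best
  }

  step <- 0L
  repeat {
    mv <- best_edge_move()
    if (mv$kind == "") mv <- best_path_move()
    if (mv$kind == "") break
    touched <- if (mv$kind == "drop") apply_change(edges_off = mv$edges)
               else apply_change(edges_on = mv$edges)
    invalidate(touched)
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, kind = mv$kind, n_edges_changed = length(mv$edges),
      edges = paste(gsub("\t", ":", edge_keys[mv$edges]), collapse = ";"),
      gain = mv$gain,
      connectivity = sum(conn), size = sum(inS),
      stringsAsFactors = FALSE
    )
  }
  finish_result(which(inS), pathset, network, config, trace, universe)
}

# Deterministic tie rule: additions before removals before path moves, then
# lexicographically smallest edge/path key. Only compares moves that already
# cleared the strict-positivity threshold (best$kind nonempty).
better_tie <- function(kind, key, best) {
  rank <- c(add = 1L, drop = 2L, path = 3L)
  if (best$kind == "") return(FALSE)
  if (rank[[kind]] != rank[[best$kind]]) return(rank[[kind]] < rank[[best$kind]])
  key < best$key
}

finish_result <- function(idx, pathset, network, config, trace, universe) {
  obj <- subnet_objective(idx, pathset, network, config)
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), kind = character(0),
               n_edges_changed = integer(0), edges = character(0),
               gain = numeric(0), connectivity = numeric(0),
               size = integer(0), stringsAsFactors = FALSE)
  structure(
    list(subnetwork = subnetwork(network, idx), objective = obj,
         trace = trace_df, universe = universe, config = config),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Greedy sub-network selection:", length(x$subnetwork$idx), "edges of",
      length(x$universe), "candidates after", nrow(x$trace), "moves\n")
  print(x$objective)
  invisible(x)
}

#' Verify local optimality of an optimization result
#'
#' Recomputes, by full objective evaluation, the gain of every single-edge
#' addition (from the candidate universe) and removal at the returned
#' sub-network. Returns `TRUE` when none is strictly positive.
#'
#' @param result An `optimization_result`.
#' @param pathset,network The inputs the result was computed from.
#' @return Logical.
#' @export
is_local_optimum <- function(result, pathset, network) {
  config <- result$config
  idx <- result$subnetwork$idx
  base <- subnet_objective(idx, pathset, network, config)$total
  for (e in result$universe) {
    trial <- if (e %in% idx) setdiff(idx, e) else c(idx, e)
    if (subnet_objective(trial, pathset, network, config)$total >
        base + GAIN_TOL) {
      return(FALSE)
    }
  }
  TRUE
}

#' Exhaustive sub-network search (reference implementation)
#'
#' Evaluates the objective of every subset of the candidate edge universe
#' and returns a global optimum. Exponential in the universe size; refuses
#' more than 20 candidate edges. Used to measure the optimality gap of the
#' greedy search on toy instances.
#'
#' @inheritParams subnet_objective
#' @param pathset A `path_set`.
#' @return List with `idx` (optimal edge indices), `objective` and
#'   `n_subsets` evaluated.
#' @export
exhaustive_optimize <- function(pathset, network, config) {
  config <- validate_config(config)
  universe <- sort(unique(unlist(lapply(pathset$paths, function(pl) {
    lapply(pl, `[[`, "edges")
  }), use.names = FALSE)))
  m <- length(universe)
  if (m > 20L) stop("exhaustive search refused: ", m, " candidate edges")
  best_idx <- integer(0)
  best <- 0
  n_sub <- 2^m
  for (mask in 0:(n_sub - 1)) {
    sel <- universe[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
    val <- subnet_objective(sel, pathset, network, config)$total
    if (val > best + GAIN_TOL) {
      best <- val
      best_idx <- sel
    }
  }
  list(idx = best_idx,
       objective = subnet_objective(best_idx, pathset, network, config),
       n_subsets = n_sub)
}

#' Sweep the sparsity cost
#'
#' Runs independent greedy optimizations for a strictly decreasing series of
#' costs. Decreasing the cost grows the inferred sub-network, giving an
#' ordered series from the sparsest core outward.
#'
#' @inheritParams subnet_objective
#' @param pathset A `path_set`.
#' @param costs Strictly decreasing vector of nonnegative costs.
#' @return List of `optimization_result`, one per cost, with an
#'   `edge_counts` attribute.
#' @export
cost_sweep <- function(pathset, network, config, costs) {
  if (length(costs) == 0L) stop("empty cost list")
  if (any(diff(costs) >= 0)) stop("costs must be strictly decreasing")
  if (any(costs < 0)) stop("costs must be nonnegative")
  res <- lapply(costs, function(xc) {
    cfg <- config
    cfg$cost <- xc
    greedy_optimize(pathset, network, validate_config(cfg))
  })
  attr(res, "edge_counts") <- vapply(res, function(r) {
    length(r$subnetwork$idx)
  }, integer(1))
  attr(res, "costs") <- costs
  res
}
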