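test_that("config validation fills defaults and enforces ranges", {
  cfg <- validate_config(list(mode = "upstream", cost = 0.01))
  expect_equal(cfg$max_path_length, 4L)
  expect_equal(cfg$k, 10L)
  expect_setequal(cfg$regulatory_types, c("pd", "srna"))

  expect_error(run_config("upstream", 0.01, max_path_length = 6),
               "\\[2, 5\\]")
  expect_error(run_config("upstream", 0.01, max_path_length = 1),
               "\\[2, 5\\]")
  expect_error(run_config("downstream", 0.01, k = 4), "\\[5, 50\\]")
  expect_error(run_config("downstream", 0.01, k = 51), "\\[5, 50\\]")
  # inclusive boundaries
  expect_equal(run_config("downstream", 0, k = 5)$k, 5L)
  expect_equal(run_config("downstream", 0, k = 50)$k, 50L)
  expect_equal(run_config("downstream", 0, max_path_length = 2)$max_path_length, 2L)
  expect_error(run_config("sideways", 0.01), "mode")
  expect_error(run_config("upstream", -1), "cost")
  expect_error(run_config("upstream", 0.01, regulatory_types = character(0)),
               "regulatory")
})

test_that("path validity implements both run-mode definitions", {
  # A <-pd- R -pd-> Y plus a pp detour
  pnet <- toy_pnet(toy_edges(list("R", "A", "pd", 1), list("R", "Y", "pd", 1),
                             list("A", "B", "pp", 0), list("B", "Y", "pd", 1),
                             list("A", "C", "pd", 1), list("C", "D", "met", 1)),
                   rep(0.5, 6))
  up <- run_config("upstream", 0)
  down <- run_config("downstream", 0)
  # against-then-with traversal through the common regulator R
  p1 <- list(nodes = c("A", "R", "Y"), edges = c(1L, 2L),
             forward = c(FALSE, TRUE))
  expect_true(is_valid_path(p1, up, pnet))
  expect_false(is_valid_path(p1, down, pnet))  # first edge runs backward
  # first edge not regulatory: invalid upstream
  p2 <- list(nodes = c("A", "B", "Y"), edges = c(3L, 4L),
             forward = c(TRUE, TRUE))
  expect_false(is_valid_path(p2, up, pnet))
  # all-forward directed path: valid downstream
  p3 <- list(nodes = c("A", "C", "D"), edges = c(5L, 6L),
             forward = c(TRUE, TRUE))
  expect_true(is_valid_path(p3, down, pnet))
  # a bare forward pd-pd chain is not an upstream path (empty prefix)
  expect_false(is_valid_path(p3, up, pnet))
  # repeated node or wrong length are structurally invalid
  expect_false(is_valid_path(list(nodes = c("A", "R", "A"),
                                  edges = c(1L, 1L),
                                  forward = c(FALSE, TRUE)), up, pnet))
  expect_false(is_valid_path(list(nodes = c("R", "A"), edges = 1L,
                                  forward = TRUE), down, pnet))
})

test_that("exhaustive enumeration matches hand counting on a triangle", {
  # A -> B -> C plus direct A -> C, all directed pd
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "C", "pd", 1)),
                   c(0.9, 0.8, 0.7))
  down <- run_config("downstream", 0)
  paths <- enumerate_valid_paths(pnet, "A", c("A", "C"), down)
  # only the two-edge forward path qualifies (min length 2, A != Y)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$nodes, c("A", "B", "C"))
  expect_equal(paths[[1]]$prob, 0.9 * 0.8)
  expect_length(enumerate_valid_paths(pnet, "C", c("A"), down), 0L)
  expect_length(enumerate_valid_paths(pnet, "A", "A", down), 0L)
  expect_error(enumerate_valid_paths(pnet, "Z", "A", down), "not in the network")
})

test_that("k-best equals the truncated exhaustive enumeration", {
  for (seed in 1:12) {
    pnet <- random_pnet(n_nodes = 8, n_edges = 14, seed = seed)
    genes <- pnet$nodes[seq_len(min(4, length(pnet$nodes)))]
    for (mode in c("downstream", "upstream")) {
      cfg <- run_config(mode, 0, max_path_length = 4, k = 5)
      ps <- suppressWarnings(k_best_paths(pnet, genes, cfg))
      for (A in ps$genes) {
        oracle <- enumerate_valid_paths(pnet, A, setdiff(ps$genes, A), cfg)
        oracle <- netsieve:::sort_paths(oracle)
        expected <- netsieve:::truncate_paths(oracle, cfg$k, cfg$k_scope)
        got <- ps$paths[[A]]
        expect_equal(lapply(got, `[`, c("nodes", "edges", "prob")),
                     lapply(expected, `[`, c("nodes", "edges", "prob")),
                     info = sprintf("seed %d mode %s start %s", seed, mode, A))
      }
    }
  }
})

test_that("downstream enumeration agrees with igraph simple paths", {
  skip_if_not_installed("igraph")
  pnet <- random_pnet(n_nodes = 8, n_edges = 16, seed = 99)
  # directed-only view so igraph semantics match the downstream mode
  dir_edges <- pnet$edges[pnet$edges$directed, , drop = FALSE]
  rownames(dir_edges) <- NULL
  dnet <- toy_pnet(dir_edges, dir_edges$prob)
  g <- igraph::graph_from_data_frame(dir_edges[, c("from", "to")],
                                     vertices = dnet$nodes)
  cfg <- run_config("downstream", 0, max_path_length = 4)
  A <- dnet$nodes[1]
  targets <- dnet$nodes[-1]
  mine <- enumerate_valid_paths(dnet, A, targets, cfg)
  ig <- igraph::all_simple_paths(g, from = A, to = targets, cutoff = 4)
  ig <- ig[lengths(ig) >= 3]  # >= 2 edges
  key <- function(nodes) paste(nodes, collapse = ">")
  expect_setequal(vapply(mine, function(p) key(p$nodes), character(1)),
                  vapply(ig, function(v) key(names(v)), character(1)))
})

test_that("zero-probability edges do not prune paths", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1)),
                   c(0, 0.5))
  cfg <- run_config("downstream", 0)
  ps <- k_best_paths(pnet, c("A", "C"), cfg)
  expect_length(ps$paths[["A"]], 1L)
  expect_equal(ps$paths[["A"]][[1]]$prob, 0)
})

test_that("k larger than the number of paths returns them all", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "D", "pd", 1), list("D", "C", "pd", 1)),
                   c(0.9, 0.9, 0.2, 0.2))
  ps <- k_best_paths(pnet, c("A", "C"), run_config("downstream", 0, k = 50))
  expect_length(ps$paths[["A"]], 2L)
  # sorted by decreasing probability
  expect_equal(vapply(ps$paths[["A"]], `[[`, numeric(1), "prob"),
               c(0.81, 0.04))
})

test_that("probability ties break lexicographically and runs are reproducible", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "D", "pd", 1), list("D", "C", "pd", 1)),
                   c(0.5, 0.5, 0.5, 0.5))
  cfg <- run_config("downstream", 0)
  ps1 <- k_best_paths(pnet, c("A", "C"), cfg)
  ps2 <- k_best_paths(pnet, c("A", "C"), cfg)
  expect_identical(ps1$paths, ps2$paths)
  expect_equal(ps1$paths[["A"]][[1]]$nodes, c("A", "B", "C"))
})

test_that("list genes absent from the network are dropped with a warning", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1)),
                   c(0.5, 0.5))
  expect_warning(ps <- k_best_paths(pnet, c("A", "C", "nope"),
                                    run_config("downstream", 0)),
                 "dropped")
  expect_setequal(ps$genes, c("A", "C"))
  expect_error(
    suppressWarnings(k_best_paths(pnet, "nope", run_config("downstream", 0))),
    "no gene-list members")
})
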