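# Small hand-checkable instance: two list genes A and C connected through B
# by two parallel two-edge routes, plus an irrelevant edge never on a path.
make_toy <- function(probs = c(0.9, 0.8, 0.6, 0.5, 0.3)) {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "D", "pd", 1), list("D", "C", "pd", 1),
                             list("E", "F", "pd", 1)),
                   probs)
  cfg <- run_config("downstream", 0.05, k = 5)
  ps <- k_best_paths(pnet, c("A", "C"), cfg)
  list(pnet = pnet, cfg = cfg, ps = ps)
}

test_that("objective decomposes into connectivity minus penalty", {
  toy <- make_toy()
  obj0 <- subnet_objective(integer(0), toy$ps, toy$pnet, toy$cfg)
  expect_equal(obj0$total, 0)
  expect_equal(obj0$connectivity_term, 0)
  # full universe: A connected via both routes; C has no downstream path
  obj <- subnet_objective(1:4, toy$ps, toy$pnet, toy$cfg)
  conn_A <- 1 - (1 - 0.9 * 0.8) * (1 - 0.6 * 0.5)  # hand computation
  expect_equal(obj$connectivity_term, conn_A)
  expect_equal(obj$penalty_term, 0.05 * 4)
  expect_equal(obj$total, conn_A - 0.2)
})

test_that("greedy finds the toy optimum and records a valid trace", {
  toy <- make_toy()
  res <- greedy_optimize(toy$ps, toy$pnet, toy$cfg)
  # exhaustive check over all subsets of the 4 candidate edges
  ex <- exhaustive_optimize(toy$ps, toy$pnet, toy$cfg)
  expect_equal(res$objective$total, ex$objective$total, tolerance = 1e-12)
  expect_setequal(res$subnetwork$idx, ex$idx)
  # edge E-F is never a candidate
  expect_false(5L %in% res$universe)
  expect_true(is_local_optimum(res, toy$ps, toy$pnet))
  expect_gte(res$objective$total, 0)
  # deterministic re-run
  res2 <- greedy_optimize(toy$ps, toy$pnet, toy$cfg)
  expect_identical(res2$trace, res$trace)
  expect_identical(res2$subnetwork$idx, res$subnetwork$idx)
})

test_that("extreme costs give the empty and the saturated solutions", {
  toy <- make_toy()
  # cost beyond any attainable connectivity: stay empty
  cfg_hi <- toy$cfg; cfg_hi$cost <- 3  # > |L| = 2
  res_hi <- greedy_optimize(toy$ps, toy$pnet, validate_config(cfg_hi))
  expect_length(res_hi$subnetwork$idx, 0L)
  expect_equal(res_hi$objective$total, 0)
  # zero cost: objective equals the full-universe objective
  cfg0 <- toy$cfg; cfg0$cost <- 0
  res0 <- greedy_optimize(toy$ps, toy$pnet, validate_config(cfg0))
  full <- subnet_objective(res0$universe, toy$ps, toy$pnet,
                           validate_config(cfg0))
  expect_equal(res0$objective$total, full$total, tolerance = 1e-12)
})

test_that("connectivity never decreases along addition moves", {
  sc <- generate_scenario(small_spec(seed = 11))
  fit <- suppressWarnings(infer_subnetwork(sc$paths$network,
                                           sc$paths$expression,
                                           sc$paths$genelist,
                                           mode = "downstream", cost = 0.005))
  tr <- fit$trace
  adds <- tr$kind %in% c("add", "path")
  prefix <- which(cumsum(!adds) == 0)
  if (length(prefix) > 1L) {
    expect_true(all(diff(tr$connectivity[prefix]) >= -1e-12))
  }
  expect_true(is_local_optimum(
    list(subnetwork = fit$subnetwork, universe = fit$universe,
         config = fit$config),
    fit$pathset, fit$network))
  expect_gte(fit$objective$total, 0)
})

test_that("cost sweep returns one run per cost with sane structure", {
  toy <- make_toy()
  expect_error(cost_sweep(toy$ps, toy$pnet, toy$cfg, numeric(0)), "empty")
  expect_error(cost_sweep(toy$ps, toy$pnet, toy$cfg, c(0.1, 0.2)),
               "decreasing")
  sweep <- cost_sweep(toy$ps, toy$pnet, toy$cfg, c(3, 0.05, 0))
  expect_length(sweep, 3L)
  expect_equal(attr(sweep, "edge_counts")[1], 0L)
  single <- cost_sweep(toy$ps, toy$pnet, toy$cfg, 0.05)
  expect_equal(single[[1]]$objective$total,
               greedy_optimize(toy$ps, toy$pnet, toy$cfg)$objective$total)
})

test_that("mean sub-network size grows as the cost drops", {
  costs <- c(0.5, 0.05, 0.005)
  sizes <- matrix(0, nrow = 4, ncol = length(costs))
  for (i in 1:4) {
    sc <- generate_scenario(small_spec(seed = 20 + i))
    pnet <- suppressMessages(build_probabilistic_network(
      read_network(sc$paths$network), read_expression(sc$paths$expression)))
    cfg <- run_config("downstream", 1)
    ps <- suppressWarnings(k_best_paths(
      pnet, read_gene_list(sc$paths$genelist), cfg))
    sweep <- suppressWarnings(cost_sweep(ps, pnet, cfg, costs))
    sizes[i, ] <- attr(sweep, "edge_counts")
  }
  means <- colMeans(sizes)
  expect_true(all(diff(means) >= 0))  # decreasing cost -> growing networks
})
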