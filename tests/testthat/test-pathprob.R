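test_that("path probability is the product of edge probabilities", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pp", 0),
                             list("C", "D", "pd", 1)),
                   c(0.9, 0.5, 0.88))
  expect_equal(path_probability(edge_path(1L, 2L), pnet), 0.45)
  expect_equal(path_probability(edge_path(3L), pnet), 0.88)
  expect_equal(path_probability(edge_path(1L, 2L, 3L), pnet), 0.9 * 0.5 * 0.88)
  expect_error(path_probability(edge_path(9L), pnet), "unknown edge")
})

test_that("restriction keeps exactly the fully contained paths", {
  paths <- list(edge_path(1L, 2L), edge_path(2L, 3L), edge_path(1L, 4L))
  expect_identical(restrict_paths(paths, 1:4), paths)
  expect_identical(restrict_paths(paths, integer(0)), list())
  surv <- restrict_paths(paths, c(1L, 2L, 3L))
  expect_identical(surv, paths[1:2])  # the path using edge 4 is dropped
})

test_that("union probability handles single, disjoint and shared-edge paths", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "D", "pd", 1), list("D", "C", "pd", 1)),
                   c(0.5, 0.4, 0.6, 0.7))
  expect_equal(union_probability(list(), pnet), 0)
  expect_equal(union_probability(list(edge_path(1L, 2L)), pnet), 0.2)
  # edge-disjoint pair p1 = 0.5, p2 = 0.4: 1 - 0.5 * 0.6
  pnet2 <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("A", "C", "pd", 1)),
                    c(0.5, 0.4))
  expect_equal(union_probability(list(edge_path(1L), edge_path(2L)), pnet2),
               0.7)
  # shared edge e1: {e1,e2}, {e1,e3} with p = (0.5, 0.4, 0.6) -> 0.38,
  # not the independent-paths value 1 - (1-0.2)(1-0.3) = 0.44
  pnet3 <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                              list("B", "D", "pd", 1)),
                    c(0.5, 0.4, 0.6))
  shared <- list(edge_path(1L, 2L), edge_path(1L, 3L))
  expect_equal(union_probability(shared, pnet3), 0.38)
  # duplicated paths cannot change the union
  expect_equal(union_probability(c(shared, shared[1]), pnet3), 0.38)
})

test_that("union agrees with 2^m brute force on random instances", {
  for (seed in 1:60) {
    set.seed(seed)
    m <- sample(3:12, 1)
    probs <- round(runif(m), 3)
    pnet <- toy_pnet(data.frame(from = paste0("n", seq_len(m)),
                                to = paste0("m", seq_len(m)),
                                type = "pd", directed = TRUE,
                                stringsAsFactors = FALSE), probs)
    n_paths <- sample(1:6, 1)
    paths <- lapply(seq_len(n_paths), function(i) {
      edge_path(sample(m, min(m, sample(1:4, 1))))
    })
    expect_equal(union_probability(paths, pnet),
                 brute_force_union(paths, pnet),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("brute-force oracle bounds its scale and base cases", {
  pnet <- toy_pnet(data.frame(from = paste0("n", 1:25), to = paste0("m", 1:25),
                              type = "pd", directed = TRUE,
                              stringsAsFactors = FALSE), rep(1, 25))
  expect_equal(brute_force_union(list(), pnet), 0)
  expect_equal(brute_force_union(list(edge_path(1:5)), pnet), 1)
  expect_error(brute_force_union(list(edge_path(1:21)), pnet),
               "oracle scale exceeded")
})

test_that("union respects bounds and is monotone in the sub-network", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 10
    probs <- round(runif(m), 3)
    pnet <- toy_pnet(data.frame(from = paste0("n", 1:m), to = paste0("m", 1:m),
                                type = "pd", directed = TRUE,
                                stringsAsFactors = FALSE), probs)
    paths <- lapply(1:5, function(i) edge_path(sample(m, sample(1:4, 1))))
    u <- union_probability(paths, pnet)
    p_i <- vapply(paths, path_probability, numeric(1), network = pnet)
    expect_gte(u, max(p_i) - 1e-12)
    expect_lte(u, min(1, sum(p_i)) + 1e-12)
    # growing S can only revalidate paths
    s_small <- sample(m, 4)
    s_big <- union(s_small, sample(m, 3))
    expect_lte(connectivity(paths, s_small, pnet),
               connectivity(paths, s_big, pnet) + 1e-12)
  }
})

test_that("connectivity restricts then takes the union", {
  pnet <- toy_pnet(toy_edges(list("A", "B", "pd", 1), list("B", "C", "pd", 1),
                             list("A", "D", "pd", 1), list("D", "C", "pd", 1)),
                   c(0.5, 0.4, 0.6, 0.7))
  paths <- list(edge_path(1L, 2L), edge_path(3L, 4L))
  expect_equal(connectivity(paths, 1:4, pnet),
               union_probability(paths, pnet))
  expect_equal(connectivity(paths, integer(0), pnet), 0)
  # only the first path survives in {1, 2}
  expect_equal(connectivity(paths, 1:2, pnet), 0.2)
})
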