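test_that("stepwise addition is deterministic and sound on 3 taxa", {
  inputs <- c(read_newick("((A,B),C);"))
  t3 <- stepwise_addition_start(c("A", "B", "C"), inputs, seed = 1)
  expect_setequal(leaf_labels(t3), c("A", "B", "C"))
  expect_length(split_keys(t3), 0L)

  cf <- conflict_free_instance(6, 15, seed = 2)
  a <- stepwise_addition_start(leaf_labels(cf$truth), cf$inputs, seed = 99)
  b <- stepwise_addition_start(leaf_labels(cf$truth), cf$inputs, seed = 99)
  expect_same_topology(a, b)
  expect_error(stepwise_addition_start(c("A", "B"), cf$inputs), "at least 3")
})

test_that("stepwise addition tracks a single consistent full input tree", {
  # with one binary tree on all 5 taxa as the only signal, greedy insertion
  # reaches d = 0 whatever the insertion order
  full <- read_newick("((A,B),(C,(D,E)));")
  for (s in 1:30) {
    st <- stepwise_addition_start(leaf_labels(full), c(full), seed = s)
    expect_identical(robinson_foulds(deroot(st), deroot(full)), 0L)
  }
})

test_that("SPR neighborhood of a quartet is the two other quartets", {
  nb <- spr_neighbors(read_newick("((A,B),(C,D));"))
  expect_length(nb, 2L)
  keys <- vapply(nb, function(t) split_keys(t), "")
  expect_setequal(keys, c(split_keys(read_newick("((A,C),(B,D));")),
                          split_keys(read_newick("((A,D),(B,C));"))))
})

test_that("SPR neighbors differ from the source and span the same leaves", {
  t <- random_supertree(LETTERS[1:6], seed = 13)
  nb <- spr_neighbors(t)
  for (u in nb) {
    expect_setequal(leaf_labels(u), leaf_labels(t))
    expect_gte(robinson_foulds(u, t), 2L)
  }
  # no duplicated topologies in the neighborhood
  sigs <- vapply(nb, function(u) paste(sort(split_keys(u)), collapse = ";"), "")
  expect_identical(anyDuplicated(sigs), 0L)
  expect_error(spr_neighbors(read_newick("(A,B,(C,D),E);")), "binary")
})

test_that("five-leaf SPR neighborhoods match the brute-force adjacency oracle", {
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  src <- all5[[4]]
  nb <- spr_neighbors(src)
  got <- sort(vapply(nb, function(u) paste(sort(split_keys(u)), collapse = ";"), ""))
  want <- character(0)
  for (i in seq_along(all5)) {
    u <- all5[[i]]
    if (oracle_is_spr_neighbor(src, u))
      want <- c(want, paste(sort(split_keys(u)), collapse = ";"))
  }
  expect_identical(got, sort(want))
})

test_that("all four strategies hill-climb with non-decreasing trajectories", {
  truth <- random_supertree(paste0("t", 1:7), seed = 4)
  sim <- generate_input_trees(synthetic_spec(
    truth, n_trees = 20, subset_size = c(4, 7), distortion_rate = 1, seed = 5))
  for (strat in 1:4) {
    res <- run_search(sim$trees,
                      config = search_config(strategy = strat, seed = 100 + strat))
    expect_true(all(diff(res$trajectory$total_log_likelihood) >= 0))
    expect_lte(max(res$trajectory$iteration), 10L)
    # reported best score is re-checkable from the tree itself
    expect_equal(res$best_score$total_log_likelihood,
                 score_supertree(res$best_tree, sim$trees)$total_log_likelihood)
  }
})

test_that("search recovers a conflict-free 6-taxon truth at total zero", {
  cf <- conflict_free_instance(6, 20, seed = 8)
  res <- run_search(cf$inputs,
                    config = search_config(strategy = 1, n_restarts = 5,
                                           seed = 17))
  expect_equal(res$best_score$total_log_likelihood, 0)
  expect_same_topology(res$best_tree, cf$truth)
})

test_that("defaults mirror the standard run settings", {
  cfg <- search_config()
  expect_identical(cfg$strategy, 4L)
  expect_identical(cfg$max_iterations, 10L)
  expect_identical(cfg$n_restarts, 1L)
})

test_that("identical seeds reproduce the search exactly", {
  cf <- conflict_free_instance(6, 10, seed = 19)
  r1 <- run_search(cf$inputs, config = search_config(strategy = 2, seed = 7))
  r2 <- run_search(cf$inputs, config = search_config(strategy = 2, seed = 7))
  expect_same_topology(r1$best_tree, r2$best_tree)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$n_trees_evaluated, r2$n_trees_evaluated)
})

test_that("user start trees are validated and polytomies resolved", {
  cf <- conflict_free_instance(6, 10, seed = 23)
  labs <- leaf_labels(cf$truth)
  bad <- read_newick("((A,B),(C,D));")
  expect_error(run_search(cf$inputs,
                          config = search_config(start_tree = bad, seed = 1)),
               "lacks taxa")
  star <- read_newick(paste0("(", paste(labs, collapse = ","), ");"))
  expect_warning(res <- run_search(cf$inputs,
                                   config = search_config(strategy = 1,
                                                          start_tree = star,
                                                          seed = 1)),
                 "polytomies")
  expect_equal(res$best_score$total_log_likelihood, 0)
})

test_that("exhaustive search enumerates (2n-5)!! topologies and bounds the heuristics", {
  q <- c(read_newick("((A,B),(C,D));"))
  ex4 <- exhaustive_ml_supertree(q)
  expect_identical(ex4$n_topologies, 3L)
  expect_equal(ex4$best_score$total_log_likelihood, 0)
  expect_same_topology(ex4$best_tree, q[[1]])

  truth <- random_supertree(LETTERS[1:6], seed = 29)
  sim <- generate_input_trees(synthetic_spec(
    truth, n_trees = 12, subset_size = c(4, 6), distortion_rate = 1, seed = 30))
  ex <- exhaustive_ml_supertree(sim$trees)
  expect_identical(ex$n_topologies, 105L)
  res <- run_search(sim$trees,
                    config = search_config(strategy = 1, n_restarts = 5,
                                           seed = 31))
  expect_lte(res$best_score$total_log_likelihood,
             ex$best_score$total_log_likelihood)

  big <- c(random_supertree(paste0("z", 1:9)))
  expect_error(exhaustive_ml_supertree(big), "limited to 8")
})
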