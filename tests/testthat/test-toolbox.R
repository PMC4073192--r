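test_that("random polytomy resolution is binary, reproducible and conservative", {
  star <- read_newick("(A,B,C,D);")
  r1 <- resolve_polytomies_random(star, seed = 5)
  expect_true(ape::is.binary(ape::unroot(r1)))
  expect_length(split_keys(r1), 1L)
  expect_same_topology(r1, resolve_polytomies_random(star, seed = 5))

  bin <- read_newick("((A,B),(C,D));")
  expect_identical(resolve_polytomies_random(bin, seed = 1), bin)

  set.seed(73)
  for (i in 1:100) {
    t <- random_polytomous_tree(sample(5:12, 1))
    r <- resolve_polytomies_random(t)
    expect_true(ape::is.binary(ape::unroot(r)))
    expect_true(all(split_keys(t) %in% split_keys(r)))
  }
})

test_that("reference-guided resolution follows the reference where informative", {
  star <- read_newick("(A,B,C,D);")
  ref <- read_newick("((A,B),(C,D));")
  r <- resolve_polytomies_reference(star, ref, seed = 1)
  expect_same_topology(r, ref)

  already <- read_newick("((A,B),(C,D));")
  r2 <- resolve_polytomies_reference(already, ref, seed = 1)
  expect_same_topology(r2, already)

  expect_error(resolve_polytomies_reference(read_newick("(A,B,Z,Q);"), ref),
               "lacks taxa")
})

test_that("reference-guided resolution never contradicts a compatible reference", {
  set.seed(79)
  for (i in 1:50) {
    n <- sample(6:10, 1)
    ref <- random_supertree(paste0("r", 1:(n + 2)))
    labs <- sample(ref$tip.label, n)
    # a polytomous tree compatible with the reference: collapse random
    # internal edges of the reference's restriction
    base <- prune_to_taxa(ref, labs)
    t <- base
    nt <- length(t$tip.label)
    t$edge.length <- ifelse(t$edge[, 2] > nt & stats::runif(nrow(t$edge)) < 0.6,
                            0, 1)
    t <- ape::di2multi(t, tol = 0.5)
    t$edge.length <- NULL

    r <- resolve_polytomies_reference(t, ref)
    expect_true(ape::is.binary(ape::unroot(r)))
    expect_true(all(split_keys(t) %in% split_keys(r)))
    # the reference's restriction is fully recovered, hence nothing in the
    # result can conflict with it
    ss_r <- tree_splits(r)
    ss_ref <- tree_splits(base)
    expect_true(all(ss_ref$keys %in% ss_r$keys))
    for (side in ss_r$sides) {
      ok <- all(vapply(ss_ref$sides, splits_compatible_oracle,
                       logical(1), b = side, n = n))
      expect_true(ok)
    }
  }
})

test_that("conflicting input splits survive reference-guided resolution", {
  set.seed(83)
  for (i in 1:10) {
    n <- 8
    labs <- paste0("r", 1:n)
    ref <- random_supertree(labs)
    t <- random_polytomous_tree(n)
    t$tip.label <- labs
    r <- resolve_polytomies_reference(t, ref)
    expect_true(ape::is.binary(ape::unroot(r)))
    expect_true(all(split_keys(t) %in% split_keys(r)))
  }
})

test_that("pruning a tree set drops low-overlap trees with a warning", {
  trees <- c(read_newick("((A,B),(C,D));"),
             read_newick("((A,E),F);"),
             read_newick("((B,C),D);"))
  expect_warning(out <- prune_trees(trees, c("A", "B", "C", "D")),
                 "indices: 2")
  expect_length(out, 2L)

  all_in <- prune_trees(trees[1], c("A", "B", "C", "D", "X"))
  expect_same_topology(all_in[[1]], trees[[1]])
  expect_warning(expect_error(prune_trees(trees[2], c("A", "B")), "no trees"))
})

test_that("newick/nexus conversion round-trips split sets", {
  f1 <- withr::local_tempfile(fileext = ".nwk")
  f2 <- withr::local_tempfile(fileext = ".nex")
  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((human,mouse),(cat,dog));", "((human,cat),(mouse,dog));"), f1)
  convert_tree_format(f1, f2, from = "newick", to = "nexus")
  convert_tree_format(f2, f3, from = "nexus", to = "newick")
  a <- read_tree_file(f1)
  b <- read_tree_file(f3)
  expect_length(b, 2L)
  for (i in 1:2) expect_same_topology(a[[i]], b[[i]])

  bad <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "END;"), bad)
  expect_error(read_tree_file(bad, format = "nexus"))
})

test_that("taxon extraction reports per-tree sets and an order-free union", {
  trees <- c(read_newick("((A,B),C);"), read_newick("((B,C),D);"))
  ex <- extract_taxa(trees)
  expect_identical(ex$per_tree[[1]], c("A", "B", "C"))
  expect_identical(ex$union, c("A", "B", "C", "D"))
  rev_ex <- extract_taxa(trees[2:1])
  expect_identical(rev_ex$union, ex$union)

  one <- extract_taxa(trees[1])
  expect_identical(one$per_tree[[1]], one$union)
})
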