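test_that("newick parsing handles resolved trees, polytomies and lengths", {
  t1 <- read_newick("((A,B),(C,D));")
  expect_s3_class(t1, "phylo")
  expect_setequal(leaf_labels(t1), c("A", "B", "C", "D"))
  expect_true(ape::is.rooted(t1))
  expect_length(split_keys(t1), 1L)

  t2 <- read_newick("(A,B,(C,D):0.5);")
  root <- length(t2$tip.label) + 1L
  expect_equal(sum(t2$edge[, 1] == root), 3L)  # 3-child root preserved
  expect_true(0.5 %in% t2$edge.length[!is.na(t2$edge.length)])

  t3 <- read_newick("A;")
  expect_equal(leaf_labels(t3), "A")
  expect_equal(write_newick(t3), "A;")
})

test_that("malformed newick is rejected with located errors", {
  expect_error(read_newick("((A,B),(C,D)"), "missing ';'")
  expect_error(read_newick("((A,B),(C,D);"), "unclosed '\\('")
  expect_error(read_newick("(A,B)),C;"), "unbalanced '\\)' at offset 6")
  expect_error(read_newick("((A,B),(A,C));"), "duplicate leaf label")
})

test_that("write/parse round trip preserves topology and branch lengths", {
  txt <- "(A:1.5,(B:0.25,C:0.5):0.125,D:2);"
  t <- read_newick(txt)
  t2 <- read_newick(write_newick(t))
  expect_same_topology(t, t2)
  expect_setequal(t2$edge.length, t$edge.length)
})

test_that("topology is invariant under write->parse for random trees", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    t <- random_polytomous_tree(n)
    t2 <- read_newick(write_newick(t))
    expect_setequal(split_keys(t2), split_keys(t))
  }
})

test_that("tree files are read in order, with line-numbered errors", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A,B),(C,D));", "", "((A,C),D);", "(A,(B,E));"), f)
  trees <- read_tree_file(f)
  expect_length(trees, 3L)
  expect_setequal(leaf_labels(trees[[2]]), c("A", "C", "D"))
  expect_setequal(union_taxa(trees), c("A", "B", "C", "D", "E"))

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A,B),(C,D));", "((A,B);"), bad)
  expect_error(read_tree_file(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".nwk")
  writeLines(character(0), empty)
  expect_error(read_tree_file(empty), "empty")
})

test_that("nexus TRANSLATE tables are resolved to full labels", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;", "  TRANSLATE",
               "    1 human,", "    2 mouse,", "    3 cat,", "    4 dog;",
               "  TREE one = ((1,2),(3,4));",
               "  TREE two = ((1,3),(2,4));",
               "END;"), f)
  trees <- read_tree_file(f, format = "nexus")
  expect_length(trees, 2L)
  expect_setequal(leaf_labels(trees[[1]]), c("human", "mouse", "cat", "dog"))
  expect_length(intersect(split_keys(trees[[1]]), split_keys(trees[[2]])), 0L)
})

test_that("pruning restricts splits exactly", {
  t <- read_newick("((A,B),(C,(D,E)));")
  p <- prune_to_taxa(t, c("A", "B", "C", "D"))
  expect_setequal(leaf_labels(p), c("A", "B", "C", "D"))
  expect_setequal(split_keys(p), split_keys(read_newick("((A,B),(C,D));")))

  expect_same_topology(prune_to_taxa(t, leaf_labels(t)), t)
  two <- prune_to_taxa(read_newick("((A,B),(C,D));"), c("A", "C"))
  expect_setequal(leaf_labels(two), c("A", "C"))
  expect_error(prune_to_taxa(t, c("X", "Y")), "no overlap")
})

test_that("pruned splits are the non-trivial restrictions of original splits", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    t <- random_polytomous_tree(n)
    labs <- leaf_labels(t)
    keep <- sample(labs, sample(4:(n - 1), 1))
    p <- prune_to_taxa(t, keep)
    # oracle: restrict every original split to 'keep' by set intersection
    expected <- character(0)
    slabs <- sort(keep)
    ss <- tree_splits(t)
    for (side_idx in ss$sides) {
      side <- intersect(ss$labels[side_idx], keep)
      other <- setdiff(keep, side)
      if (length(side) < 2L || length(other) < 2L) next
      cs <- if (slabs[1] %in% side) side else other
      expected <- c(expected, paste(sort(match(cs, slabs)), collapse = ","))
    }
    expect_setequal(split_keys(p), unique(expected))
  }
})

test_that("deroot and reroot conserve the unrooted split set", {
  t <- read_newick("((A,B),(C,D));")
  u <- deroot(t)
  expect_false(ape::is.rooted(u))
  expect_setequal(split_keys(u), split_keys(t))
  expect_same_topology(deroot(u), u)
  expect_error(deroot(read_newick("(A,B);")), "fewer than 3")

  r <- reroot_on(t, c("C", "D"))
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("C", "D")))
  expect_setequal(split_keys(r), split_keys(t))

  r1 <- reroot_on(t, "A")  # single-leaf outgroup always valid
  expect_setequal(split_keys(r1), split_keys(t))

  expect_error(reroot_on(t, c("A", "C")), "not monophyletic")
  expect_error(reroot_on(t, c("A", "B", "C", "D")), "full leaf set")
  expect_error(reroot_on(t, c("A", "Z")), "not in tree")
})
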