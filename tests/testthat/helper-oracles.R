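# Independent oracles used across the suite. Split enumeration goes through
# ape::prop.part (C implementation, set algebra done here), deliberately a
# different route from the package's own edge-traversal split encoding.

# canonical split keys via prop.part: each non-trivial bipartition encoded
# by the sorted labels of the side containing the alphabetically first taxon
oracle_split_keys <- function(phy) {
  labs <- sort(phy$tip.label)
  n <- length(labs)
  if (n < 4L) return(character(0))
  u <- ape::unroot(phy)
  pp <- ape::prop.part(u)
  keys <- character(0)
  for (cl in pp) {
    side <- sort(u$tip.label[cl])
    k <- length(side)
    if (k < 2L || k > n - 2L) next
    if (!(labs[1] %in% side)) side <- sort(setdiff(labs, side))
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

oracle_rf <- function(a, b) {
  sa <- oracle_split_keys(a)
  sb <- oracle_split_keys(b)
  length(sa) + length(sb) - 2L * length(intersect(sa, sb))
}

# brute-force total score: prune with ape, enumerate splits with prop.part
oracle_total_log_likelihood <- function(supertree, inputs,
                                        alpha = 1, beta = 1) {
  tot <- 0
  for (t in inputs) {
    pruned <- ape::keep.tip(supertree, t$tip.label)
    tot <- tot + log(alpha) - beta * oracle_rf(pruned, t)
  }
  tot
}

# a random topology with random polytomies
random_polytomous_tree <- function(n, collapse_prob = 0.35) {
  t <- ape::rtree(n)
  nt <- length(t$tip.label)
  internal <- t$edge[, 2] > nt
  t$edge.length <- ifelse(internal & stats::runif(nrow(t$edge)) < collapse_prob,
                          0, 1)
  t <- ape::di2multi(t, tol = 0.5)
  t$edge.length <- NULL
  t
}

# is 'side' (labels) a pendant subtree (one side of an edge) of unrooted phy?
oracle_is_pendant <- function(phy, side) {
  labs <- sort(phy$tip.label)
  k <- length(side)
  if (k == 1L || k == length(labs) - 1L) return(TRUE)
  if (!(labs[1] %in% side)) side <- setdiff(labs, side)
  paste(sort(side), collapse = ",") %in% oracle_split_keys(phy)
}

# brute-force SPR adjacency: U is one SPR move from T iff some leaf subset S
# is a pendant subtree with identical induced topology in both trees, and
# the trees agree exactly after deleting S
oracle_is_spr_neighbor <- function(T, U) {
  labs <- T$tip.label
  n <- length(labs)
  if (!setequal(labs, U$tip.label)) return(FALSE)
  if (oracle_rf(T, U) == 0L) return(FALSE)
  for (sz in 1:(n - 3L)) {
    for (S in utils::combn(labs, sz, simplify = FALSE)) {
      rest <- setdiff(labs, S)
      if (!oracle_is_pendant(T, S) || !oracle_is_pendant(U, S)) next
      if (sz >= 3L) {
        ti <- ape::keep.tip(T, S)
        ui <- ape::keep.tip(U, S)
        if (oracle_rf(ti, ui) != 0L) next
      }
      tr <- ape::keep.tip(T, rest)
      ur <- ape::keep.tip(U, rest)
      if (oracle_rf(tr, ur) == 0L) return(TRUE)
    }
  }
  FALSE
}

# conflict-free fixture: input trees are undistorted restrictions of a known
# binary truth
conflict_free_instance <- function(n_taxa, n_trees, seed,
                                   min_size = 4, max_size = n_taxa) {
  truth <- random_supertree(paste0("t", seq_len(n_taxa)), seed = seed)
  sim <- generate_input_trees(synthetic_spec(
    truth, n_trees = n_trees, subset_size = c(min_size, max_size),
    distortion_rate = 0, seed = seed + 1))
  list(truth = truth, inputs = sim$trees, sim = sim)
}

split_keys <- function(phy) tree_splits(phy)$keys

expect_same_topology <- function(a, b) {
  expect_setequal(split_keys(a), split_keys(b))
}

# independent split-compatibility check by explicit set algebra
splits_compatible_oracle <- function(a, b, n) {
  ac <- setdiff(seq_len(n), a)
  bc <- setdiff(seq_len(n), b)
  length(intersect(a, b)) == 0 || length(intersect(a, bc)) == 0 ||
    length(intersect(ac, b)) == 0 || length(intersect(ac, bc)) == 0
}
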