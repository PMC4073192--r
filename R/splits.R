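#' Non-trivial splits of a tree
#'
#' Computes the set of non-trivial splits (bipartitions of the leaf set
#' induced by internal edges) of the derooted topology. Splits are encoded
#' canonically so that the two orientations of a bipartition compare equal:
#' each split is represented by the side containing the lexicographically
#' first leaf label, as sorted label indices. A binary unrooted tree on
#' `n >= 4` leaves has exactly `n - 3` such splits; trees on fewer than 4
#' leaves have none.
#'
#' @param tree A `phylo` object.
#' @return An object of class `tree_splits`: a list with `labels` (sorted
#'   leaf labels), `keys` (canonical split keys, one per split) and `sides`
#'   (for each split, the sorted indices into `labels` of the side containing
#'   `labels[1]`).
#' @examples
#' tree_splits(read_newick("(((A,B),C),D,E);"))$keys
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- sort(tree$tip.label)
  n <- length(labs)
  out <- list(labels = labs, keys = character(0), sides = list())
  class(out) <- "tree_splits"
  if (n < 4L) return(out)
  sides <- edge_leaf_sets(tree)          # tip-index sets below each edge
  idx <- match(tree$tip.label, labs)     # tip number -> sorted-label index
  seen <- character(0)
  keep_sides <- list()
  for (s in sides) {
    k <- length(s)
    if (k < 2L || k > n - 2L) next
    side <- sort(idx[s])
    if (!(1L %in% side)) side <- setdiff(seq_len(n), side)
    key <- paste(side, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    keep_sides[[length(keep_sides) + 1L]] <- side
  }
  out$keys <- seen
  out$sides <- keep_sides
  out
}

#' @export
print.tree_splits <- function(x, ...) {
  cat("Set of", length(x$keys), "non-trivial split(s) on",
      length(x$labels), "taxa\n")
  for (i in seq_along(x$sides)) {
    side <- x$labels[x$sides[[i]]]
    other <- setdiff(x$labels, side)
    cat("  ", paste(side, collapse = " "), "|",
        paste(other, collapse = " "), "\n")
  }
  invisible(x)
}

# leaf-index set below each edge (child side), by postorder accumulation
edge_leaf_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  e1 <- tree$edge[, 1]
  e2 <- tree$edge[, 2]
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  for (j in seq_along(e1)) {
    below[[e1[j]]] <- c(below[[e1[j]]], below[[e2[j]]])
  }
  lapply(seq_along(e1), function(j) below[[e2[j]]])
}

# canonical key of one side of a split, given the full (sorted) label set
canonical_split_key <- function(side, labels) {
  slabs <- sort(labels)
  idx <- sort(match(side, slabs))
  if (anyNA(idx)) stop("split side contains unknown labels")
  if (!(1L %in% idx)) idx <- setdiff(seq_along(slabs), idx)
  paste(idx, collapse = ",")
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference distance on non-trivial splits: the number of
#' splits present in exactly one of the two trees. Both directions of the
#' symmetric difference are counted (the classical unweighted distance, not
#' the halved variant). The comparison is purely topological; branch lengths
#' and rootings are ignored. Both trees must have the same leaf set — prune
#' first (see [prune_to_taxa()]) when they do not.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @return A non-negative integer; `0` iff the two split sets are equal.
#' @examples
#' robinson_foulds(read_newick("((A,B),(C,D));"), read_newick("((A,C),(B,D));"))
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- leaf_labels(t1)
  l2 <- leaf_labels(t2)
  if (!setequal(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop("leaf sets differ: only in first = {",
         paste(only1, collapse = ","), "}; only in second = {",
         paste(only2, collapse = ","), "}")
  }
  s1 <- tree_splits(t1)$keys
  s2 <- tree_splits(t2)$keys
  length(s1) + length(s2) - 2L * length(intersect(s1, s2))
}

# pairwise compatibility of two splits over the same n labels
# (sides as index vectors): compatible iff one of the four intersections
# of sides is empty
splits_compatible <- function(a, b, n) {
  ac <- setdiff(seq_len(n), a)
  bc <- setdiff(seq_len(n), b)
  length(intersect(a, b)) == 0L || length(intersect(a, bc)) == 0L ||
    length(intersect(ac, b)) == 0L || length(intersect(ac, bc)) == 0L
}

# Build a (possibly multifurcating) tree displaying exactly the given
# pairwise-compatible non-trivial splits, with optional internal-node labels
# (one per split, e.g. bootstrap supports). Splits are given as sides
# (index vectors into sorted 'labels').
build_tree_from_splits <- function(labels, sides, clade_labels = NULL) {
  labels <- sort(labels)
  n <- length(labels)
  if (length(sides) == 0L) {
    return(read_newick(paste0("(", paste(labels, collapse = ","), ");")))
  }
  # clades relative to an (arbitrary) rooting at labels[1]
  clades <- lapply(sides, function(s) {
    s <- sort(as.integer(s))
    if (1L %in% s) sort(setdiff(seq_len(n), s)) else s
  })
  keys <- vapply(clades, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate splits supplied")
  if (is.null(clade_labels)) clade_labels <- rep("", length(clades))
  sizes <- lengths(clades)
  contains <- function(a, b) all(b %in% a) && length(b) < length(a)
  clade_newick <- function(id) {
    members <- clades[[id]]
    inner <- which(vapply(seq_along(clades), function(j)
      contains(members, clades[[j]]), logical(1)))
    assemble(members, inner, suffix = clade_labels[id])
  }
  assemble <- function(universe, ids, suffix = NULL) {
    # maximal clades among ids, plus uncovered singleton leaves
    maximal <- ids[vapply(ids, function(i)
      !any(vapply(ids, function(j)
        j != i && contains(clades[[j]], clades[[i]]), logical(1))),
      logical(1))]
    parts <- vapply(maximal, clade_newick, "")
    covered <- unlist(clades[maximal])
    singles <- setdiff(universe, covered)
    body <- paste(c(parts, labels[singles]), collapse = ",")
    if (is.null(suffix)) body else paste0("(", body, ")", suffix)
  }
  universe <- 2:n
  ids <- which(vapply(clades, function(cl) !(1L %in% cl), logical(1)))
  body <- assemble(universe, ids)
  read_newick(paste0("(", labels[1], ",", body, ");"))
}
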