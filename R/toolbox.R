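#' Randomly resolve polytomies
#'
#' Refines every multifurcation into a binary subtree by iteratively joining
#' randomly chosen child pairs. Every original split is preserved; new
#' splits only refine the polytomies. Already-binary trees are returned
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param seed Optional integer seed for reproducibility.
#' @return A binary `phylo`.
#' @export
resolve_polytomies_random <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = TRUE)
}

#' Resolve polytomies against a reference tree
#'
#' Refines each polytomy to agree with the reference topology wherever the
#' reference (restricted to the tree's taxa) is informative: every reference
#' split compatible with the tree is added, then any residual ambiguity is
#' resolved randomly. All original splits are preserved, and no split of the
#' result conflicts with the reference's restriction.
#'
#' @param tree A `phylo` object.
#' @param reference A `phylo` whose leaves cover the tree's leaves.
#' @param seed Optional integer seed for the residual random resolution.
#' @return A binary `phylo` displaying all original splits plus the
#'   compatible reference splits.
#' @export
resolve_polytomies_reference <- function(tree, reference, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(reference, "phylo"))
  missing <- setdiff(leaf_labels(tree), leaf_labels(reference))
  if (length(missing))
    stop("reference lacks taxa: ", paste(sort(missing), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  labs <- sort(leaf_labels(tree))
  n <- length(labs)
  ref <- prune_to_taxa(reference, labs)
  ts <- tree_splits(tree)
  rs <- tree_splits(ref)
  sides <- ts$sides
  keys <- ts$keys
  for (i in seq_along(rs$keys)) {
    if (rs$keys[i] %in% keys) next
    cand <- rs$sides[[i]]
    ok <- all(vapply(sides, splits_compatible, logical(1),
                     b = cand, n = n))
    if (ok) {
      sides[[length(sides) + 1L]] <- cand
      keys <- c(keys, rs$keys[i])
    }
  }
  refined <- build_tree_from_splits(labs, sides)
  resolve_polytomies_random(refined)
}

#' Prune a set of trees to a taxon subset
#'
#' Applies [prune_to_taxa()] to every tree; trees sharing fewer than two
#' taxa with `keep` are dropped with a warning.
#'
#' @param trees A `multiPhylo` or list of `phylo`.
#' @param keep Character vector of taxa to retain.
#' @return A `multiPhylo` of the pruned trees, in input order.
#' @export
prune_trees <- function(trees, keep) {
  trees <- as_treelist(trees)
  ovl <- vapply(trees, function(t) length(intersect(leaf_labels(t), keep)),
                integer(1))
  drop <- which(ovl < 2L)
  if (length(drop))
    warning("dropping ", length(drop), " tree(s) sharing fewer than 2 taxa ",
            "with the retained set (indices: ",
            paste(drop, collapse = ", "), ")")
  kept <- which(ovl >= 2L)
  if (length(kept) == 0L) stop("no trees share at least 2 taxa with 'keep'")
  out <- lapply(trees[kept], prune_to_taxa, keep = keep)
  class(out) <- "multiPhylo"
  out
}

#' Convert a tree file between newick and nexus
#'
#' Lossless with respect to topology and labels: nexus `TRANSLATE` tables
#' are expanded on read and regenerated on write.
#'
#' @param in_path Input file path.
#' @param out_path Output file path.
#' @param from,to `"newick"` or `"nexus"`.
#' @return Invisibly, the trees written.
#' @export
convert_tree_format <- function(in_path, out_path,
                                from = c("newick", "nexus"),
                                to = c("nexus", "newick")) {
  from <- match.arg(from)
  to <- match.arg(to)
  trees <- read_tree_file(in_path, format = from)
  if (to == "nexus") {
    ape::write.nexus(trees, file = out_path, translate = TRUE)
  } else {
    writeLines(vapply(trees, write_newick, ""), out_path)
  }
  invisible(trees)
}

#' Taxon sets of a collection of trees
#'
#' @param trees A `multiPhylo` or list of `phylo`.
#' @return A list with `per_tree` (sorted leaf labels of each tree, in input
#'   order) and `union` (their sorted union).
#' @export
extract_taxa <- function(trees) {
  trees <- as_treelist(trees)
  per <- lapply(trees, function(t) sort(leaf_labels(t)))
  list(per_tree = per, union = sort(unique(unlist(per))))
}
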